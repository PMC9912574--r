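#' Renumber and topologically order a pedigree
#'
#' Takes raw (animal, sire, dam) triples with arbitrary identifiers and returns
#' a validated pedigree in which every parent precedes its offspring. Unknown
#' parents (coded `NA`, `""` or `"0"`) are treated as unrelated, non-inbred
#' base-population animals. Ties in the topological order are broken by input
#' order, so the layout of every downstream matrix is reproducible.
#'
#' @param raw_records data.frame with columns `animal`, `sire`, `dam`
#'   (character or integer ids). Parents that never appear as animals are
#'   added implicitly as base animals, in order of first mention.
#' @param compute_F compute inbreeding coefficients immediately (default TRUE).
#' @return An object of class `pedigree` : list with `labels` (character),
#'   `sire`/`dam` (integer indices into `labels`, 0 = unknown), `F`
#'   (inbreeding coefficients) and `n`.
#' @export
renumber_pedigree <- function(raw_records, compute_F = TRUE) {
  stopifnot(is.data.frame(raw_records),
            all(c("animal", "sire", "dam") %in% names(raw_records)))
  id   <- as.character(raw_records$animal)
  sire <- as.character(raw_records$sire)
  dam  <- as.character(raw_records$dam)
  unk <- function(x) is.na(x) | x == "" | x == "0"
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)]   <- NA_character_
  if (anyDuplicated(id))
    stop("duplicated animal id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  self <- !is.na(sire) & sire == id | !is.na(dam) & dam == id
  if (any(self))
    stop("animal listed as its own parent: ", paste(id[self], collapse = ", "))

  # implicit base parents, registered in order of first mention
  extra <- setdiff(stats::na.omit(c(rbind(sire, dam))), id)
  if (length(extra)) {
    id   <- c(extra, id)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam  <- c(rep(NA_character_, length(extra)), dam)
  }
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)

  # Kahn topological sort, stable in input order
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (!is.na(p)) {
      indeg[i] <- indeg[i] + 1L
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  order_out <- integer(0)
  ready <- which(indeg == 0L)   # ascending = input order
  while (length(ready)) {
    v <- ready[1L]; ready <- ready[-1L]
    order_out <- c(order_out, v)
    for (w in kids[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- sort(c(ready, w))
    }
  }
  if (length(order_out) < n) {
    left <- setdiff(seq_len(n), order_out)
    stop("pedigree cycle detected involving: ",
         paste(id[left], collapse = ", "))
  }
  pos <- integer(n); pos[order_out] <- seq_len(n)
  ped <- structure(list(
    labels = id[order_out],
    sire = ifelse(is.na(si[order_out]), 0L, pos[si[order_out]]),
    dam  = ifelse(is.na(di[order_out]), 0L, pos[di[order_out]]),
    F = rep(NA_real_, n),
    n = n), class = "pedigree")
  if (compute_F) ped$F <- compute_inbreeding(ped)
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", x$n, "animals,",
      sum(x$sire == 0L & x$dam == 0L), "founders, mean F =",
      format(mean(x$F), digits = 4), "\n")
  invisible(x)
}

#' Inbreeding coefficients by the recursive tabular identity
#'
#' F of an animal equals half the additive relationship between its parents;
#' computed by the Meuwissen–Luo style recursion over Mendelian-sampling
#' variances, exact for any pedigree.
#'
#' @param ped a [renumber_pedigree()] pedigree.
#' @return numeric vector of inbreeding coefficients, one per animal.
#' @export
compute_inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  F <- .ml_inbreeding(ped$sire, ped$dam)
  names(F) <- ped$labels
  F
}

#' Numerator relationship matrix A (tabular method)
#'
#' @param ped a pedigree.
#' @param subset optional character vector of labels: return the block of A
#'   for these animals (built on the full pedigree, then restricted).
#' @return dense symmetric matrix with dimnames = animal labels.
#' @export
build_A <- function(ped, subset = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  A <- .tabular_A(ped$sire, ped$dam)
  dimnames(A) <- list(ped$labels, ped$labels)
  if (!is.null(subset)) {
    miss <- setdiff(subset, ped$labels)
    if (length(miss))
      stop("subset ids absent from pedigree: ", paste(miss, collapse = ", "))
    A <- A[subset, subset, drop = FALSE]
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' `1/b_i` to its diagonal and the usual -1/2, 1/4 patterns to parent
#' entries, where `b_i` is the Mendelian-sampling variance
#' (`0.5 - 0.25 (F_s + F_d)` with both parents known, `0.75 - 0.25 F_p`
#' with one, 1 with none).
#'
#' @param ped a pedigree (F is computed if absent).
#' @return sparse symmetric matrix (`Matrix::dsCMatrix`) with labels.
#' @export
build_A_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  F <- if (anyNA(ped$F)) compute_inbreeding(ped) else ped$F
  n <- ped$n
  s <- ped$sire; d <- ped$dam
  Fs <- ifelse(s > 0, F[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0, F[pmax(d, 1L)], 0)
  b <- 1 - 0.25 * ((s > 0) * (1 + Fs) + (d > 0) * (1 + Fd))
  al <- 1 / b
  i <- seq_len(n)
  ii <- c(i); jj <- c(i); xx <- c(al)                       # animal diagonal
  ks <- which(s > 0)
  ii <- c(ii, ks, s[ks]); jj <- c(jj, s[ks], s[ks])
  xx <- c(xx, -0.5 * al[ks], 0.25 * al[ks])
  kd <- which(d > 0)
  ii <- c(ii, kd, d[kd]); jj <- c(jj, d[kd], d[kd])
  xx <- c(xx, -0.5 * al[kd], 0.25 * al[kd])
  kb <- which(s > 0 & d > 0)
  lo <- pmin(s[kb], d[kb]); hi <- pmax(s[kb], d[kb])
  ii <- c(ii, hi); jj <- c(jj, lo)           # (s,d) quarter, lower triangle
  xx <- c(xx, 0.25 * al[kb])
  keep <- ii >= jj
  Ainv <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                               dims = c(n, n), symmetric = TRUE)
  dimnames(Ainv) <- list(ped$labels, ped$labels)
  Ainv
}

#' Pedigree relationship block for genotyped animals and its inverse
#'
#' @param ped a pedigree.
#' @param genotyped character labels of genotyped animals.
#' @return list with `A22` (dense) and `A22_inv` (dense).
#' @export
build_A22 <- function(ped, genotyped) {
  A22 <- build_A(ped, subset = genotyped)
  A22_inv <- chol2inv(chol(A22))
  dimnames(A22_inv) <- dimnames(A22)
  list(A22 = A22, A22_inv = A22_inv)
}

#' Read a pedigree CSV (columns animal, sire, dam; "0" or empty = unknown)
#' @param path file path.
#' @return a [renumber_pedigree()] pedigree.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  names(df) <- tolower(names(df))
  renumber_pedigree(df)
}

#' Write a pedigree to CSV in the dialect read by [read_pedigree()]
#' @param ped pedigree object.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  df <- data.frame(
    animal = ped$labels,
    sire = ifelse(ped$sire > 0, ped$labels[pmax(ped$sire, 1L)], "0"),
    dam  = ifelse(ped$dam > 0,  ped$labels[pmax(ped$dam, 1L)],  "0"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
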