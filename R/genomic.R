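#' Construct a genotype-matrix object
#'
#' @param M animals x SNPs matrix of gene contents in {0,1,2}, `NA` = missing;
#'   rownames = animal ids, colnames = SNP ids.
#' @param map data.frame with columns `snp`, `chrom`, `pos` (bp). Reordered to
#'   (chrom, pos); the genotype columns follow the map order.
#' @return object of class `geno` : list(ids, snp, map, M).
#' @export
geno_matrix <- function(M, map) {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)),
            all(c("snp", "chrom", "pos") %in% names(map)))
  map <- map[order(map$chrom, map$pos), , drop = FALSE]
  stopifnot(setequal(map$snp, colnames(M)))
  M <- M[, as.character(map$snp), drop = FALSE]
  bad <- !(M %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("gene contents must be 0/1/2 or missing")
  structure(list(ids = rownames(M), snp = as.character(map$snp),
                 map = map, M = M), class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat("Genotypes:", length(x$ids), "animals x", length(x$snp), "SNPs on",
      length(unique(x$map$chrom)), "chromosomes;",
      format(100 * mean(is.na(x$M)), digits = 3), "% missing\n")
  invisible(x)
}

#' Genotype quality control
#'
#' Removes SNPs with per-SNP call rate below `call_rate_min`, minor-allele
#' frequency (on observed calls) below `maf_min`, and monomorphic SNPs
#' (always removed). Animals are never dropped.
#'
#' @param g a [geno_matrix()] object.
#' @param call_rate_min minimum fraction of non-missing calls (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @return list(geno = filtered object, report = data.frame of counts).
#' @export
qc_filter <- function(g, call_rate_min = 0.90, maf_min = 0.01) {
  stopifnot(inherits(g, "geno"))
  cr <- colMeans(!is.na(g$M))
  p <- colMeans(g$M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail_cr <- cr < call_rate_min
  fail_maf <- !fail_cr & maf < maf_min
  fail_mono <- !fail_cr & !fail_maf & (is.na(maf) | maf == 0)
  keep <- !(fail_cr | fail_maf | fail_mono)
  if (!any(keep)) stop("no SNPs survive quality control")
  report <- data.frame(
    criterion = c("input", "call_rate", "maf", "monomorphic", "retained"),
    n = c(length(keep), sum(fail_cr), sum(fail_maf), sum(fail_mono), sum(keep)))
  gq <- geno_matrix(g$M[, keep, drop = FALSE],
                    g$map[g$map$snp %in% g$snp[keep], , drop = FALSE])
  list(geno = gq, report = report)
}

#' Base-population allele frequencies (gene-content GLS)
#'
#' Per SNP, treats observed gene contents as repeated measurements of twice
#' the base allele frequency with covariance proportional to the pedigree
#' relationship among genotyped animals, and solves the generalised least
#' squares estimate `2 p = (1' A22^-1 m) / (1' A22^-1 1)` — the limiting
#' (variance-ratio -> 0) fixed-effect solution of the gene-content mixed
#' model. SNPs with missing calls use the inverse of the observed-animal
#' block of A22.
#'
#' @param g a [geno_matrix()] object.
#' @param A22_inv dense inverse of A22 for the genotyped animals (rows of `g`).
#' @param A22 dense A22, required only when some calls are missing.
#' @param clamp frequencies are clamped to this range (default c(0.01, 0.99)).
#' @return numeric vector of base allele frequencies, one per SNP.
#' @export
estimate_base_frequencies <- function(g, A22_inv, A22 = NULL,
                                      clamp = c(0.01, 0.99)) {
  stopifnot(inherits(g, "geno"))
  M <- g$M
  n <- nrow(M)
  stopifnot(nrow(A22_inv) == n)
  w <- rowSums(A22_inv)                     # 1' A22^-1
  denom <- sum(w)
  if (!is.finite(denom) || denom <= 0) stop("A22 looks singular; jitter it")
  p <- numeric(ncol(M))
  complete <- !colAnyNA(M)
  if (any(complete))
    p[complete] <- as.numeric(w %*% M[, complete, drop = FALSE]) / (2 * denom)
  if (any(!complete)) {
    if (is.null(A22)) stop("A22 needed to handle missing genotypes")
    patterns <- apply(!is.na(M[, !complete, drop = FALSE]), 2, paste0, collapse = "")
    for (pat in unique(patterns)) {
      obs <- strsplit(pat, "")[[1]] == "TRUE"
      Ai <- chol2inv(chol(A22[obs, obs, drop = FALSE]))
      wo <- rowSums(Ai); dn <- sum(wo)
      cols <- which(!complete)[patterns == pat]
      p[cols] <- as.numeric(wo %*% M[obs, cols, drop = FALSE]) / (2 * dn)
    }
  }
  names(p) <- g$snp
  pmin(pmax(p, clamp[1]), clamp[2])
}

colAnyNA <- function(M) colSums(is.na(M)) > 0L

#' VanRaden genomic relationship matrix with SNP weights
#'
#' `G = Z D Z' / (2 sum_i d_i p_i (1 - p_i))` with `Z` the gene contents
#' centred by twice the base allele frequencies and `D = diag(d)`. The
#' weighted denominator keeps the trace scale comparable as SNP weights
#' change across weighted-ssGBLUP iterations. Missing gene contents are
#' imputed to `2 p` (zero after centring).
#'
#' @param g a QC'd [geno_matrix()] object.
#' @param p base allele frequencies (per SNP, in map order).
#' @param d positive SNP weights (default all 1).
#' @return list(G, Z, p, d, lambda) where `lambda = 1/(2 sum d p (1-p))` is
#'   the SNP-to-genomic variance ratio used when backsolving SNP effects.
#' @export
build_G <- function(g, p, d = rep(1, length(p))) {
  stopifnot(inherits(g, "geno"), length(p) == ncol(g$M), all(d > 0))
  M <- g$M
  if (any(colMeans(is.na(M)) == 1)) stop("all-missing SNP present; run qc_filter")
  Z <- sweep(M, 2, 2 * p)
  Z[is.na(Z)] <- 0
  den <- 2 * sum(d * p * (1 - p))
  G <- tcrossprod(sweep(Z, 2, d, `*`), Z) / den
  dimnames(G) <- list(g$ids, g$ids)
  list(G = G, Z = Z, p = p, d = d, lambda = 1 / den)
}

#' Blend the genomic relationship matrix towards its pedigree counterpart
#'
#' `G = (1 - tau) G0 + tau A22`, the standard ridge used to keep G invertible
#' when near-duplicate genotypes (many full sibs) make it singular. `tau = 0`
#' returns G0 unchanged.
#'
#' @param G0 raw genomic relationship matrix.
#' @param A22 pedigree relationships of the genotyped animals.
#' @param tau blending weight in `[0, 1)`, default 0.05.
#' @export
blend_G <- function(G0, A22, tau = 0.05) {
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0 || tau >= 1)
    stop("tau must lie in [0, 1)")
  stopifnot(all(dim(G0) == dim(A22)))
  if (tau == 0) return(G0)
  (1 - tau) * G0 + tau * A22
}

#' Single-step relationship inverse H^-1
#'
#' `H^-1 = A^-1` plus `(G^-1 - A22^-1)` added into the genotyped block.
#'
#' @param A_inv sparse pedigree relationship inverse.
#' @param G_inv dense inverse of the (blended) genomic relationship matrix.
#' @param A22_inv dense inverse of the genotyped pedigree block.
#' @param genotyped_index integer positions of the genotyped animals within
#'   the pedigree ordering of `A_inv` (in the row order of `G_inv`).
#' @return sparse symmetric matrix.
#' @export
build_H_inverse <- function(A_inv, G_inv = NULL, A22_inv = NULL,
                            genotyped_index = integer(0)) {
  if (length(genotyped_index) == 0) return(A_inv)
  stopifnot(!is.null(G_inv), !is.null(A22_inv),
            all(dim(G_inv) == length(genotyped_index)),
            all(dim(A22_inv) == length(genotyped_index)))
  corr <- G_inv - A22_inv
  if (all(corr == 0)) return(A_inv)
  n <- nrow(A_inv)
  ng <- length(genotyped_index)
  idx <- cbind(rep(genotyped_index, ng), rep(genotyped_index, each = ng))
  low <- idx[, 1] >= idx[, 2]
  S <- Matrix::sparseMatrix(i = idx[low, 1], j = idx[low, 2],
                            x = as.numeric(corr)[low],
                            dims = c(n, n), symmetric = TRUE)
  out <- methods::as(A_inv + S, "symmetricMatrix")
  dimnames(out) <- dimnames(A_inv)
  out
}
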