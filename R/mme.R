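#' Specify the multiple-trait animal model
#'
#' Each trait gets its own fixed-effect formula (one-sided); the random part
#' is always an additive animal effect (via `A^-1` or `H^-1`) and, optionally,
#' a full-sib family effect.
#'
#' @param traits character vector of trait column names (1 or 2).
#' @param fixed named list of one-sided formulas, one per trait, e.g.
#'   `list(fy = ~ age + line + harvest_year:harvest_group)`.
#' @param family include the full-sib family random effect (default TRUE).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(traits, fixed, family = TRUE) {
  stopifnot(length(traits) >= 1, length(traits) <= 2,
            all(traits %in% names(fixed)))
  structure(list(traits = traits, fixed = fixed[traits], family = family),
            class = "model_spec")
}

#' Two-trait model of the fillet-yield / body-weight evaluation
#'
#' Fillet yield: harvest age covariate, line, and the harvest-year x
#' slaughter-group interaction. Body weight: age covariate, line, hatch year.
#' Both traits carry animal and full-sib family random effects.
#' @export
trout_model_spec <- function() {
  model_spec(
    traits = c("fy", "bw"),
    fixed = list(fy = ~ age + line + harvest_year:harvest_group,
                 bw = ~ age + line + hatch_year),
    family = TRUE)
}

#' Variance-component container
#' @param Su,Sf,Se trait x trait covariance matrices for the additive,
#'   family and residual effects (`Sf = NULL` for models without the family
#'   term).
#' @export
vc_components <- function(Su, Sf = NULL, Se) {
  Su <- as.matrix(Su); Se <- as.matrix(Se)
  if (!is.null(Sf)) Sf <- as.matrix(Sf)
  for (S in Filter(Negate(is.null), list(Su, Sf, Se)))
    if (any(abs(S - t(S)) > 1e-10)) stop("variance components must be symmetric")
  structure(list(Su = Su, Sf = Sf, Se = Se), class = "vc_components")
}

# Full-rank fixed-effect design. Terms are built as full indicator sets
# (every level of a factor or factor interaction, times any numeric parts),
# then reduced to full column rank by pivoted QR on the rows where the trait
# is recorded. This keeps single-level factors and interaction-only terms
# valid and makes the dropped-level choice deterministic (intercept and
# earlier terms/levels win).
fixed_design <- function(formula, data, rows = seq_len(nrow(data))) {
  tt <- stats::terms(formula)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  labs <- attr(tt, "term.labels")
  cols <- list()
  if (attr(tt, "intercept") == 1)
    cols[["(Intercept)"]] <- matrix(1, nrow(data), 1,
                                    dimnames = list(NULL, "(Intercept)"))
  for (lab in labs) {
    vars <- strsplit(lab, ":", fixed = TRUE)[[1]]
    vals <- mf[vars]
    is_fac <- vapply(vals, function(v) is.character(v) || is.factor(v),
                     logical(1))
    num <- if (any(!is_fac))
      Reduce(`*`, lapply(vals[!is_fac], as.numeric)) else NULL
    if (any(is_fac)) {
      fac <- interaction(lapply(vals[is_fac], as.factor),
                         drop = TRUE, sep = ":", lex.order = TRUE)
      Ind <- matrix(0, nrow(data), nlevels(fac),
                    dimnames = list(NULL, paste0(lab, levels(fac))))
      okr <- which(!is.na(fac))
      Ind[cbind(okr, as.integer(fac)[okr])] <- 1
      if (!is.null(num)) Ind <- Ind * num
      cols[[lab]] <- Ind
    } else {
      cols[[lab]] <- matrix(num, ncol = 1, dimnames = list(NULL, lab))
    }
  }
  X <- do.call(cbind, cols)
  qrx <- qr(X[rows, , drop = FALSE])
  if (qrx$rank < ncol(X)) {
    keep <- sort(qrx$pivot[seq_len(qrx$rank)])
    X <- X[, keep, drop = FALSE]
  }
  X
}

#' Build the structural (variance-free) part of the mixed model equations
#'
#' Precomputes designs, incidence and indexing so that the coefficient matrix
#' can be re-assembled cheaply for new variance components (REML iterations,
#' weighted-G updates).
#'
#' @param spec a [model_spec()].
#' @param data data.frame with columns `animal`, `family` (if the family
#'   effect is in the model), the fixed-effect variables, and one column per
#'   trait (NA = trait not recorded).
#' @param K_inv sparse additive relationship inverse (`A^-1` or `H^-1`) whose
#'   dimnames define the animal ordering.
#' @return object of class `mme_structure`.
#' @export
mme_structure <- function(spec, data, K_inv) {
  stopifnot(inherits(spec, "model_spec"))
  traits <- spec$traits; T <- length(traits)
  labels <- rownames(K_inv)
  anim_idx <- match(as.character(data$animal), labels)
  if (anyNA(anim_idx))
    stop("animals absent from pedigree: ",
         paste(unique(data$animal[is.na(anim_idx)]), collapse = ", "))
  n_ped <- nrow(K_inv)
  if (spec$family) {
    fam_levels <- unique(as.character(data$family))
    fam_idx <- match(as.character(data$family), fam_levels)
    n_fam <- length(fam_levels)
  } else {
    fam_levels <- character(0); fam_idx <- NULL; n_fam <- 0L
  }
  Y <- as.matrix(data[, traits, drop = FALSE])
  obs <- !is.na(Y)
  X <- lapply(seq_len(T), function(t)
    fixed_design(spec$fixed[[t]], data, rows = which(obs[, t])))
  names(X) <- traits
  p <- vapply(X, ncol, integer(1))
  off_b <- cumsum(c(0, p))[seq_len(T)]
  off_u <- sum(p) + (seq_len(T) - 1L) * n_ped
  off_f <- sum(p) + T * n_ped + (seq_len(T) - 1L) * n_fam
  n_eq <- sum(p) + T * n_ped + T * n_fam
  # long rows: trait-major stacking of observed records
  idx_long <- matrix(NA_integer_, nrow(data), T)
  rows_i <- integer(0); rows_j <- integer(0); rows_x <- numeric(0)
  cur <- 0L
  long_rec <- integer(0); long_trait <- integer(0)
  for (t in seq_len(T)) {
    r <- which(obs[, t])
    idx_long[r, t] <- cur + seq_along(r)
    long_rec <- c(long_rec, r); long_trait <- c(long_trait, rep(t, length(r)))
    nt <- length(r)
    Xt <- X[[t]][r, , drop = FALSE]
    rows_i <- c(rows_i, rep(cur + seq_len(nt), times = p[t]),
                cur + seq_len(nt),
                if (spec$family) cur + seq_len(nt))
    rows_j <- c(rows_j, rep(off_b[t] + seq_len(p[t]), each = nt),
                off_u[t] + anim_idx[r],
                if (spec$family) off_f[t] + fam_idx[r])
    rows_x <- c(rows_x, as.numeric(Xt),
                rep(1, nt), if (spec$family) rep(1, nt))
    cur <- cur + nt
  }
  keep <- rows_x != 0
  W <- Matrix::sparseMatrix(i = rows_i[keep], j = rows_j[keep],
                            x = rows_x[keep], dims = c(cur, n_eq))
  y_long <- Y[cbind(long_rec, long_trait)]
  # record residual patterns: integer code over traits observed
  pat_code <- as.integer(obs %*% (2 ^ (seq_len(T) - 1)))
  structure(list(
    spec = spec, traits = traits, T = T, n_rec = nrow(data),
    labels = labels, n_ped = n_ped, K_inv = K_inv,
    fam_levels = fam_levels, fam_idx = fam_idx, n_fam = n_fam,
    X = X, p = p, off_b = off_b, off_u = off_u, off_f = off_f, n_eq = n_eq,
    anim_idx = anim_idx, obs = obs, Y = Y,
    W = W, y_long = y_long, n_long = cur,
    idx_long = idx_long, long_rec = long_rec, long_trait = long_trait,
    pat_code = pat_code), class = "mme_structure")
}

# residual inverse (and optionally a derivative pattern matrix) on long rows
residual_long <- function(str, Smat) {
  Ts <- str$T
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (code in unique(str$pat_code)) {
    if (code == 0L) next
    P <- which(bitwAnd(code, 2 ^ (seq_len(Ts) - 1L)) > 0L)
    recs <- which(str$pat_code == code)
    Sp <- Smat[P, P, drop = FALSE]
    for (a in seq_along(P)) for (b in seq_along(P)) {
      v <- Sp[a, b]
      if (v == 0) next
      ii <- c(ii, str$idx_long[recs, P[a]])
      jj <- c(jj, str$idx_long[recs, P[b]])
      xx <- c(xx, rep(v, length(recs)))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(str$n_long, str$n_long))
}

rinv_long <- function(str, Se) {
  Ts <- str$T
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (code in unique(str$pat_code)) {
    if (code == 0L) next
    P <- which(bitwAnd(code, 2 ^ (seq_len(Ts) - 1L)) > 0L)
    recs <- which(str$pat_code == code)
    E <- solve(Se[P, P, drop = FALSE])
    for (a in seq_along(P)) for (b in seq_along(P)) {
      ii <- c(ii, str$idx_long[recs, P[a]])
      jj <- c(jj, str$idx_long[recs, P[b]])
      xx <- c(xx, rep(E[a, b], length(recs)))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(str$n_long, str$n_long))
}

#' Assemble the mixed model equations for given variance components
#'
#' @param str a [mme_structure()].
#' @param vc a [vc_components()] whose dimensions match the model's traits.
#' @return list with the symmetric sparse coefficient matrix `C`, right-hand
#'   side `rhs`, the residual inverse on record space, and bookkeeping.
#' @export
build_mme <- function(str, vc) {
  stopifnot(inherits(str, "mme_structure"), inherits(vc, "vc_components"))
  Ts <- str$T
  for (S in Filter(Negate(is.null), list(vc$Su, vc$Sf, vc$Se)))
    if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
      stop("variance component matrix is not positive semi-definite")
  Rinv <- rinv_long(str, vc$Se)
  WtR <- Matrix::crossprod(str$W, Rinv)
  Cdata <- WtR %*% str$W
  rhs <- as.numeric(WtR %*% str$y_long)
  Su_inv <- solve(vc$Su)
  blocks <- list(Matrix::Diagonal(sum(str$p), 0),
                 Matrix::kronecker(Su_inv, str$K_inv))
  if (str$spec$family && str$n_fam > 0) {
    Sf_inv <- solve(vc$Sf)
    blocks <- c(blocks, list(Matrix::kronecker(Sf_inv,
                                               Matrix::Diagonal(str$n_fam))))
  }
  C <- Matrix::forceSymmetric(Cdata + Matrix::bdiag(blocks), uplo = "L")
  list(C = C, rhs = rhs, Rinv = Rinv, str = str, vc = vc)
}

#' Solve assembled mixed model equations
#'
#' Direct simplicial sparse Cholesky by default; optionally a
#' Jacobi-preconditioned conjugate-gradient solver.
#'
#' @param sys output of [build_mme()].
#' @param method "direct" or "cg".
#' @param tol,maxit conjugate-gradient stopping rule (relative residual).
#' @return object of class `blup_solutions` : fixed effects `b` (list per
#'   trait), breeding values `u` (animals x traits), family effects `f`,
#'   the record-level fixed+family fitted parts, and the Cholesky factor.
#' @export
solve_mme <- function(sys, method = c("direct", "cg"), tol = 1e-10,
                      maxit = 10000L) {
  method <- match.arg(method)
  str <- sys$str
  if (method == "direct") {
    ch <- Matrix::Cholesky(sys$C, LDL = TRUE, super = FALSE, perm = TRUE)
    sol <- as.numeric(Matrix::solve(ch, sys$rhs))
  } else {
    ch <- NULL
    sol <- cg_solve(sys$C, sys$rhs, tol = tol, maxit = maxit)
  }
  shape_solutions(str, sol, ch)
}

shape_solutions <- function(str, sol, ch = NULL) {
  Ts <- str$T
  b <- lapply(seq_len(Ts), function(t)
    stats::setNames(sol[str$off_b[t] + seq_len(str$p[t])],
                    colnames(str$X[[t]])))
  names(b) <- str$traits
  u <- vapply(seq_len(Ts), function(t) sol[str$off_u[t] + seq_len(str$n_ped)],
              numeric(str$n_ped))
  dimnames(u) <- list(str$labels, str$traits)
  f <- NULL
  if (str$spec$family && str$n_fam > 0) {
    f <- vapply(seq_len(Ts), function(t) sol[str$off_f[t] + seq_len(str$n_fam)],
                numeric(str$n_fam))
    dimnames(f) <- list(str$fam_levels, str$traits)
  }
  fitted_fixed <- matrix(NA_real_, str$n_rec, Ts,
                         dimnames = list(NULL, str$traits))
  fitted_family <- matrix(NA_real_, str$n_rec, Ts,
                          dimnames = list(NULL, str$traits))
  for (t in seq_len(Ts)) {
    fitted_fixed[, t] <- as.numeric(str$X[[t]] %*% b[[t]])
    fitted_family[, t] <- if (is.null(f)) 0 else f[str$fam_idx, t]
  }
  structure(list(b = b, u = u, f = f, sol = sol,
                 fitted_fixed = fitted_fixed, fitted_family = fitted_family,
                 chol = ch, str = str), class = "blup_solutions")
}

cg_solve <- function(C, rhs, tol = 1e-10, maxit = 10000L) {
  n <- length(rhs)
  x <- numeric(n)
  r <- rhs
  Minv <- 1 / Matrix::diag(C)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(rhs^2))
  for (it in seq_len(maxit)) {
    Cp <- as.numeric(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    if (sqrt(sum(r^2)) <= tol * nb) return(x)
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("conjugate gradient did not converge; relative residual ",
       format(sqrt(sum(r^2)) / nb))
}

#' Adjust phenotypes for estimated fixed and family effects
#'
#' `y* = y - X b - Z2 f` per record and trait; the benchmark used by the
#' forward validation on adjusted phenotypes.
#'
#' @param fit a [solve_mme()] result from the whole-data pedigree run.
#' @return matrix of adjusted records (NA where the trait was not recorded),
#'   rows aligned with the data used to build the MME.
#' @export
adjust_phenotypes <- function(fit) {
  stopifnot(inherits(fit, "blup_solutions"))
  str <- fit$str
  ystar <- str$Y - fit$fitted_fixed - fit$fitted_family
  ystar[!str$obs] <- NA_real_
  rownames(ystar) <- as.character(str$labels[str$anim_idx])
  ystar
}
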