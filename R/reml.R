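# ---- restricted log-likelihood and selected-inverse helpers ----------------

# selected inverse of the MME coefficient matrix on the pattern of its
# Cholesky factor; returns a closure that looks entries up by (row, col)
selected_inverse <- function(ch) {
  ex <- Matrix::expand(ch)
  L <- methods::as(ex$L, "CsparseMatrix")
  Zx <- .takahashi_selinv(L@p, L@i, L@x)
  perm_pos <- integer(ncol(L))
  perm_pos[ch@perm + 1L] <- seq_len(ncol(L)) # original index -> factor position
  list(
    lookup = function(rows, cols) {
      .selinv_lookup(L@p, L@i, Zx, perm_pos[rows] - 1L, perm_pos[cols] - 1L)
    })
}

# -2 * restricted log-likelihood, up to a constant not depending on the
# variance components (the log|K| and n*log(2*pi) terms)
reml_m2ll <- function(sys, ch, sol) {
  str <- sys$str; vc <- sys$vc
  ldC <- as.numeric(Matrix::determinant(ch, sqrt = FALSE)$modulus)
  ldR <- 0
  for (code in unique(str$pat_code)) {
    if (code == 0L) next
    P <- which(bitwAnd(code, 2 ^ (seq_len(str$T) - 1L)) > 0L)
    ldR <- ldR + sum(str$pat_code == code) *
      as.numeric(determinant(vc$Se[P, P, drop = FALSE])$modulus)
  }
  ldG <- str$n_ped * as.numeric(determinant(vc$Su)$modulus)
  if (str$spec$family && str$n_fam > 0)
    ldG <- ldG + str$n_fam * as.numeric(determinant(vc$Sf)$modulus)
  yPy <- sum(str$y_long * as.numeric(sys$Rinv %*% str$y_long)) -
    sum(sol * sys$rhs)
  ldC + ldR + ldG + yPy
}

# parameter <-> matrix packing: one row per free element (component, i, j)
vc_param_table <- function(Ts, family, free_cov_e) {
  comp <- c(rep("u", Ts * (Ts + 1) / 2),
            if (family) rep("f", Ts * (Ts + 1) / 2),
            rep("e", Ts * (Ts + 1) / 2))
  ij <- which(upper.tri(diag(Ts), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 2], ij[, 1]), , drop = FALSE]
  tab <- data.frame(comp = comp,
                    i = rep(ij[, 1], length.out = length(comp)),
                    j = rep(ij[, 2], length.out = length(comp)))
  if (!free_cov_e) tab <- tab[!(tab$comp == "e" & tab$i != tab$j), ]
  tab
}

vc_pack <- function(vc, tab) {
  S <- list(u = vc$Su, f = vc$Sf, e = vc$Se)
  vapply(seq_len(nrow(tab)), function(k)
    S[[tab$comp[k]]][tab$i[k], tab$j[k]], numeric(1))
}

vc_unpack <- function(theta, tab, template) {
  S <- list(u = template$Su, f = template$Sf, e = template$Se)
  for (k in seq_len(nrow(tab))) {
    S[[tab$comp[k]]][tab$i[k], tab$j[k]] <- theta[k]
    S[[tab$comp[k]]][tab$j[k], tab$i[k]] <- theta[k]
  }
  vc_components(Su = S$u, Sf = S$f, Se = S$e)
}

vc_is_pd <- function(vc, family) {
  ok <- function(S) !is.null(S) &&
    min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0
  ok(vc$Su) && ok(vc$Se) && (!family || ok(vc$Sf))
}

# project an update onto the interior of the parameter space: variances that
# collapsed to (or crossed) zero are pinned at a tiny fraction of the total
# trait variance, correlations are clipped to |r| <= 0.999; this is the
# standard boundary treatment that keeps Newton-type REML from crawling when
# a component is effectively zero
vc_project <- function(vc, floor_frac = 1e-8) {
  mats <- Filter(Negate(is.null), list(vc$Su, vc$Sf, vc$Se))
  scale_t <- Reduce(`+`, lapply(mats, function(S) abs(diag(S))))
  fix <- function(S) {
    if (is.null(S)) return(NULL)
    d <- pmax(diag(S), floor_frac * scale_t)
    out <- S; diag(out) <- d
    for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) if (i != j) {
      lim <- 0.999 * sqrt(d[i] * d[j])
      out[i, j] <- sign(S[i, j]) * min(abs(S[i, j]), lim)
    }
    out
  }
  vc_components(fix(vc$Su), fix(vc$Sf), fix(vc$Se))
}

# ---- AI-REML ----------------------------------------------------------------

#' Estimate variance components by average-information REML
#'
#' Two-trait (or single-trait) animal model with an optional full-sib family
#' effect. First derivatives of the restricted likelihood use exact trace
#' terms computed from a Takahashi selected inverse of the sparse Cholesky
#' factor of the coefficient matrix; the average-information matrix is built
#' from working variates (one extra sparse solve per free parameter).
#' When an AI update leaves the positive-definite cone the step is halved,
#' and if still invalid the additive and family matrices fall back to their
#' closed-form expectation-maximisation update. Standard errors come from the
#' inverse of the AI matrix at convergence.
#'
#' @param spec a [model_spec()].
#' @param data records data.frame (see [mme_structure()]).
#' @param K_inv sparse relationship inverse defining the animal ordering
#'   (`A^-1` for the pedigree-only analysis).
#' @param start starting [vc_components()].
#' @param free_cov_e estimate the residual covariance between traits
#'   (default TRUE when records observed for both traits exist).
#' @param tol convergence: relative norm of the parameter change < `tol`.
#' @param max_iter iteration cap; non-convergence is flagged, not fatal.
#' @param verbose print per-iteration likelihood and criteria.
#' @return list with `vc` (estimates), `se` (same layout), `ai`, `ai_inv`,
#'   `converged`, `iterations`, `m2ll`, `trace` (per-iteration data.frame),
#'   and the final inner fit (`fit`).
#' @export
estimate_vc_aireml <- function(spec, data, K_inv, start,
                               free_cov_e = NULL, tol = 1e-8,
                               max_iter = 200L, verbose = FALSE) {
  str <- mme_structure(spec, data, K_inv)
  Ts <- str$T
  nm <- list(str$traits, str$traits)
  start$Su <- structure(start$Su, dimnames = nm)
  start$Se <- structure(start$Se, dimnames = nm)
  if (!is.null(start$Sf)) start$Sf <- structure(start$Sf, dimnames = nm)
  n_both <- if (Ts == 2) sum(rowSums(str$obs) == 2) else 0L
  if (is.null(free_cov_e)) free_cov_e <- Ts == 2 && n_both >= 2
  tab <- vc_param_table(Ts, str$spec$family, free_cov_e)
  vc <- start
  if (!vc_is_pd(vc, str$spec$family)) stop("start values must be positive definite")
  theta <- vc_pack(vc, tab)
  np <- nrow(tab)
  is_diag <- tab$i == tab$j
  trace_df <- NULL
  converged <- FALSE
  last <- NULL
  # active-set boundary handling: variances whose AI update crosses zero are
  # pinned at a small fixed floor and excluded from later updates until the
  # gradient points back into the interior; covariances of a pinned trait
  # within the same component are pinned at zero
  pinned <- rep(FALSE, np)
  pin_val <- numeric(np)
  floor_of <- function(th) {
    # per (component, trait) floor: a tiny fraction of the trait's total variance
    scale_t <- numeric(max(tab$i))
    for (t in seq_along(scale_t))
      scale_t[t] <- sum(abs(th[is_diag & tab$i == t]))
    1e-8 * scale_t
  }
  cov_partners <- function(k) which(tab$comp == tab$comp[k] & !is_diag &
                                      (tab$i == tab$i[k] | tab$j == tab$i[k]))
  for (it in seq_len(max_iter)) {
    last <- reml_iteration(str, vc, tab)
    g <- last$gradient; AI <- last$AI
    # release pinned variances when the likelihood wants them positive again
    release <- pinned & is_diag & g > 0
    if (any(release)) {
      pinned[release] <- FALSE
      for (k in which(release)) pinned[cov_partners(k)] <- FALSE
    }
    free <- !pinned
    step <- numeric(np)
    Af <- AI[free, free, drop = FALSE]
    step[free] <- tryCatch(solve(Af, g[free]), error = function(e)
      solve(Af + diag(1e-8 * max(abs(diag(Af))), nrow(Af)), g[free]))
    prop <- theta + step
    prop[pinned] <- pin_val[pinned]
    cand <- vc_unpack(prop, tab, vc)
    if (!vc_is_pd(cand, str$spec$family)) {
      flo <- floor_of(theta)
      newly <- which(is_diag & !pinned & prop <= flo[tab$i])
      for (k in newly) {
        pinned[k] <- TRUE; pin_val[k] <- flo[tab$i[k]]
        prop[k] <- pin_val[k]
        for (k2 in cov_partners(k)) {
          pinned[k2] <- TRUE; pin_val[k2] <- 0; prop[k2] <- 0
        }
      }
      # clip any remaining out-of-range covariances (not pinned: free to move)
      for (k in which(!is_diag & !pinned)) {
        rows <- tab$comp == tab$comp[k] & is_diag
        d_i <- prop[which(rows & tab$i == tab$i[k])]
        d_j <- prop[which(rows & tab$i == tab$j[k])]
        lim <- 0.999 * sqrt(max(d_i, 0) * max(d_j, 0))
        prop[k] <- sign(prop[k]) * min(abs(prop[k]), lim)
      }
      cand <- vc_unpack(prop, tab, vc)
      if (!vc_is_pd(cand, str$spec$family)) {
        # EM fallback for the additive/family matrices, current Se retained
        cand <- vc
        cand$Su <- (last$Q_u + last$W_u) / str$n_ped
        if (str$spec$family && str$n_fam > 0)
          cand$Sf <- (last$Q_f + last$W_f) / str$n_fam
        cand <- vc_components(cand$Su, cand$Sf, cand$Se)
        pinned[] <- FALSE
      }
    }
    theta_new <- vc_pack(cand, tab)
    crit <- sqrt(sum((theta_new - theta) ^ 2) / sum(theta_new ^ 2))
    if (verbose)
      message(sprintf("it %3d  -2logL = %.6f  crit = %.3e", it, last$m2ll, crit))
    trace_df <- rbind(trace_df,
                      data.frame(iter = it, m2ll = last$m2ll, crit = crit))
    vc <- cand; theta <- theta_new
    if (crit < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("AI-REML did not reach the convergence criterion in ",
            max_iter, " iterations; returning the final estimates")
  ai_inv <- tryCatch(solve(last$AI), error = function(e) NULL)
  se <- if (!is.null(ai_inv)) vc_unpack(sqrt(pmax(diag(ai_inv), 0)), tab,
                                        vc_zero_like(vc)) else NULL
  list(vc = vc, se = se, ai = last$AI, ai_inv = ai_inv,
       converged = converged, iterations = it, m2ll = last$m2ll,
       trace = trace_df, fit = last$fit, param_table = tab)
}

vc_zero_like <- function(vc) {
  z <- function(S) if (is.null(S)) NULL else S * 0
  vc_components(z(vc$Su), z(vc$Sf), z(vc$Se))
}

# one inner evaluation: solve MME, selected inverse, gradient and AI matrix
reml_iteration <- function(str, vc, tab) {
  sys <- build_mme(str, vc)
  ch <- Matrix::Cholesky(sys$C, LDL = TRUE, super = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(ch, sys$rhs))
  fit <- shape_solutions(str, sol, ch)
  m2ll <- reml_m2ll(sys, ch, sol)
  Ts <- str$T
  Py <- as.numeric(sys$Rinv %*% (str$y_long - as.numeric(str$W %*% sol)))
  sel <- selected_inverse(ch)

  # quadratic forms and selected-inverse trace matrices per random effect
  U <- fit$u
  Q_u <- crossprod(U, as.matrix(str$K_inv %*% U))
  Kt <- methods::as(methods::as(str$K_inv, "generalMatrix"), "TsparseMatrix")
  W_u <- matrix(0, Ts, Ts)
  for (a in seq_len(Ts)) for (b in a:Ts) {
    v <- sum(Kt@x * sel$lookup(str$off_u[a] + Kt@i + 1L,
                               str$off_u[b] + Kt@j + 1L))
    W_u[a, b] <- W_u[b, a] <- v
  }
  Q_f <- W_f <- NULL
  if (str$spec$family && str$n_fam > 0) {
    Q_f <- crossprod(fit$f)
    W_f <- matrix(0, Ts, Ts)
    ks <- seq_len(str$n_fam)
    for (a in seq_len(Ts)) for (b in a:Ts) {
      v <- sum(sel$lookup(str$off_f[a] + ks, str$off_f[b] + ks))
      W_f[a, b] <- W_f[b, a] <- v
    }
  }

  Su_inv <- solve(vc$Su)
  Sf_inv <- if (!is.null(vc$Sf)) solve(vc$Sf)
  Se_inv_pat <- list()

  Ebasis <- function(i, j, Ts) {
    E <- matrix(0, Ts, Ts); E[i, j] <- E[j, i] <- 1; E
  }

  np <- nrow(tab)
  Fmat <- matrix(0, str$n_long, np)   # working variates dV_k P y
  grad <- numeric(np)
  B <- sys$Rinv %*% str$W             # reused for residual trace matrices
  for (k in seq_len(np)) {
    i <- tab$i[k]; j <- tab$j[k]
    E <- Ebasis(i, j, Ts)
    if (tab$comp[k] == "u" || tab$comp[k] == "f") {
      if (tab$comp[k] == "u") {
        S_inv <- Su_inv; Wr <- W_u; Qr <- Q_u; q <- str$n_ped
        Ut <- U %*% (S_inv %*% E)
        lev <- str$anim_idx
      } else {
        S_inv <- Sf_inv; Wr <- W_f; Qr <- Q_f; q <- str$n_fam
        Ut <- fit$f %*% (S_inv %*% E)
        lev <- str$fam_idx
      }
      Fmat[, k] <- Ut[cbind(lev[str$long_rec], str$long_trait)]
      tr1 <- q * sum(E * S_inv)
      tr2 <- sum(E * (S_inv %*% Wr %*% S_inv))
      grad[k] <- -0.5 * (tr1 - tr2 - sum(Fmat[, k] * Py))
    } else {
      # residual element (i, j)
      tr1 <- 0
      for (code in unique(str$pat_code)) {
        if (code == 0L) next
        P <- which(bitwAnd(code, 2 ^ (seq_len(Ts) - 1L)) > 0L)
        if (!(i %in% P) || !(j %in% P)) next
        key <- as.character(code)
        if (is.null(Se_inv_pat[[key]]))
          Se_inv_pat[[key]] <- solve(vc$Se[P, P, drop = FALSE])
        tr1 <- tr1 + sum(str$pat_code == code) *
          sum(Se_inv_pat[[key]] * E[P, P, drop = FALSE])
      }
      dR <- residual_long(str, E)
      M <- methods::as(methods::as(Matrix::crossprod(B, dR %*% B),
                                   "generalMatrix"), "TsparseMatrix")
      tr2 <- sum(M@x * sel$lookup(M@i + 1L, M@j + 1L))
      Fmat[, k] <- as.numeric(dR %*% Py)
      grad[k] <- -0.5 * (tr1 - tr2 - sum(Fmat[, k] * Py))
    }
  }
  # AI matrix: 0.5 * F' P F with P f = Rinv (f - W C^-1 W' Rinv f)
  RF <- as.matrix(sys$Rinv %*% Fmat)
  TH <- Matrix::solve(ch, as.matrix(Matrix::crossprod(str$W, RF)))
  PF <- as.matrix(sys$Rinv %*% (Fmat - as.matrix(str$W %*% TH)))
  AI <- 0.5 * crossprod(Fmat, PF)
  AI <- (AI + t(AI)) / 2
  list(fit = fit, m2ll = m2ll, gradient = grad, AI = AI,
       Q_u = Q_u, W_u = W_u, Q_f = Q_f, W_f = W_f, Py = Py)
}

#' Heritabilities, family-variance fractions and the genetic correlation
#'
#' `h2_t = Su_tt / (Su_tt + Sf_tt + Se_tt)`, `f2_t = Sf_tt / sigma2_p,t`,
#' `r_g = Su_12 / sqrt(Su_11 Su_22)`; standard errors by the delta method
#' from the inverse AI matrix when available.
#'
#' @param reml an [estimate_vc_aireml()] result, or a bare [vc_components()].
#' @return data.frame with one row per parameter (estimate, se).
#' @export
compute_genetic_parameters <- function(reml) {
  if (inherits(reml, "vc_components")) reml <- list(vc = reml, ai_inv = NULL)
  vc <- reml$vc
  Ts <- ncol(vc$Su)
  trts <- colnames(vc$Su)
  if (is.null(trts)) trts <- as.character(seq_len(Ts))
  par_fun <- function(theta, tab) {
    v <- vc_unpack(theta, tab, vc)
    tot <- diag(v$Su) + (if (is.null(v$Sf)) 0 else diag(v$Sf)) + diag(v$Se)
    if (any(tot <= 0)) stop("zero total variance")
    out <- c(stats::setNames(diag(v$Su) / tot, paste0("h2.", trts)),
             if (!is.null(v$Sf))
               stats::setNames(diag(v$Sf) / tot, paste0("f2.", trts)))
    if (Ts == 2)
      out <- c(out, r_g = v$Su[1, 2] / sqrt(v$Su[1, 1] * v$Su[2, 2]))
    out
  }
  if (!is.null(reml$ai_inv) && !is.null(reml$param_table)) {
    tab <- reml$param_table
    theta <- vc_pack(vc, tab)
    est <- par_fun(theta, tab)
    J <- matrix(0, length(est), length(theta))
    for (k in seq_along(theta)) {
      hstep <- max(1e-6, 1e-6 * abs(theta[k]))
      up <- theta; up[k] <- up[k] + hstep
      dn <- theta; dn[k] <- dn[k] - hstep
      J[, k] <- (par_fun(up, tab) - par_fun(dn, tab)) / (2 * hstep)
    }
    V <- J %*% reml$ai_inv %*% t(J)
    se <- sqrt(pmax(diag(V), 0))
  } else {
    tab <- vc_param_table(Ts, !is.null(vc$Sf), TRUE)
    est <- par_fun(vc_pack(vc, tab), tab)
    se <- rep(NA_real_, length(est))
  }
  data.frame(parameter = names(est), estimate = unname(est), se = se)
}
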