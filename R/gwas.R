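#' Backsolve GEBVs of genotyped animals into SNP effects
#'
#' `a_hat = lambda D Z' G^-1 u_hat`, the exact BLUP inverse map of the
#' genomic relationship matrix construction, with
#' `lambda = 1 / (2 sum d_i p_i (1 - p_i))` matching the G denominator.
#' One trait at a time.
#'
#' @param u_hat_genotyped GEBVs of the genotyped animals (G row order).
#' @param G_inv inverse of the (blended) genomic relationship matrix.
#' @param Z centred gene-content matrix.
#' @param d SNP weights used when G was built.
#' @param lambda the SNP-to-genomic variance ratio of the G construction.
#' @return data.frame: snp, effect.
#' @export
backsolve_snp_effects <- function(u_hat_genotyped, G_inv, Z, d, lambda) {
  stopifnot(length(u_hat_genotyped) == nrow(Z), all(dim(G_inv) == nrow(Z)),
            length(d) == ncol(Z))
  a <- lambda * d * as.numeric(crossprod(Z, G_inv %*% u_hat_genotyped))
  data.frame(snp = colnames(Z), effect = a, row.names = NULL)
}

#' Per-SNP sampling variances, z-ratios and p-values
#'
#' `var(a_hat) = lambda^2 D Z' G^-1 Cov(u_hat_g) G^-1 Z D` with
#' `Cov(u_hat_g) = sigma2_u G - C^uu`, where `C^uu` is the genotyped block of
#' the inverse MME coefficient matrix for the trait. Two-sided normal
#' p-values `2 (1 - Phi(|a / SD(a)|))`.
#'
#' @param effects data.frame from [backsolve_snp_effects()].
#' @param G,G_inv the (blended) genomic relationship matrix and its inverse.
#' @param Z,d,lambda as in [backsolve_snp_effects()].
#' @param Cuu genotyped block of the inverse coefficient matrix for the trait.
#' @param sigma2_u additive genetic variance of the trait.
#' @return the effects data.frame with columns sd, z, p, neglog10p added.
#' @export
snp_pvalues <- function(effects, G, G_inv, Z, d, lambda, Cuu, sigma2_u) {
  Cov_u <- sigma2_u * G - Cuu
  GZ <- G_inv %*% Z
  v <- lambda^2 * d^2 * colSums(GZ * (Cov_u %*% GZ))
  neg <- v <= 0
  if (any(neg)) {
    warning(sum(neg), " SNP effect variance(s) <= 0 from numerical error; clipped")
    v[neg] <- .Machine$double.eps
  }
  effects$sd <- sqrt(v)
  effects$z <- effects$effect / effects$sd
  effects$p <- 2 * (1 - stats::pnorm(abs(effects$z)))
  effects$p <- pmax(effects$p, .Machine$double.xmin)
  effects$neglog10p <- -log10(effects$p)
  effects
}

#' Bonferroni display threshold on the -log10 scale
#'
#' @param n_snp number of tested SNPs.
#' @param alpha familywise error rate (default 0.05).
#' @return `-log10(alpha / n_snp)` (display convention: 1 decimal place).
#' @export
bonferroni_threshold <- function(n_snp, alpha = 0.05) {
  stopifnot(n_snp >= 1, alpha > 0, alpha < 1)
  -log10(alpha / n_snp)
}

#' Percentage of additive variance explained by SNP windows
#'
#' Sliding windows of `window_size` adjacent SNPs within each chromosome
#' (step 1). Per window, the variance across genotyped animals of the summed
#' marker contributions `sum_i z_i a_i`, as a percentage of the total
#' additive genetic variance.
#'
#' @param effects data.frame with per-SNP `effect` (map order).
#' @param Z centred gene contents (columns in map order).
#' @param map SNP map (snp, chrom, pos), same order as `Z` columns.
#' @param window_size number of adjacent SNPs per window (default 20).
#' @param total_genetic_variance denominator (REML additive variance).
#' @return data.frame: chrom, first_snp, last_snp, pct_variance.
#' @export
window_variance <- function(effects, Z, map, window_size = 20,
                            total_genetic_variance) {
  stopifnot(nrow(effects) == ncol(Z), nrow(map) == ncol(Z))
  out <- NULL
  for (chr in unique(map$chrom)) {
    cols <- which(map$chrom == chr)
    if (length(cols) < window_size) {
      warning("chromosome ", chr, " has fewer than ", window_size,
              " SNPs; using one truncated window")
      starts <- cols[1]; width <- length(cols)
    } else {
      starts <- cols[seq_len(length(cols) - window_size + 1)]
      width <- window_size
    }
    contrib <- sweep(Z[, cols, drop = FALSE], 2, effects$effect[cols], `*`)
    cs <- cbind(0, t(apply(contrib, 1, cumsum)))
    for (s in starts) {
      a <- s - cols[1] + 1
      g <- cs[, a + width] - cs[, a]
      out <- rbind(out, data.frame(
        chrom = chr, first_snp = map$snp[s], last_snp = map$snp[s + width - 1],
        pct_variance = 100 * stats::var(g) / total_genetic_variance))
    }
  }
  rownames(out) <- NULL
  out
}

#' Nonlinear-A SNP weights
#'
#' `d_i = CT ^ (|a_i| / sd(a) - 2)`, the departure-from-normality weighting;
#' the standardised effect is capped before exponentiation to keep weights
#' bounded. A zero effect spread yields unit weights.
#'
#' @param effects per-SNP effects (vector or the data.frame from
#'   [backsolve_snp_effects()]).
#' @param CT constant > 1 controlling the departure from normality.
#' @param cap ceiling on `|a| / sd(a)` (default 5).
#' @return vector of positive SNP weights.
#' @export
nonlinearA_weights <- function(effects, CT, cap = 5) {
  if (is.data.frame(effects)) effects <- effects$effect
  if (!is.numeric(CT) || CT <= 1) stop("CT must exceed 1")
  s <- stats::sd(effects)
  if (s == 0) return(rep(1, length(effects)))
  CT ^ (pmin(abs(effects) / s, cap) - 2)
}

#' Iterate weighted ssGBLUP
#'
#' Iteration 1 is the unweighted ssGBLUP (all SNP weights 1). Each following
#' iteration backsolves SNP effects one trait at a time, converts them to
#' nonlinear-A weights, renormalises the weights to mean 1, rebuilds G and
#' H^-1, re-solves the evaluation, and records validation statistics through
#' `validation_hook`.
#'
#' @param data,ped,vc,spec,geno,tau,base_freq as in [genetic_evaluation()].
#' @param CT nonlinear-A constant (> 1).
#' @param n_iter number of iterations (default 5).
#' @param trait trait whose effects drive the weights (default first trait).
#' @param validation_hook optional `function(fit, iter)` returning a
#'   validation report list for the iteration.
#' @return list with per-iteration `fits`, `effects`, `weights`, `validation`.
#' @export
wssgblup_iterate <- function(data, ped, vc, spec = trout_model_spec(),
                             geno, CT, n_iter = 5, trait = spec$traits[1],
                             tau = 0.05, base_freq = NULL,
                             validation_hook = NULL) {
  if (CT <= 1) stop("CT must exceed 1")
  t_idx <- match(trait, spec$traits)
  d <- NULL
  fits <- effects <- weights <- validation <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    fit <- genetic_evaluation(data, ped, vc, spec, geno = geno, weights = d,
                              tau = tau, base_freq = base_freq)
    if (is.null(base_freq)) base_freq <- fit$p
    u_g <- fit$u[fit$genotyped, t_idx]
    eff <- backsolve_snp_effects(u_g, fit$G_inv, fit$Z, fit$d, fit$lambda)
    d_new <- nonlinearA_weights(eff, CT)
    d_new <- d_new / mean(d_new)
    rep_it <- if (!is.null(validation_hook)) validation_hook(fit, it)
    if (!is.null(rep_it) && !is.null(rep_it$accuracy) && is.na(rep_it$accuracy)) {
      warning("validation accuracy undefined at iteration ", it,
              "; stopping with partial trace")
      fits[[it]] <- fit; effects[[it]] <- eff
      weights[[it]] <- fit$d; validation[[it]] <- rep_it
      break
    }
    fits[[it]] <- fit; effects[[it]] <- eff
    weights[[it]] <- fit$d; validation[[it]] <- rep_it
    d <- d_new
  }
  list(fits = fits, effects = effects, weights = weights,
       validation = validation, CT = CT, trait = trait)
}

#' Genotyped-animal block of the inverse MME coefficient matrix
#'
#' Columns of `C^-1` for one trait's genotyped-animal equations, obtained
#' from the stored sparse factor (exact, no approximation).
#'
#' @param fit a `gs_fit` from [genetic_evaluation()] (ssGBLUP mode).
#' @param trait trait name.
#' @return dense symmetric matrix (genotyped x genotyped).
#' @export
inverse_block_genotyped <- function(fit, trait) {
  stopifnot(inherits(fit, "gs_fit"), !is.null(fit$genotyped_index))
  str <- fit$str
  t_idx <- match(trait, str$traits)
  eqs <- str$off_u[t_idx] + fit$genotyped_index
  E <- matrix(0, str$n_eq, length(eqs))
  E[cbind(eqs, seq_along(eqs))] <- 1
  X <- as.matrix(Matrix::solve(fit$chol, E))
  Cuu <- X[eqs, , drop = FALSE]
  (Cuu + t(Cuu)) / 2
}
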