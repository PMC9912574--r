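#' Mid-parent validation
#'
#' Compares family-mean progeny phenotypes against the parent average (PA) of
#' (G)EBVs from a training run that excludes those progeny. Half-sib families
#' are removed first: any family sharing a sire or a dam with an
#' already-retained family is dropped, keeping the first occurrence. The
#' family-mean phenotype is regressed on PA, so a slope below 1 signals
#' over-dispersed breeding values.
#'
#' @param gebv named vector of (G)EBVs for the trait (must cover all parents).
#' @param progeny data.frame with columns `family`, `sire`, `dam`, and
#'   `phenotype` (one row per progeny record; raw or adjusted phenotypes).
#' @return validation report list: method, n (families), cor, b0, b1.
#' @export
midparent_validation <- function(gebv, progeny) {
  stopifnot(all(c("family", "sire", "dam", "phenotype") %in% names(progeny)))
  fams <- progeny[!duplicated(progeny$family),
                  c("family", "sire", "dam"), drop = FALSE]
  keep <- logical(nrow(fams))
  seen_s <- character(0); seen_d <- character(0)
  for (k in seq_len(nrow(fams))) {
    if (!(fams$sire[k] %in% seen_s) && !(fams$dam[k] %in% seen_d)) {
      keep[k] <- TRUE
      seen_s <- c(seen_s, fams$sire[k]); seen_d <- c(seen_d, fams$dam[k])
    }
  }
  fams <- fams[keep, , drop = FALSE]
  if (nrow(fams) < 3) stop("fewer than 3 full-sib families after de-duplication")
  miss <- setdiff(unique(c(fams$sire, fams$dam)), names(gebv))
  if (length(miss))
    stop("parents without evaluated breeding values: ",
         paste(miss, collapse = ", "))
  pa <- (gebv[fams$sire] + gebv[fams$dam]) / 2
  fmean <- vapply(fams$family, function(fid)
    mean(progeny$phenotype[progeny$family == fid], na.rm = TRUE), numeric(1))
  if (stats::sd(pa) == 0)
    stop("parent averages are constant; correlation undefined")
  co <- stats::coef(stats::lm(fmean ~ pa))
  list(method = "midparent", n = nrow(fams),
       cor = stats::cor(fmean, pa),
       b0 = unname(co[1]), b1 = unname(co[2]))
}

#' Forward validation on phenotypes adjusted for fixed effects
#'
#' Accuracy is the correlation between whole-data adjusted phenotypes and the
#' partial-data (G)EBVs of the validation animals, divided by the square root
#' of the heritability; bias and dispersion are the intercept and slope of
#' the regression of adjusted phenotypes on (G)EBV.
#'
#' @param y_star adjusted phenotypes of the validation animals.
#' @param u_hat_partial their (G)EBVs from the run omitting their phenotypes.
#' @param h2 heritability of the trait.
#' @return validation report list: method, n, accuracy, b0, b1.
#' @export
forward_validation_adjusted <- function(y_star, u_hat_partial, h2) {
  ok <- !is.na(y_star) & !is.na(u_hat_partial)
  y_star <- y_star[ok]; u <- u_hat_partial[ok]
  if (stats::sd(u) == 0) stop("(G)EBVs have zero variance")
  co <- stats::coef(stats::lm(y_star ~ u))
  list(method = "adjusted", n = length(u),
       accuracy = stats::cor(y_star, u) / sqrt(h2),
       b0 = unname(co[1]), b1 = unname(co[2]))
}

#' LR-method validation statistics
#'
#' The four whole-vs-partial statistics: accuracy
#' `sqrt(cov(u_w, u_p) / ((1 - Fbar) sigma2_u))`, bias `mean(u_p) - mean(u_w)`
#' (expected 0 for unbiased evaluations), slope `cov(u_w, u_p) / var(u_p)`
#' (dispersion; ideally 1) and consistency `cor(u_w, u_p)`. Sample
#' (co)variances use the n-1 denominator.
#'
#' @param u_hat_whole,u_hat_partial (G)EBVs of the same validation animals
#'   from the whole and partial runs, in matching order.
#' @param F_bar mean pedigree inbreeding of the validation animals.
#' @param sigma2_u additive genetic variance of the trait (whole-data REML).
#' @return validation report list: method, n, accuracy (NA with
#'   `accuracy_undefined = TRUE` if the covariance is negative), bias, slope,
#'   consistency.
#' @export
lr_validation <- function(u_hat_whole, u_hat_partial, F_bar, sigma2_u) {
  stopifnot(length(u_hat_whole) == length(u_hat_partial))
  cv <- stats::cov(u_hat_whole, u_hat_partial)
  acc2 <- cv / ((1 - F_bar) * sigma2_u)
  list(method = "LR", n = length(u_hat_whole),
       accuracy = if (acc2 >= 0) sqrt(acc2) else NA_real_,
       accuracy_undefined = acc2 < 0,
       bias = mean(u_hat_partial) - mean(u_hat_whole),
       slope = cv / stats::var(u_hat_partial),
       consistency = stats::cor(u_hat_whole, u_hat_partial))
}
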