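#' Forward-validation study: whole vs partial evaluations
#'
#' Runs the pedigree (and, when genotypes are given, single-step genomic)
#' evaluation on the whole data and on a partial data set from which all
#' phenotypes of animals hatched in or after `cut_year` are removed
#' (genotypes are retained, so validation animals are genotyped but
#' unphenotyped). Validation animals are the genotyped fish of the cut year
#' with records for both traits (all fish of the cut year with both records
#' in a pedigree-only study). Produces, per model and trait, the
#' adjusted-phenotype statistics (accuracy, b0, b1) and the four LR-method
#' statistics.
#'
#' @param data records data.frame (see [mme_structure()]).
#' @param ped a [renumber_pedigree()] pedigree.
#' @param vc whole-data variance components ([vc_components()]).
#' @param spec a [model_spec()].
#' @param geno optional [geno_matrix()] for the single-step runs.
#' @param cut_year hatch year whose cohort (and later) is validated.
#' @param tau G blending weight passed to [genetic_evaluation()].
#' @param models subset of c("pblup", "ssgblup") to run.
#' @return list with `reports` (long data.frame: model, method, trait,
#'   statistic, value, n), `validation_animals`, and the four fits.
#' @export
validation_study <- function(data, ped, vc, spec = trout_model_spec(),
                             geno = NULL, cut_year, tau = 0.05,
                             models = if (is.null(geno)) "pblup"
                                      else c("pblup", "ssgblup")) {
  yr <- as.numeric(as.character(data$hatch_year))
  cut <- as.numeric(as.character(cut_year))
  partial <- data[yr < cut, , drop = FALSE]
  if (nrow(partial) == 0) stop("no training records before the cut year")
  both <- rowSums(!is.na(data[, spec$traits, drop = FALSE])) ==
    length(spec$traits)
  val <- as.character(data$animal[yr >= cut & both])
  if (!is.null(geno)) val <- intersect(val, geno$ids)
  if (length(val) < 3) stop("fewer than 3 validation animals")

  tot <- diag(vc$Su) + (if (is.null(vc$Sf)) 0 else diag(vc$Sf)) + diag(vc$Se)
  h2 <- diag(vc$Su) / tot
  F_all <- if (anyNA(ped$F)) compute_inbreeding(ped) else ped$F
  F_bar <- mean(F_all[match(val, ped$labels)])

  fits <- list()
  for (m in models) {
    g <- if (m == "ssgblup") geno else NULL
    fits[[paste0(m, "_whole")]] <-
      genetic_evaluation(data, ped, vc, spec, geno = g, tau = tau)
    fits[[paste0(m, "_partial")]] <-
      genetic_evaluation(partial, ped, vc, spec, geno = g, tau = tau)
  }
  # adjusted phenotypes always come from the whole-data pedigree run
  fit_for_ystar <- if ("pblup" %in% models) fits$pblup_whole
    else genetic_evaluation(data, ped, vc, spec)
  ystar <- adjust_phenotypes(fit_for_ystar)
  ystar_val <- ystar[match(val, rownames(ystar)), , drop = FALSE]

  rows <- NULL
  add <- function(rows, model, trait, rep) {
    stats <- rep[setdiff(names(rep), c("method", "n"))]
    stats <- stats[vapply(stats, is.numeric, logical(1))]
    rbind(rows, data.frame(model = model, method = rep$method, trait = trait,
                           statistic = names(stats), value = unlist(stats),
                           n = rep$n, row.names = NULL))
  }
  for (m in models) {
    uw <- fits[[paste0(m, "_whole")]]$u
    up <- fits[[paste0(m, "_partial")]]$u
    for (t in seq_along(spec$traits)) {
      tr <- spec$traits[t]
      rep_adj <- forward_validation_adjusted(ystar_val[, t],
                                             up[val, t], h2[t])
      rep_lr <- lr_validation(uw[val, t], up[val, t], F_bar, vc$Su[t, t])
      rows <- add(rows, m, tr, rep_adj)
      rows <- add(rows, m, tr, rep_lr)
    }
  }
  list(reports = rows, validation_animals = val, h2 = h2, F_bar = F_bar,
       fits = fits, ystar = ystar_val)
}

#' Mid-parent validation study for the fillet-yield trait
#'
#' Evaluates with the last cohort's phenotypes excluded, then compares the
#' parent-average (G)EBV of each validation family against its mean progeny
#' phenotype (raw and adjusted).
#'
#' @inheritParams validation_study
#' @param trait trait validated (default "fy").
#' @return list of reports per model x {raw, adjusted}.
#' @export
midparent_study <- function(data, ped, vc, spec = trout_model_spec(),
                            geno = NULL, cut_year, trait = "fy", tau = 0.05,
                            models = if (is.null(geno)) "pblup"
                                     else c("pblup", "ssgblup")) {
  yr <- as.numeric(as.character(data$hatch_year))
  cut <- as.numeric(as.character(cut_year))
  t_idx <- match(trait, spec$traits)
  partial <- data[yr < cut, , drop = FALSE]
  prog <- data[yr >= cut & !is.na(data[[trait]]), , drop = FALSE]
  sire_of <- ped$labels[ped$sire[match(prog$animal, ped$labels)]]
  dam_of <- ped$labels[ped$dam[match(prog$animal, ped$labels)]]
  progeny <- data.frame(family = as.character(prog$family),
                        sire = sire_of, dam = dam_of,
                        phenotype = prog[[trait]])
  # adjusted progeny phenotypes from the whole-data pedigree run
  fit_w <- genetic_evaluation(data, ped, vc, spec)
  ystar <- adjust_phenotypes(fit_w)
  prog_rows <- match(prog$animal, rownames(ystar))
  progeny_adj <- progeny
  progeny_adj$phenotype <- ystar[prog_rows, t_idx]
  out <- list()
  for (m in models) {
    g <- if (m == "ssgblup") geno else NULL
    fit_p <- genetic_evaluation(partial, ped, vc, spec, geno = g, tau = tau)
    gebv <- fit_p$u[, t_idx]
    out[[m]] <- list(raw = midparent_validation(gebv, progeny),
                     adjusted = midparent_validation(gebv, progeny_adj))
  }
  out
}
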