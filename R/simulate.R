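#' Configuration of the synthetic breeding program
#'
#' Defaults emulate the resource population the evaluation pipeline targets:
#' full-sib families produced by single-pair matings, ~15 offspring eligible
#' per family, fillet yield recorded on 5 fish per family picked by a
#' body-weight rank-skipping rule, body weight recorded on all fish,
#' divergent high/low lines selected on family breeding values under a <= 1%
#' per-generation inbreeding constraint, and generating (co)variances equal
#' to the two-trait REML estimates of the real population (additive 1.99 and
#' 17648, family 0.24 and 5679, residual 2.60 and 29913, genetic correlation
#' 0.24).
#'
#' @param n_generations number of offspring generations (default 3).
#' @param families_per_generation full-sib families per generation (60).
#' @param offspring_per_family eligible fish per family (15).
#' @param genome list: n_chrom, snps_per_chrom, qtl_per_chrom, map_length
#'   (Morgans per chromosome).
#' @param founder_freq_range uniform range of founder allele frequencies.
#' @param target_vc generating [vc_components()] (defaults above).
#' @param r_g generating additive genetic correlation (0.24).
#' @param selection list: trait, proportion of families contributing
#'   parents, and what selection acts on (`"family_ebv"` or `"phenotype"`).
#' @param prop_line_h fraction of families in the upward-selected line (0.8).
#' @param inbreeding_limit_per_gen cap on expected progeny inbreeding above
#'   the parental-generation mean (0.01).
#' @param fy_sampled_per_family fillet-yield records per family (5).
#' @param genotype_parents genotype selected parents as well as the sampled
#'   fish (default TRUE).
#' @param seed mandatory integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_generations = 3,
                       families_per_generation = 60,
                       offspring_per_family = 15,
                       genome = list(n_chrom = 29, snps_per_chrom = 300,
                                     qtl_per_chrom = 10, map_length = 1.0),
                       founder_freq_range = c(0.1, 0.9),
                       target_vc = NULL,
                       r_g = 0.24,
                       selection = list(trait = "fy", proportion = 0.5,
                                        on = "family_ebv"),
                       prop_line_h = 0.8,
                       inbreeding_limit_per_gen = 0.01,
                       fy_sampled_per_family = 5,
                       genotype_parents = TRUE,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (is.null(target_vc)) {
    su <- c(1.99, 17648)
    Su <- diag(su); Su[1, 2] <- Su[2, 1] <- r_g * sqrt(prod(su))
    Sf <- diag(c(0.24, 5679)); Se <- diag(c(2.60, 29913))
    nm <- list(c("fy", "bw"), c("fy", "bw"))
    dimnames(Su) <- dimnames(Sf) <- dimnames(Se) <- nm
    target_vc <- vc_components(Su = Su, Sf = Sf, Se = Se)
  }
  stopifnot(n_generations >= 1, families_per_generation >= 2,
            offspring_per_family >= 1,
            selection$proportion > 0, selection$proportion <= 1,
            fy_sampled_per_family >= 1)
  structure(list(
    n_generations = n_generations,
    families_per_generation = families_per_generation,
    offspring_per_family = offspring_per_family,
    genome = genome, founder_freq_range = founder_freq_range,
    target_vc = target_vc, r_g = r_g, selection = selection,
    prop_line_h = prop_line_h,
    inbreeding_limit_per_gen = inbreeding_limit_per_gen,
    fy_sampled_per_family = fy_sampled_per_family,
    genotype_parents = genotype_parents,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate founder haplotypes in linkage equilibrium
#'
#' Per-locus allele frequencies are drawn uniformly on
#' `founder_freq_range`; founder haplotypes are sampled independently per
#' locus. Marker and QTL loci are laid out jointly on the genetic map; QTL
#' positions are withheld from the genotyping panel.
#'
#' @param cfg a [sim_config()].
#' @param n_founders number of founder animals (default two per family).
#' @return list with `map` (locus, chrom, pos, pos_m, type), `freq`,
#'   and haplotype matrices `hap1`, `hap2` (founders x loci).
#' @export
simulate_founders <- function(cfg, n_founders = 2 * cfg$families_per_generation) {
  if (n_founders < 1) stop("at least one founder is required")
  gn <- cfg$genome
  per_chrom <- gn$snps_per_chrom + gn$qtl_per_chrom
  map <- do.call(rbind, lapply(seq_len(gn$n_chrom), function(chr) {
    pos_m <- sort(stats::runif(per_chrom, 0, gn$map_length))
    type <- rep("marker", per_chrom)
    if (gn$qtl_per_chrom > 0)
      type[sort(sample.int(per_chrom, gn$qtl_per_chrom))] <- "qtl"
    data.frame(locus = sprintf("c%d_l%d", chr, seq_len(per_chrom)),
               chrom = chr, pos = round(pos_m * 25e6), pos_m = pos_m,
               type = type)
  }))
  map$snp <- ifelse(map$type == "marker",
                    sprintf("snp_%05d", cumsum(map$type == "marker")), NA)
  n_loci <- nrow(map)
  freq <- stats::runif(n_loci, cfg$founder_freq_range[1],
                       cfg$founder_freq_range[2])
  hap <- function() matrix(stats::rbinom(n_founders * n_loci, 1,
                                         rep(freq, each = n_founders)),
                           n_founders, n_loci)
  list(map = map, freq = freq, hap1 = hap(), hap2 = hap())
}

# one gamete from a parent's haplotype pair: Poisson-count crossovers at
# uniform positions (Haldane map), segments copied alternately
make_gamete <- function(h1, h2, map_chrom_index, chrom_lengths, chrom_cols) {
  gam <- integer(length(h1))
  for (c_i in seq_along(chrom_cols)) {
    cols <- chrom_cols[[c_i]]
    len <- chrom_lengths[c_i]
    nbr <- stats::rpois(1, len)
    start <- stats::rbinom(1, 1, 0.5)
    if (nbr == 0) {
      gam[cols] <- if (start == 0) h1[cols] else h2[cols]
    } else {
      breaks <- sort(stats::runif(nbr, 0, len))
      seg <- findInterval(map_chrom_index[[c_i]], breaks)
      pick <- (start + seg) %% 2
      gam[cols] <- ifelse(pick == 0, h1[cols], h2[cols])
    }
  }
  gam
}

#' Drop genes through a pedigree with recombination
#'
#' Founders (both parents unknown) take their haplotypes from `founders`
#' (rows matched by label); every other animal receives one recombinant
#' gamete from each parent, with crossover counts Poisson on the chromosome
#' map length (Haldane model, no interference).
#'
#' @param ped a [renumber_pedigree()] pedigree.
#' @param founders output of [simulate_founders()] (or compatible list with
#'   `hap1`, `hap2`, `map` and rownames/ids in `ids`).
#' @param founder_ids labels of the founder rows, in hap row order.
#' @return list `hap1`, `hap2` (all animals x loci, pedigree order).
#' @export
gene_drop <- function(ped, founders, founder_ids) {
  map <- founders$map
  n_loci <- nrow(map)
  chroms <- unique(map$chrom)
  chrom_cols <- lapply(chroms, function(ch) which(map$chrom == ch))
  chrom_lengths <- vapply(chrom_cols, function(cols) max(map$pos_m[cols]),
                          numeric(1))
  map_chrom_index <- lapply(chrom_cols, function(cols) map$pos_m[cols])
  H1 <- matrix(NA_integer_, ped$n, n_loci)
  H2 <- matrix(NA_integer_, ped$n, n_loci)
  frow <- match(ped$labels, founder_ids)
  for (i in seq_len(ped$n)) {
    if (ped$sire[i] == 0L && ped$dam[i] == 0L) {
      if (is.na(frow[i])) stop("founder ", ped$labels[i], " has no haplotypes")
      H1[i, ] <- founders$hap1[frow[i], ]
      H2[i, ] <- founders$hap2[frow[i], ]
    } else {
      s <- ped$sire[i]; d <- ped$dam[i]
      if (s == 0L || d == 0L) stop("gene drop requires both parents known")
      H1[i, ] <- make_gamete(H1[s, ], H2[s, ], map_chrom_index,
                             chrom_lengths, chrom_cols)
      H2[i, ] <- make_gamete(H1[d, ], H2[d, ], map_chrom_index,
                             chrom_lengths, chrom_cols)
    }
  }
  list(hap1 = H1, hap2 = H2)
}

#' Assign the two-trait QTL architecture
#'
#' Bivariate normal QTL effects with the target genetic correlation, then an
#' exact linear rescaling so that the realised founder breeding-value
#' covariance matrix equals the target additive covariance exactly.
#'
#' @param cfg a [sim_config()].
#' @param qtl_dosage founder QTL gene contents (founders x QTL).
#' @return list `effects` (QTL x 2) and `center` (2p of QTL), such that
#'   `TBV = (dosage - center) %*% effects`.
#' @export
assign_trait_architecture <- function(cfg, qtl_dosage) {
  n_qtl <- ncol(qtl_dosage)
  Su <- cfg$target_vc$Su
  if (n_qtl == 0)
    return(list(effects = matrix(0, 0, 2), center = numeric(0)))
  if (any(apply(qtl_dosage, 2, stats::var) == 0) && n_qtl < 2)
    stop("all QTL monomorphic in founders")
  r <- cfg$r_g
  center <- colMeans(qtl_dosage)
  Qc <- sweep(qtl_dosage, 2, center)
  if (abs(r) >= 0.9999) {
    e1 <- stats::rnorm(n_qtl)
    E <- cbind(e1, sign(r) * e1)
    tb <- Qc %*% E
    E <- sweep(E, 2, sqrt(diag(Su) / apply(tb, 2, stats::var)), `*`)
  } else {
    E <- matrix(stats::rnorm(2 * n_qtl), n_qtl, 2)
    E[, 2] <- r * E[, 1] + sqrt(1 - r^2) * E[, 2]
    tb <- Qc %*% E
    S0 <- stats::cov(tb)
    if (min(eigen(S0, only.values = TRUE)$values) <= 0)
      stop("degenerate founder QTL variation")
    M <- mat_sqrt_inv(S0) %*% mat_sqrt(Su)
    E <- E %*% M
  }
  list(effects = E, center = center)
}

mat_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}
mat_sqrt_inv <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
}

#' Simulate phenotypes for one generation of fish
#'
#' `y = fixed effects + TBV + family effect + residual`, with the residual
#' pair drawn jointly for every fish. Body weight is recorded on all fish;
#' fillet yield on `fy_sampled_per_family` fish per family chosen by the
#' rank-skipping rule on simulated body weight after excluding fish more
#' than 3 SD from the family mean; sampled fish are assigned to harvest
#' groups within family in descending body-weight order.
#'
#' @param tbv matrix (fish x 2) of true breeding values (FY, BW).
#' @param meta data.frame with columns `animal`, `family`, `line`,
#'   `hatch_year` for the generation's fish.
#' @param cfg a [sim_config()].
#' @param year_effects list with per-year fixed values (see
#'   [run_breeding_program()]); drawn there once per simulation.
#' @return data.frame: animal, family, line, hatch_year, harvest_year,
#'   harvest_group, age, fy, bw (fy NA for unsampled fish).
#' @export
simulate_phenotypes <- function(tbv, meta, cfg, year_effects) {
  n <- nrow(meta)
  Sf <- cfg$target_vc$Sf; Se <- cfg$target_vc$Se
  fams <- unique(meta$family)
  # symmetric square roots: valid for semi-definite (including zero) matrices
  fam_eff <- matrix(stats::rnorm(2 * length(fams)), length(fams)) %*%
    mat_sqrt(Sf)
  rownames(fam_eff) <- fams
  resid <- matrix(stats::rnorm(2 * n), n) %*% mat_sqrt(Se)
  age <- round(stats::rnorm(n, 440, 7))
  line_eff <- cbind(fy = ifelse(meta$line == "H", 0, -0.3),
                    bw = ifelse(meta$line == "H", 0, -25))
  yr <- as.character(meta$hatch_year)
  bw <- year_effects$mu_bw + year_effects$bw_year[yr] +
    year_effects$beta_bw * (age - 440) + line_eff[, "bw"] +
    tbv[, 2] + fam_eff[meta$family, 2] + resid[, 2]
  # fillet-yield sampling by body-weight rank within family
  sampled <- logical(n); hgroup <- rep(NA_integer_, n)
  for (f in fams) {
    idx <- which(meta$family == f)
    mu <- mean(bw[idx]); sdv <- stats::sd(bw[idx])
    elig <- idx[abs(bw[idx] - mu) <= 3 * sdv | is.na(sdv)]
    elig <- elig[order(bw[elig], decreasing = TRUE)]
    k <- cfg$fy_sampled_per_family
    if (length(elig) < k) {
      warning("family ", f, ": only ", length(elig), " eligible fish; taking all")
      take <- elig
    } else {
      step <- max(1L, floor(length(elig) / k))
      take <- elig[seq(1L, by = step, length.out = k)]
    }
    sampled[take] <- TRUE
    hgroup[take] <- pmin(seq_along(take), 5L)  # heaviest fish -> first group
  }
  fy <- year_effects$mu_fy +
    year_effects$fy_year_group[cbind(yr, as.character(
      ifelse(is.na(hgroup), 1L, hgroup)))] +
    year_effects$beta_fy * (age - 440) + line_eff[, "fy"] +
    tbv[, 1] + fam_eff[meta$family, 1] + resid[, 1]
  fy[!sampled] <- NA_real_
  data.frame(animal = meta$animal, family = meta$family, line = meta$line,
             hatch_year = yr, harvest_year = yr,
             harvest_group = ifelse(is.na(hgroup), "none",
                                    as.character(hgroup)),
             age = age, fy = fy, bw = bw, stringsAsFactors = FALSE)
}

# family-mean breeding values from a single-trait fillet-yield PBLUP on all
# records so far, at the generating variance components
internal_family_ebv <- function(records, ped_df, cfg) {
  ped <- renumber_pedigree(ped_df)
  spec1 <- model_spec("fy",
                      list(fy = ~ age + line + harvest_year:harvest_group),
                      family = TRUE)
  vcs <- cfg$target_vc
  vc1 <- vc_components(Su = vcs$Su[1, 1, drop = FALSE],
                       Sf = vcs$Sf[1, 1, drop = FALSE],
                       Se = vcs$Se[1, 1, drop = FALSE])
  A_inv <- build_A_inverse(ped)
  fit <- solve_mme(build_mme(mme_structure(spec1, records, A_inv), vc1))
  fit$u[, 1]
}

#' Run the full breeding-program simulation
#'
#' Generations are produced sequentially. Families of the upward line are
#' selected on family-mean fillet-yield EBV from an internal pedigree BLUP
#' on the data accumulated so far; the downward line is selected once
#' (generation 2) and mated at random afterwards. Mate allocation is a
#' greedy constraint satisfier: each sire is paired with the best available
#' dam whose expected progeny inbreeding `a(s, d) / 2` does not exceed the
#' parental-generation mean inbreeding plus the per-generation limit.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_output` : `ped` (pedigree), `data`
#'   (phenotype records for all offspring), `geno` (genotyped subset as a
#'   [geno_matrix()]), `truth` (animal, tbv_fy, tbv_bw, F), `history`
#'   (per-generation means), and `cfg`.
#' @export
run_breeding_program <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_fam <- cfg$families_per_generation
  n_off <- cfg$offspring_per_family
  founders <- simulate_founders(cfg)
  map <- founders$map
  qtl_cols <- which(map$type == "qtl")
  marker_cols <- which(map$type == "marker")
  n_founders <- nrow(founders$hap1)
  founder_ids <- sprintf("F%03d", seq_len(n_founders))

  arch <- assign_trait_architecture(
    cfg, founders$hap1[, qtl_cols, drop = FALSE] +
      founders$hap2[, qtl_cols, drop = FALSE])
  tbv_of <- function(h1, h2) {
    q <- h1[, qtl_cols, drop = FALSE] + h2[, qtl_cols, drop = FALSE]
    if (length(arch$center) == 0) return(matrix(0, nrow(h1), 2))
    sweep(q, 2, arch$center) %*% arch$effects
  }

  years <- 2010 + 2 * seq_len(cfg$n_generations)
  ng <- 5L
  year_effects <- list(
    mu_fy = 50.9, mu_bw = 1043, beta_fy = 0.02, beta_bw = 3,
    bw_year = stats::setNames(stats::rnorm(length(years), 0, 80),
                              as.character(years)),
    fy_year_group = matrix(stats::rnorm(length(years) * ng, 0, 0.5),
                           length(years), ng,
                           dimnames = list(as.character(years),
                                           as.character(seq_len(ng)))))

  # founder state
  sex <- rep(c("M", "F"), length.out = n_founders)
  # sex-stratified line assignment so both lines can form full-pair matings
  line0 <- rep("H", n_founders)
  n_l_half <- round((1 - cfg$prop_line_h) * n_founders / 2)
  line0[sample(which(sex == "M"), n_l_half)] <- "L"
  line0[sample(which(sex == "F"), n_l_half)] <- "L"
  ped_df <- data.frame(animal = founder_ids, sire = "0", dam = "0",
                       stringsAsFactors = FALSE)
  cur <- list(ids = founder_ids, sex = sex, line = line0,
              hap1 = founders$hap1, hap2 = founders$hap2,
              A = diag(n_founders), F = rep(0, n_founders),
              family = rep(NA_character_, n_founders),
              tbv = tbv_of(founders$hap1, founders$hap2))
  truth <- data.frame(animal = founder_ids, tbv_fy = cur$tbv[, 1],
                      tbv_bw = cur$tbv[, 2], F = 0,
                      generation = 0, stringsAsFactors = FALSE)
  records <- NULL
  geno_rows <- list()
  qtl_rows <- list()
  history <- data.frame(generation = 0, mean_F = 0,
                        mean_tbv_fy = mean(cur$tbv[, 1]),
                        mean_tbv_bw = mean(cur$tbv[, 2]))
  relax_warned <- FALSE

  for (g in seq_len(cfg$n_generations)) {
    # -- select parents within line ------------------------------------------
    fam_ebv <- NULL
    if (g > 1 && cfg$selection$on == "family_ebv") {
      ebv <- internal_family_ebv(records, ped_df, cfg)
      fam_ebv <- tapply(ebv[cur$ids], cur$family, mean)
    }
    score <- if (g == 1) stats::runif(length(cur$ids))
      else if (cfg$selection$on == "phenotype") {
        stats::setNames(records$fy[match(cur$ids, records$animal)], cur$ids)
      } else as.numeric(fam_ebv[cur$family])
    score[is.na(score)] <- -Inf
    n_fam_h <- round(cfg$prop_line_h * n_fam)
    n_fam_l <- n_fam - n_fam_h
    pairs <- NULL
    for (ln in c("H", "L")) {
      want <- if (ln == "H") n_fam_h else n_fam_l
      if (want == 0) next
      in_line <- which(cur$line == ln)
      direction <- if (ln == "H") -1 else if (g == 2) 1 else 0
      # rank candidate *families* (founders count as one-animal families),
      # keep the selected fraction, then interleave parents across families
      # (best family first) so many new families come from few parental
      # families without exhausting any single one
      famkey <- if (g == 1) as.character(in_line) else cur$family[in_line]
      fam_score <- tapply(score[in_line], famkey, mean)
      shuf <- function(v) if (length(v) < 2) v else sample(v)
      fam_rank <- if (direction == 0) shuf(names(fam_score))
        else names(sort(direction * fam_score))
      n_sel_fam <- max(2L, ceiling(cfg$selection$proportion * length(fam_rank)))
      # interleave over the whole ranking: selected families come first, but
      # lower-ranked families remain available when kinship blocks a mating
      interleave <- function(sx) {
        per_fam <- lapply(fam_rank, function(f)
          shuf(in_line[famkey == f & cur$sex[in_line] == sx]))
        len <- max(vapply(per_fam, length, integer(1)))
        sel <- seq_len(min(n_sel_fam, length(per_fam)))
        ord <- c(lapply(seq_len(len), function(k) lapply(per_fam[sel], `[`, k)),
                 lapply(seq_len(len), function(k) lapply(per_fam[-sel], `[`, k)))
        idx <- unlist(ord, use.names = FALSE)
        idx[!is.na(idx)]
      }
      sires <- interleave("M")
      dams <- interleave("F")
      thr <- mean(cur$F) + cfg$inbreeding_limit_per_gen
      used_d <- logical(length(dams))
      made <- 0L
      # first pass: honour the constraint, skipping sires with no feasible dam
      for (s in sires) {
        if (made == want) break
        rel <- cur$A[s, dams]
        feas <- which(!used_d & rel / 2 <= thr)
        if (length(feas) == 0) next
        used_d[feas[1]] <- TRUE      # ranked pools: first feasible is best
        pairs <- rbind(pairs, data.frame(sire = s, dam = dams[feas[1]],
                                         line = ln))
        made <- made + 1L
      }
      if (made < want) {
        # infeasible remainder: relax to minimum-kinship matings, log it
        if (!relax_warned) {
          warning("inbreeding constraint relaxed for some matings")
          relax_warned <- TRUE
        }
        used_s <- sires %in% pairs$sire
        for (s in sires[!used_s]) {
          if (made == want) break
          open <- which(!used_d)
          if (length(open) == 0) break
          dsel <- open[which.min(cur$A[s, dams][open])]
          used_d[dsel] <- TRUE
          pairs <- rbind(pairs, data.frame(sire = s, dam = dams[dsel],
                                           line = ln))
          made <- made + 1L
        }
        if (made < want)
          warning("line ", ln, ": only ", made, " of ", want,
                  " families could be mated")
      }
    }

    # -- produce offspring ----------------------------------------------------
    n_new_fam <- nrow(pairs)
    n_new <- n_new_fam * n_off
    ids <- sprintf("G%d_%04d", g, seq_len(n_new))
    fam_ids <- sprintf("fam_%d_%03d", g, rep(seq_len(n_new_fam), each = n_off))
    map_idx <- lapply(unique(map$chrom), function(ch) which(map$chrom == ch))
    chrom_lengths <- vapply(map_idx, function(cl) max(map$pos_m[cl]), numeric(1))
    pos_list <- lapply(map_idx, function(cl) map$pos_m[cl])
    H1 <- matrix(NA_integer_, n_new, nrow(map))
    H2 <- matrix(NA_integer_, n_new, nrow(map))
    for (k in seq_len(n_new)) {
      fidx <- (k - 1L) %/% n_off + 1L
      s <- pairs$sire[fidx]; d <- pairs$dam[fidx]
      H1[k, ] <- make_gamete(cur$hap1[s, ], cur$hap2[s, ], pos_list,
                             chrom_lengths, map_idx)
      H2[k, ] <- make_gamete(cur$hap1[d, ], cur$hap2[d, ], pos_list,
                             chrom_lengths, map_idx)
    }
    # relationships of the new generation from the parental A
    Ap <- cur$A
    sv <- pairs$sire[(seq_len(n_new) - 1L) %/% n_off + 1L]
    dv <- pairs$dam[(seq_len(n_new) - 1L) %/% n_off + 1L]
    # a(i, j) = (a(si,sj) + a(si,dj) + a(di,sj) + a(di,dj)) / 4 for i != j
    # (exact also for full sibs); diagonal 1 + a(s, d) / 2
    Anew <- 0.25 * (Ap[sv, sv] + Ap[sv, dv] + Ap[dv, sv] + Ap[dv, dv])
    Fnew <- 0.5 * Ap[cbind(sv, dv)]
    diag(Anew) <- 1 + Fnew
    tbv_new <- tbv_of(H1, H2)
    meta <- data.frame(animal = ids, family = fam_ids,
                       line = pairs$line[(seq_len(n_new) - 1L) %/% n_off + 1L],
                       hatch_year = years[g], stringsAsFactors = FALSE)
    recs_g <- simulate_phenotypes(tbv_new, meta, cfg, year_effects)
    records <- rbind(records, recs_g)
    ped_df <- rbind(ped_df, data.frame(animal = ids,
                                       sire = cur$ids[sv], dam = cur$ids[dv],
                                       stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(animal = ids, tbv_fy = tbv_new[, 1],
                                     tbv_bw = tbv_new[, 2], F = Fnew,
                                     generation = g))
    # genotyped subset: sampled fish, plus this generation's parents
    g_sampled <- ids[!is.na(recs_g$fy)]
    g_parents <- if (cfg$genotype_parents)
      unique(cur$ids[c(pairs$sire, pairs$dam)]) else character(0)
    for (an in g_sampled) {
      k <- match(an, ids)
      geno_rows[[an]] <- H1[k, marker_cols] + H2[k, marker_cols]
      qtl_rows[[an]] <- H1[k, qtl_cols] + H2[k, qtl_cols]
    }
    for (an in g_parents) if (is.null(geno_rows[[an]])) {
      k <- match(an, cur$ids)
      geno_rows[[an]] <- cur$hap1[k, marker_cols] + cur$hap2[k, marker_cols]
      qtl_rows[[an]] <- cur$hap1[k, qtl_cols] + cur$hap2[k, qtl_cols]
    }
    history <- rbind(history, data.frame(
      generation = g, mean_F = mean(Fnew),
      mean_tbv_fy = mean(tbv_new[, 1]), mean_tbv_bw = mean(tbv_new[, 2])))
    sex_new <- sample(rep(c("M", "F"), length.out = n_new))
    cur <- list(ids = ids, sex = sex_new, line = meta$line,
                hap1 = H1, hap2 = H2, A = Anew, F = Fnew,
                family = fam_ids, tbv = tbv_new)
  }

  ped <- renumber_pedigree(ped_df)
  M <- do.call(rbind, geno_rows)
  Q <- do.call(rbind, qtl_rows)
  storage.mode(M) <- "integer"
  snp_map <- data.frame(snp = map$snp[marker_cols],
                        chrom = map$chrom[marker_cols],
                        pos = map$pos[marker_cols])
  colnames(M) <- snp_map$snp
  geno <- geno_matrix(M, snp_map)
  truth$F_ped <- ped$F[match(truth$animal, ped$labels)]
  founder_freq <- stats::setNames(founders$freq[marker_cols], snp_map$snp)
  structure(list(ped = ped, data = records, geno = geno, truth = truth,
                 founder_freq = founder_freq,
                 history = history, cfg = cfg, qtl_dosage = Q,
                 qtl_effects = arch$effects, qtl_center = arch$center,
                 year_effects = year_effects), class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat("Simulated breeding program:", x$ped$n, "animals,",
      nrow(x$data), "records,", length(x$geno$ids), "genotyped;",
      "mean F by generation:",
      paste(format(x$history$mean_F, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Write a simulation to the file bundle read by the evaluation pipeline
#'
#' Emits pedigree CSV, phenotype CSV, PLINK RAW genotypes, SNP map CSV and a
#' truth TSV (animal, tbv_fy, tbv_bw, F).
#'
#' @param sim a [run_breeding_program()] output.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_sim_output <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(dir, "pedigree.csv"),
             phe = file.path(dir, "phenotypes.csv"),
             raw = file.path(dir, "genotypes.raw"),
             map = file.path(dir, "snp_map.csv"),
             tru = file.path(dir, "truth.tsv"))
  write_pedigree(sim$ped, paths["ped"])
  utils::write.csv(sim$data, paths["phe"], row.names = FALSE, quote = FALSE)
  write_genotypes_raw(sim$geno, paths["raw"])
  utils::write.csv(sim$geno$map, paths["map"], row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth, paths["tru"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
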