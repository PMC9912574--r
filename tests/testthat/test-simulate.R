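test_that("configuration validates inputs and requires a seed", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, selection = list(trait = "fy",
                                                     proportion = 0,
                                                     on = "family_ebv")))
  cfg <- sim_config(seed = 3)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$fy_sampled_per_family, 5)
  # generating covariances reproduce the published genetic parameters
  gp <- compute_genetic_parameters(cfg$target_vc)
  est <- setNames(round(gp$estimate, 2), gp$parameter)
  expect_equal(unname(est[c("h2.fy", "h2.bw", "f2.bw", "r_g")]),
               c(0.41, 0.33, 0.11, 0.24))
})

test_that("founder haplotypes are seeded, frequency-bounded, and error on zero founders", {
  cfg <- test_sim_config(seed = 5, founder_freq_range = c(0.5, 0.5))
  expect_error(simulate_founders(cfg, n_founders = 0), "founder")
  set.seed(cfg$seed); f1 <- simulate_founders(cfg, n_founders = 200)
  set.seed(cfg$seed); f2 <- simulate_founders(cfg, n_founders = 200)
  expect_identical(f1$hap1, f2$hap1)              # determinism under the seed
  expect_true(all(f1$freq == 0.5))
  het <- mean(f1$hap1 != f1$hap2)                 # expected heterozygosity 1/2
  expect_lt(abs(het - 0.5), 0.02)
})

test_that("gene drop is Mendelian and degenerates to intact haplotypes at map length 0", {
  cfg <- test_sim_config(seed = 7)
  cfg$genome$map_length <- 0
  set.seed(1)
  f <- simulate_founders(cfg, n_founders = 4)
  f$map$pos_m <- rep(0, nrow(f$map))
  ped <- renumber_pedigree(data.frame(
    animal = c("f1", "f2", "f3", "f4", "k1", "k2"),
    sire = c("0", "0", "0", "0", "f1", "f1"),
    dam = c("0", "0", "0", "0", "f2", "f2")))
  gd <- gene_drop(ped, f, founder_ids = c("f1", "f2", "f3", "f4"))
  # zero map length: each chromosome of a gamete is one intact parental
  # haplotype (chromosomes still segregate independently)
  k1_pat <- gd$hap1[5, ]
  for (ch in unique(f$map$chrom)) {
    cols <- which(f$map$chrom == ch)
    expect_true(identical(k1_pat[cols], f$hap1[1, cols]) ||
                identical(k1_pat[cols], f$hap2[1, cols]))
  }
  # Mendelian consistency at every locus under a recombining map
  cfg2 <- test_sim_config(seed = 9)
  set.seed(2)
  f2 <- simulate_founders(cfg2, n_founders = 4)
  gd2 <- gene_drop(ped, f2, founder_ids = c("f1", "f2", "f3", "f4"))
  gc <- gd2$hap1 + gd2$hap2
  for (k in 5:6) {
    s <- ped$sire[k]; d <- ped$dam[k]
    # offspring allele from each parent must be carried by that parent
    expect_true(all(gd2$hap1[k, ] == gd2$hap1[s, ] |
                    gd2$hap1[k, ] == gd2$hap2[s, ]))
    expect_true(all(gd2$hap2[k, ] == gd2$hap1[d, ] |
                    gd2$hap2[k, ] == gd2$hap2[d, ]))
    expect_true(all(gc[k, ] %in% 0:2))
  }
})

test_that("gene-content correlation across the pedigree tracks A on average", {
  cfg <- test_sim_config(seed = 11)
  set.seed(3)
  n_f <- 6
  f <- simulate_founders(cfg, n_founders = n_f)
  ids <- sprintf("f%d", 1:n_f)
  ped <- renumber_pedigree(data.frame(
    animal = c(ids, "x", "y", "z"),
    sire = c(rep("0", n_f), "f1", "f1", "x"),
    dam = c(rep("0", n_f), "f2", "f2", "y")))
  gd <- gene_drop(ped, f, founder_ids = ids)
  gc <- gd$hap1 + gd$hap2
  A <- build_A(ped)
  Z <- scale(t(gc), center = TRUE, scale = FALSE)
  Gobs <- crossprod(t(t(Z))) / nrow(Z)
  # empirical covariance of gene content between relatives scales with A:
  # check the sib pair (x, y) against an unrelated pair (x, f3)
  covxy <- cov(gc[7, ], gc[8, ]) / var(as.numeric(gc[7, ]))
  expect_gt(cor(gc[7, ], gc[8, ]), cor(gc[7, ], gc[3, ]))
})

test_that("trait architecture rescaling hits the target founder covariance exactly", {
  cfg <- test_sim_config(seed = 13)
  set.seed(4)
  q <- matrix(rbinom(200 * 50, 2, 0.4), 200, 50)
  arch <- assign_trait_architecture(cfg, q)
  tbv <- sweep(q, 2, arch$center) %*% arch$effects
  expect_equal(unname(cov(tbv)), unname(cfg$target_vc$Su), tolerance = 1e-10)
  # perfect genetic correlation: proportional effects, realized r = 1
  cfg1 <- test_sim_config(seed = 13, r_g = 1)
  arch1 <- assign_trait_architecture(cfg1, q)
  tbv1 <- sweep(q, 2, arch1$center) %*% arch1$effects
  expect_equal(cor(tbv1[, 1], tbv1[, 2]), 1, tolerance = 1e-12)
  # no QTL: zero breeding values
  arch0 <- assign_trait_architecture(cfg, q[, 0, drop = FALSE])
  expect_equal(nrow(arch0$effects), 0)
})

test_that("phenotype bookkeeping: FY sampling rule, harvest groups, zero-variance limit", {
  cfg <- test_sim_config(seed = 17)
  n <- 40
  meta <- data.frame(animal = sprintf("x%02d", 1:n),
                     family = rep(c("fa", "fb", "fc", "fd"), each = 10),
                     line = "H", hatch_year = 2012)
  ye <- list(mu_fy = 50, mu_bw = 1000, beta_fy = 0.02, beta_bw = 3,
             bw_year = c("2012" = 10),
             fy_year_group = matrix(0, 1, 5, dimnames = list("2012", 1:5)))
  set.seed(5)
  tbv <- matrix(rnorm(2 * n), n) %*% chol(cfg$target_vc$Su)
  ph <- simulate_phenotypes(tbv, meta, cfg, ye)
  # exactly 5 FY records per family; all BW recorded
  expect_equal(as.integer(table(ph$family[!is.na(ph$fy)])), rep(5L, 4))
  expect_true(all(!is.na(ph$bw)))
  # sampled fish occupy harvest groups 1..5 by descending weight within family
  for (f in unique(ph$family)) {
    sub <- ph[ph$family == f & !is.na(ph$fy), ]
    expect_setequal(sub$harvest_group, as.character(1:5))
    expect_true(all(diff(sub$bw[order(as.integer(sub$harvest_group))]) <= 0))
  }
  # all-zero variance components: phenotype equals the fixed-effect sum
  cfg0 <- test_sim_config(seed = 17)
  cfg0$target_vc <- vc_components(Su = diag(c(0, 0)), Sf = diag(c(0, 0)),
                                  Se = diag(c(0, 0)))
  ph0 <- simulate_phenotypes(matrix(0, n, 2), meta, cfg0, ye)
  expect_equal(ph0$bw, 1000 + 10 + 3 * (ph0$age - 440), tolerance = 1e-12)
})

test_that("the breeding program is deterministic under its seed", {
  s1 <- suppressWarnings(run_breeding_program(test_sim_config(seed = 19)))
  s2 <- suppressWarnings(run_breeding_program(test_sim_config(seed = 19)))
  expect_identical(s1$data, s2$data)
  expect_identical(s1$geno$M, s2$geno$M)
  expect_identical(s1$truth, s2$truth)
  s3 <- suppressWarnings(run_breeding_program(test_sim_config(seed = 20)))
  expect_false(identical(s1$data$bw, s3$data$bw))
})

test_that("selection moves the mean breeding value in the selected direction", {
  # no selection, random mating: no systematic trend
  cfg_null <- test_sim_config(seed = 23, n_generations = 3,
                              families_per_generation = 20,
                              selection = list(trait = "fy", proportion = 1,
                                               on = "phenotype"),
                              prop_line_h = 1)
  trends <- vapply(1:3, function(k) {
    cfg_null$seed <- 23L + k
    h <- suppressWarnings(run_breeding_program(cfg_null))$history
    h$mean_tbv_fy[nrow(h)] - h$mean_tbv_fy[1]
  }, numeric(1))
  expect_lt(abs(mean(trends)), 2 * sqrt(1.99))
  # upward family-EBV selection: positive trend in the H line
  cfg_sel <- test_sim_config(seed = 29, n_generations = 3,
                             families_per_generation = 20)
  sim <- suppressWarnings(run_breeding_program(cfg_sel))
  tr <- merge(sim$truth, sim$data[, c("animal", "line")], by = "animal")
  gain <- mean(tr$tbv_fy[tr$line == "H" & tr$generation == 3]) -
    mean(sim$truth$tbv_fy[sim$truth$generation == 0])
  expect_gt(gain, 0)
})

test_that("realized inbreeding obeys the per-generation constraint on average", {
  # enough parents that the constraint is attainable (drift alone gives
  # roughly 1/(8 Nm) + 1/(8 Nf) per generation)
  dfs <- vapply(1:2, function(k) {
    sim <- suppressWarnings(run_breeding_program(test_sim_config(
      seed = 31 + k, n_generations = 4, families_per_generation = 40)))
    mean(diff(sim$history$mean_F))
  }, numeric(1))
  expect_true(all(dfs <= 0.01 + 1e-9))
})

test_that("simulation bundle round-trips through the pipeline file formats", {
  sim <- suppressWarnings(run_breeding_program(test_sim_config(
    seed = 37, families_per_generation = 8, snps_per_chrom = 20)))
  dir <- withr::local_tempdir()
  paths <- write_sim_output(sim, dir)
  ped2 <- read_pedigree(paths["ped"])
  expect_identical(ped2$labels, sim$ped$labels)
  map2 <- read_snp_map(paths["map"])
  g2 <- read_genotypes_raw(paths["raw"], map2)
  expect_identical(g2$M, sim$geno$M)
  d2 <- read_phenotypes(paths["phe"])
  expect_equal(d2$bw, sim$data$bw, tolerance = 1e-10)
  tru <- utils::read.delim(paths["tru"])
  expect_equal(nrow(tru), sim$ped$n)
})

test_that("YAML configuration round-trips and rejects unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 99", "n_generations: 2", "families_per_generation: 10"),
             path)
  cfg <- sim_config_from_yaml(path)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$n_generations, 2)
  writeLines(c("seed: 1", "bogus_knob: 3"), path)
  expect_error(sim_config_from_yaml(path), "bogus_knob")
  writeLines("n_generations: 2", path)
  expect_error(sim_config_from_yaml(path), "seed")
})
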