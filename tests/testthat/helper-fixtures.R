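# shared in-code fixtures for the test suite

# random but reproducible pedigree: founders then descendants with random
# known/unknown parents
random_pedigree <- function(n, n_founders = 10, seed = 1, p_unknown = 0.1) {
  set.seed(seed)
  sire <- dam <- integer(n)
  for (i in (n_founders + 1):n) {
    sire[i] <- sample(seq_len(i - 1), 1)
    dam[i] <- sample(seq_len(i - 1), 1)
    if (dam[i] == sire[i]) dam[i] <- 0L
    if (stats::runif(1) < p_unknown) sire[i] <- 0L
  }
  lab <- sprintf("a%03d", seq_len(n))
  renumber_pedigree(data.frame(
    animal = lab,
    sire = ifelse(sire == 0, "0", lab[pmax(sire, 1)]),
    dam = ifelse(dam == 0, "0", lab[pmax(dam, 1)])))
}

# small two-generation genotyped pedigree with genotypes for GLS tests
small_geno_pedigree <- function(seed = 42, n_snp = 25) {
  set.seed(seed)
  n_founders <- 10; n_off <- 20
  lab <- c(sprintf("f%02d", 1:n_founders), sprintf("o%02d", 1:n_off))
  sire <- c(rep("0", n_founders),
            sample(lab[1:5], n_off, replace = TRUE))
  dam <- c(rep("0", n_founders),
           sample(lab[6:10], n_off, replace = TRUE))
  ped <- renumber_pedigree(data.frame(animal = lab, sire = sire, dam = dam))
  p <- stats::runif(n_snp, 0.2, 0.8)
  hap <- function() matrix(stats::rbinom(n_founders * n_snp, 1,
                                         rep(p, each = n_founders)),
                           n_founders, n_snp)
  h1 <- hap(); h2 <- hap()
  rownames(h1) <- rownames(h2) <- lab[1:n_founders]
  M <- matrix(NA_integer_, length(lab), n_snp,
              dimnames = list(lab, sprintf("s%02d", 1:n_snp)))
  M[1:n_founders, ] <- h1 + h2
  gam <- function(a) {
    pick <- matrix(stats::rbinom(n_snp, 1, 0.5), 1)  # unlinked loci
    ifelse(pick == 1, h1[a, ], h2[a, ])
  }
  for (k in seq_len(n_off)) {
    i <- n_founders + k
    M[i, ] <- gam(sire[i]) + gam(dam[i])
  }
  map <- data.frame(snp = colnames(M), chrom = 1L, pos = seq_len(n_snp) * 1000L)
  list(ped = ped, geno = geno_matrix(M, map), p_true = p)
}

# small two-trait records on a given pedigree, simulated straight from the
# linear model (multivariate normal), for MME and REML oracles
mvn_records <- function(ped, Su, Sf, Se, seed = 1, n_fam = 8,
                        fy_missing = 0.5) {
  set.seed(seed)
  n <- ped$n
  A <- build_A(ped)
  L <- t(chol(A + diag(1e-8, n)))
  U <- (L %*% matrix(stats::rnorm(2 * n), n)) %*% chol(Su)
  fam <- sample(sprintf("fam%02d", seq_len(n_fam)), n, replace = TRUE)
  Fm <- matrix(stats::rnorm(2 * n_fam), n_fam) %*% chol(Sf)
  rownames(Fm) <- sprintf("fam%02d", seq_len(n_fam))
  E <- matrix(stats::rnorm(2 * n), n) %*% chol(Se)
  age <- round(stats::rnorm(n, 440, 7))
  grp <- sample(as.character(1:3), n, replace = TRUE)
  line <- sample(c("H", "L"), n, replace = TRUE)
  fy <- 50 + 0.02 * (age - 440) + (line == "L") * -0.3 + U[, 1] +
    Fm[fam, 1] + E[, 1]
  bw <- 1000 + 3 * (age - 440) + (line == "L") * -25 + U[, 2] +
    Fm[fam, 2] + E[, 2]
  fy[stats::runif(n) < fy_missing] <- NA
  data.frame(animal = ped$labels, family = fam, line = line,
             hatch_year = "2012", harvest_year = "2012", harvest_group = grp,
             age = age, fy = fy, bw = bw, stringsAsFactors = FALSE)
}

default_start <- function(data) {
  vp <- apply(data[, c("fy", "bw")], 2, stats::var, na.rm = TRUE)
  vc_components(Su = diag(0.3 * vp), Sf = diag(0.1 * vp), Se = diag(0.6 * vp))
}

# fast simulator configuration for tests that do not probe the full design
test_sim_config <- function(seed, n_generations = 2,
                            families_per_generation = 12,
                            offspring_per_family = 10,
                            snps_per_chrom = 40, n_chrom = 5, ...) {
  sim_config(n_generations = n_generations,
             families_per_generation = families_per_generation,
             offspring_per_family = offspring_per_family,
             genome = list(n_chrom = n_chrom, snps_per_chrom = snps_per_chrom,
                           qtl_per_chrom = 10, map_length = 1.0),
             seed = seed, ...)
}
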