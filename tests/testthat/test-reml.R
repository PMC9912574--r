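test_that("selected inverse equals the dense inverse on its pattern", {
  set.seed(1)
  n <- 120
  B <- Matrix::rsparsematrix(n, n, 0.03)
  C <- Matrix::forceSymmetric(Matrix::crossprod(B) + Matrix::Diagonal(n, 5))
  ch <- Matrix::Cholesky(C, LDL = TRUE, super = FALSE, perm = TRUE)
  sel <- troutGS:::selected_inverse(ch)
  Ci <- solve(as.matrix(C))
  idx <- which(as.matrix(C) != 0, arr.ind = TRUE)   # pattern of C is in L
  vals <- sel$lookup(idx[, 1], idx[, 2])
  expect_lt(max(abs(vals - Ci[idx])), 1e-10)
})

test_that("analytic REML gradient matches numerical differentiation", {
  ped <- random_pedigree(60, seed = 31)
  Su <- matrix(c(1, 4, 4, 100), 2); Sf <- diag(c(0.3, 30))
  Se <- matrix(c(2, -5, -5, 200), 2)
  d <- mvn_records(ped, Su, Sf, Se, seed = 31)
  spec <- trout_model_spec()
  str <- mme_structure(spec, d, build_A_inverse(ped))
  tab <- troutGS:::vc_param_table(2, TRUE, TRUE)
  vc0 <- vc_components(Su = diag(c(0.8, 120)) + 2 * (1 - diag(2)),
                       Sf = diag(c(0.4, 25)), Se = diag(c(1.8, 240)))
  theta <- troutGS:::vc_pack(vc0, tab)
  m2ll_at <- function(th) {
    v <- troutGS:::vc_unpack(th, tab, vc0)
    sys <- build_mme(str, v)
    ch <- Matrix::Cholesky(sys$C, LDL = TRUE, super = FALSE, perm = TRUE)
    sol <- as.numeric(Matrix::solve(ch, sys$rhs))
    troutGS:::reml_m2ll(sys, ch, sol)
  }
  it <- troutGS:::reml_iteration(str, vc0, tab)
  num <- vapply(seq_along(theta), function(k) {
    h <- max(1e-5, 1e-5 * abs(theta[k]))
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- dn[k] - h
    (m2ll_at(up) - m2ll_at(dn)) / (2 * h)
  }, numeric(1))
  expect_equal(-2 * it$gradient, num, tolerance = 1e-4)
})

test_that("REML likelihood from the MME equals the dense restricted likelihood", {
  ped <- random_pedigree(40, seed = 37)
  Su <- diag(c(1, 90)); Sf <- diag(c(0.2, 15)); Se <- diag(c(2, 150))
  d <- mvn_records(ped, Su, Sf, Se, seed = 37)
  spec <- model_spec(c("fy", "bw"), list(fy = ~ age, bw = ~ age), family = TRUE)
  vc <- vc_components(Su, Sf, Se)
  str <- mme_structure(spec, d, build_A_inverse(ped))
  sys <- build_mme(str, vc)
  ch <- Matrix::Cholesky(sys$C, LDL = TRUE, super = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(ch, sys$rhs))
  m2_mme <- troutGS:::reml_m2ll(sys, ch, sol)
  # dense computation of log|V| + log|X'V^-1 X| + y'Py
  A <- build_A(ped)
  nl <- str$n_long
  Zu <- matrix(0, nl, 2 * ped$n); Zf <- matrix(0, nl, 2 * str$n_fam)
  Xl <- matrix(0, nl, sum(str$p))
  for (t in 1:2) {
    rows <- which(str$long_trait == t)
    rec <- str$long_rec[rows]
    Zu[cbind(rows, (t - 1) * ped$n + str$anim_idx[rec])] <- 1
    Zf[cbind(rows, (t - 1) * str$n_fam + str$fam_idx[rec])] <- 1
    Xl[rows, (str$off_b[t] + 1):(str$off_b[t] + str$p[t])] <-
      str$X[[t]][rec, , drop = FALSE]
  }
  R <- matrix(0, nl, nl)
  for (r in seq_len(str$n_rec)) for (a in 1:2) for (b in 1:2) {
    ia <- str$idx_long[r, a]; ib <- str$idx_long[r, b]
    if (!is.na(ia) && !is.na(ib)) R[ia, ib] <- Se[a, b]
  }
  V <- Zu %*% kronecker(Su, A) %*% t(Zu) +
    Zf %*% kronecker(Sf, diag(str$n_fam)) %*% t(Zf) + R
  Vi <- solve(V)
  XtVX <- t(Xl) %*% Vi %*% Xl
  P <- Vi - Vi %*% Xl %*% solve(XtVX, t(Xl) %*% Vi)
  m2_dense <- as.numeric(determinant(V)$modulus) +
    as.numeric(determinant(XtVX)$modulus) +
    as.numeric(t(str$y_long) %*% P %*% str$y_long)
  # the MME form omits the variance-free constant T * log|A|
  const <- 2 * as.numeric(determinant(A)$modulus)
  expect_equal(m2_mme, m2_dense - const, tolerance = 1e-6)
})

test_that("single-trait REML on a balanced half-sib design matches ANOVA", {
  # 40 unrelated sires x 12 half-sib progeny, dams unknown; the animal model
  # maps 1:1 onto the sire model, whose balanced-design REML equals ANOVA:
  # sigma2_s = (MSB - MSW) / n, with sigma2_a = 4 sigma2_s
  set.seed(41)
  n_s <- 40; n_prog <- 12
  sigma_a <- 4; sigma_e <- 12   # true components
  sires <- sprintf("s%02d", 1:n_s)
  prog <- sprintf("p%03d", 1:(n_s * n_prog))
  ped <- renumber_pedigree(data.frame(
    animal = c(sires, prog),
    sire = c(rep("0", n_s), rep(sires, each = n_prog)),
    dam = "0"))
  us <- rnorm(n_s, 0, sqrt(sigma_a))
  y <- rep(us / 2, each = n_prog) +
    rnorm(n_s * n_prog, 0, sqrt(sigma_e + 0.75 * sigma_a))
  d <- data.frame(animal = prog, family = rep(sires, each = n_prog),
                  fy = y, stringsAsFactors = FALSE)
  spec <- model_spec("fy", list(fy = ~ 1), family = FALSE)
  start <- vc_components(Su = matrix(var(y) / 2), Se = matrix(var(y) / 2))
  r <- estimate_vc_aireml(spec, d, build_A_inverse(ped), start, tol = 1e-10)
  grp <- rep(seq_len(n_s), each = n_prog)
  msb <- n_prog * var(tapply(y, grp, mean))
  msw <- sum((y - ave(y, grp))^2) / (n_s * (n_prog - 1))
  s2_sire <- (msb - msw) / n_prog
  expect_true(r$converged)
  expect_equal(r$vc$Su[1, 1], 4 * s2_sire, tolerance = 1e-6)
  expect_equal(r$vc$Se[1, 1], msw - 0.75 * 4 * s2_sire, tolerance = 1e-5)
})

test_that("REML drives the family variance to the boundary when it is absent", {
  ped <- random_pedigree(800, n_founders = 80, seed = 43)
  Su <- diag(c(1, 100)); Se <- diag(c(1.5, 150))
  d <- mvn_records(ped, Su, Sf = diag(c(1e-12, 1e-10)), Se, seed = 43,
                   n_fam = 60, fy_missing = 0)
  spec <- model_spec(c("fy", "bw"), list(fy = ~ 1, bw = ~ 1), family = TRUE)
  start <- default_start(d)
  r <- estimate_vc_aireml(spec, d, build_A_inverse(ped), start)
  gp <- compute_genetic_parameters(r)
  f2 <- gp$estimate[grepl("^f2", gp$parameter)]
  expect_lt(max(f2), 0.02)
})

test_that("REML recovers generating components within Monte-Carlo error", {
  # 5 replicates on simulator pedigrees with exact multivariate-normal
  # effects drawn from the target covariances (isolates the estimator from
  # the finite-locus genetics, which the full-scale recovery study covers);
  # generating values must lie inside mean +- 2 MC-SE (floor 0.05)
  Su <- matrix(c(1.99, 44.98, 44.98, 17648), 2)
  Sf <- diag(c(0.24, 5679)); Se <- diag(c(2.60, 29913))
  ests <- NULL
  for (s in 1:5) {
    sim <- suppressWarnings(run_breeding_program(test_sim_config(
      seed = 50 + s, families_per_generation = 30,
      offspring_per_family = 12, snps_per_chrom = 5)))
    ped <- sim$ped
    set.seed(500 + s)
    L <- t(chol(build_A(ped)))
    U <- (L %*% matrix(rnorm(2 * ped$n), ped$n)) %*% chol(Su)
    rownames(U) <- ped$labels
    d <- sim$data
    fams <- unique(d$family)
    Fm <- matrix(rnorm(2 * length(fams)), length(fams)) %*% chol(Sf)
    rownames(Fm) <- fams
    E <- matrix(rnorm(2 * nrow(d)), nrow(d)) %*% chol(Se)
    keep_fy <- !is.na(d$fy)
    d$fy <- 50 + 0.02 * (d$age - 440) + U[d$animal, 1] + Fm[d$family, 1] + E[, 1]
    d$fy[!keep_fy] <- NA
    d$bw <- 1000 + 3 * (d$age - 440) + U[d$animal, 2] + Fm[d$family, 2] + E[, 2]
    r <- estimate_vc_aireml(trout_model_spec(), d,
                            build_A_inverse(ped), default_start(d))
    gp <- compute_genetic_parameters(r)
    ests <- rbind(ests, gp$estimate)
  }
  m <- colMeans(ests); se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  truth <- c(0.41, 0.33, 0.05, 0.107, 0.24)
  expect_true(all(abs(m - truth) <= pmax(2 * se, 0.05)))
})

test_that("genetic parameters from fixed covariance matrices match hand values", {
  Su <- matrix(c(1.99, 44.98, 44.98, 17648), 2)
  Sf <- diag(c(0.24, 5679)); Se <- diag(c(2.60, 29913))
  gp <- compute_genetic_parameters(vc_components(Su, Sf, Se))
  est <- setNames(gp$estimate, gp$parameter)
  expect_equal(round(unname(est["h2.1"]), 2), 0.41)
  expect_equal(round(unname(est["h2.2"]), 2), 0.33)
  expect_equal(round(unname(est["f2.2"]), 2), 0.11)
  expect_equal(round(unname(est["r_g"]), 2), 0.24)
  # zero additive covariance means zero genetic correlation
  Su0 <- diag(c(1.99, 17648))
  gp0 <- compute_genetic_parameters(vc_components(Su0, Sf, Se))
  expect_equal(gp0$estimate[gp0$parameter == "r_g"], 0)
})
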