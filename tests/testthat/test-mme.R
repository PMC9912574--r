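test_that("intercept-only model returns the mean", {
  ped <- renumber_pedigree(data.frame(animal = c("a", "b", "c"),
                                      sire = "0", dam = "0"))
  d <- data.frame(animal = c("a", "b", "c"), family = "f1",
                  fy = c(1, 2, 3), stringsAsFactors = FALSE)
  spec <- model_spec("fy", list(fy = ~ 1), family = FALSE)
  vc <- vc_components(Su = matrix(1e-8), Se = matrix(1))
  fit <- solve_mme(build_mme(mme_structure(spec, d, build_A_inverse(ped)), vc))
  expect_equal(unname(fit$b$fy), 2, tolerance = 1e-6)
})

test_that("vanishing variance ratio reduces to fixed-effect least squares", {
  ped <- random_pedigree(40, seed = 2)
  d <- mvn_records(ped, Su = diag(c(1, 100)), Sf = diag(c(0.2, 20)),
                   Se = diag(c(2, 200)), seed = 3)
  spec <- model_spec(c("fy", "bw"),
                     list(fy = ~ age + line, bw = ~ age + line), family = FALSE)
  tiny <- vc_components(Su = diag(c(1e-10, 1e-8)), Se = diag(c(2, 200)))
  fit <- solve_mme(build_mme(mme_structure(spec, d, build_A_inverse(ped)), tiny))
  # parameterisations differ (full indicators vs treatment contrasts), so
  # compare fitted values, which are invariant
  str <- fit$str
  fitted_ls <- fitted(lm(fy ~ age + line, d))
  expect_equal(unname(fit$fitted_fixed[!is.na(d$fy), "fy"]),
               unname(fitted_ls), tolerance = 1e-4)
  expect_lt(max(abs(fit$u)), 1e-4)
})

test_that("shrinkage limit: huge residual variance sends EBVs to zero", {
  ped <- random_pedigree(30, seed = 5)
  d <- mvn_records(ped, Su = diag(c(1, 100)), Sf = diag(c(0.2, 20)),
                   Se = diag(c(2, 200)), seed = 5)
  spec <- model_spec(c("fy", "bw"), list(fy = ~ 1, bw = ~ 1), family = FALSE)
  vc <- vc_components(Su = diag(c(1, 100)), Se = diag(c(1e8, 1e10)))
  fit <- solve_mme(build_mme(mme_structure(spec, d, build_A_inverse(ped)), vc))
  expect_lt(max(abs(fit$u[, 1])), 1e-3)
})

test_that("a trait with no records carries only prior terms and zero EBVs", {
  ped <- random_pedigree(25, seed = 7)
  d <- mvn_records(ped, Su = diag(c(1, 100)), Sf = diag(c(0.2, 20)),
                   Se = diag(c(2, 200)), seed = 7, fy_missing = 1)
  spec <- model_spec(c("fy", "bw"), list(fy = ~ 1, bw = ~ 1), family = TRUE)
  vc <- vc_components(Su = diag(c(1, 100)), Sf = diag(c(0.2, 20)),
                      Se = diag(c(2, 200)))
  str <- mme_structure(spec, d, build_A_inverse(ped))
  expect_equal(str$p[["fy"]], 0L)      # no estimable fixed effects
  fit <- solve_mme(build_mme(str, vc))
  expect_lt(max(abs(fit$u[, "fy"])), 1e-10)
})

test_that("sparse MME solution equals the dense GLS oracle (two traits, family)", {
  ped <- random_pedigree(100, seed = 11)
  Su <- matrix(c(1, 0.3 * sqrt(100), 0.3 * sqrt(100), 100), 2)
  Sf <- diag(c(0.2, 20)); Se <- matrix(c(2, 8, 8, 200), 2)
  d <- mvn_records(ped, Su, Sf, Se, seed = 11, n_fam = 10)
  spec <- trout_model_spec()
  vc <- vc_components(Su, Sf, Se)
  str <- mme_structure(spec, d, build_A_inverse(ped))
  sys <- build_mme(str, vc)
  fit <- solve_mme(sys)
  # dense oracle: build V record-wise and solve GLS + BLUP identities
  A <- build_A(ped)
  n_fam <- str$n_fam
  nl <- str$n_long
  Zu <- matrix(0, nl, 2 * ped$n); Zf <- matrix(0, nl, 2 * n_fam)
  Xl <- matrix(0, nl, sum(str$p))
  for (t in 1:2) {
    rows <- which(str$long_trait == t)
    rec <- str$long_rec[rows]
    Zu[cbind(rows, (t - 1) * ped$n + str$anim_idx[rec])] <- 1
    Zf[cbind(rows, (t - 1) * n_fam + str$fam_idx[rec])] <- 1
    Xl[rows, (str$off_b[t] + 1):(str$off_b[t] + str$p[t])] <-
      str$X[[t]][rec, , drop = FALSE]
  }
  R <- matrix(0, nl, nl)
  for (r in seq_len(str$n_rec)) for (a in 1:2) for (b in 1:2) {
    ia <- str$idx_long[r, a]; ib <- str$idx_long[r, b]
    if (!is.na(ia) && !is.na(ib)) R[ia, ib] <- Se[a, b]
  }
  Gu <- kronecker(Su, A); Gf <- kronecker(Sf, diag(n_fam))
  V <- Zu %*% Gu %*% t(Zu) + Zf %*% Gf %*% t(Zf) + R
  Vi <- solve(V)
  y <- str$y_long
  b_hat <- solve(t(Xl) %*% Vi %*% Xl, t(Xl) %*% Vi %*% y)
  resid <- Vi %*% (y - Xl %*% b_hat)
  u_hat <- Gu %*% t(Zu) %*% resid
  f_hat <- Gf %*% t(Zf) %*% resid
  expect_lt(max(abs(fit$sol[1:sum(str$p)] - b_hat)), 1e-8)
  expect_lt(max(abs(c(fit$u) - c(u_hat))), 1e-8)
  expect_lt(max(abs(c(fit$f) - c(f_hat))), 1e-8)
})

test_that("direct and conjugate-gradient solvers agree", {
  ped <- random_pedigree(80, seed = 13)
  d <- mvn_records(ped, diag(c(1, 100)), diag(c(0.2, 20)), diag(c(2, 200)),
                   seed = 13)
  spec <- trout_model_spec()
  vc <- vc_components(diag(c(1, 100)), diag(c(0.2, 20)), diag(c(2, 200)))
  sys <- build_mme(mme_structure(spec, d, build_A_inverse(ped)), vc)
  fit_d <- solve_mme(sys, method = "direct")
  fit_cg <- solve_mme(sys, method = "cg", tol = 1e-12)
  expect_lt(max(abs(fit_d$sol - fit_cg$sol)), 1e-6)
})

test_that("permuting record order permutes nothing in the solutions", {
  ped <- random_pedigree(40, seed = 17)
  d <- mvn_records(ped, diag(c(1, 100)), diag(c(0.2, 20)), diag(c(2, 200)),
                   seed = 17)
  spec <- trout_model_spec()
  vc <- vc_components(diag(c(1, 100)), diag(c(0.2, 20)), diag(c(2, 200)))
  fit1 <- solve_mme(build_mme(mme_structure(spec, d, build_A_inverse(ped)), vc))
  d2 <- d[sample(nrow(d)), ]
  fit2 <- solve_mme(build_mme(mme_structure(spec, d2, build_A_inverse(ped)), vc))
  expect_equal(fit1$u, fit2$u, tolerance = 1e-9)
})

test_that("ssGBLUP with no genotyped animals reproduces PBLUP bit for bit", {
  ped <- random_pedigree(40, seed = 19)
  d <- mvn_records(ped, diag(c(1, 100)), diag(c(0.2, 20)), diag(c(2, 200)),
                   seed = 19)
  spec <- trout_model_spec()
  vc <- vc_components(diag(c(1, 100)), diag(c(0.2, 20)), diag(c(2, 200)))
  A_inv <- build_A_inverse(ped)
  H_inv <- build_H_inverse(A_inv)            # empty correction
  fit_a <- solve_mme(build_mme(mme_structure(spec, d, A_inv), vc))
  fit_h <- solve_mme(build_mme(mme_structure(spec, d, H_inv), vc))
  expect_identical(fit_a$sol, fit_h$sol)
})

test_that("adjusted phenotypes remove fixed and family parts", {
  # hand case: y = 5, fixed part 2, family effect 1 -> y* = 2
  ped <- renumber_pedigree(data.frame(animal = c("a", "b", "c", "d"),
                                      sire = "0", dam = "0"))
  d <- data.frame(animal = c("a", "b", "c", "d"),
                  family = c("f1", "f1", "f2", "f2"),
                  fy = c(5, 4, 3, 6), stringsAsFactors = FALSE)
  spec <- model_spec("fy", list(fy = ~ 1), family = TRUE)
  vc <- vc_components(Su = matrix(0.5), Sf = matrix(0.3), Se = matrix(1))
  fit <- solve_mme(build_mme(mme_structure(spec, d, build_A_inverse(ped)), vc))
  ystar <- adjust_phenotypes(fit)
  manual <- d$fy - fit$b$fy[1] - fit$f[d$family, 1]
  expect_equal(unname(ystar[, 1]), unname(manual))
  # no-family model: y* = y - Xb
  spec2 <- model_spec("fy", list(fy = ~ 1), family = FALSE)
  vc2 <- vc_components(Su = matrix(0.5), Se = matrix(1))
  fit2 <- solve_mme(build_mme(mme_structure(spec2, d, build_A_inverse(ped)), vc2))
  expect_equal(unname(adjust_phenotypes(fit2)[, 1]),
               d$fy - unname(fit2$b$fy[1]))
})
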