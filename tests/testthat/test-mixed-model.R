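test_that("weaning weight adjustment follows the 90-day gain formula", {
  expect_equal(adjust_weaning_weight(22, 4, 100), 16.2)
  # at age 90 the adjustment is daily gain times 90
  expect_equal(adjust_weaning_weight(22, 4, 90), 18)
  g <- 0.27
  expect_equal(adjust_weaning_weight(4 + g * 90, 4, 90), g * 90)
  expect_equal(adjust_weaning_weight(4, 4, 50), 0)
  expect_error(adjust_weaning_weight(22, 4, 0), "positive")
})

test_that("build_design produces one-hot random-effect incidence", {
  ped <- trio_pedigree()
  ph <- data.frame(animal = "O", dam = "D", sex = "M", birth_type = "1",
                   herd = "h1", birth_year = "y1", dam_age = "2",
                   trait = 3.2)
  des <- build_design(ph, ped)
  # all fixed effects constant -> intercept only
  expect_equal(ncol(des$X), 1L)
  expect_equal(as.numeric(des$Z_a[1, ]), as.numeric(des$animal_ids == "O"))
  expect_equal(as.numeric(des$S_m[1, ]), as.numeric(des$animal_ids == "D"))
  expect_equal(dim(des$W_p), c(1L, 1L))
  expect_identical(des$dam_ids, "D")
  # full-rank dummy coding: intercept + (2-1) + (3-1) columns
  ph2 <- data.frame(animal = rep("O", 6), dam = "D",
                    sex = rep(c("M", "F"), 3),
                    birth_type = rep(c("1", "2", "3"), 2),
                    herd = "h", birth_year = "y", dam_age = "1",
                    trait = rnorm(6))
  des2 <- build_design(ph2, ped, fixed = c("sex", "birth_type"))
  expect_equal(ncol(des2$X), 4L)
  # every row of the incidence matrices has exactly one 1
  expect_true(all(Matrix::rowSums(des2$Z_a) == 1))
  expect_true(all(Matrix::rowSums(des2$S_m) == 1))
  expect_true(all(Matrix::rowSums(des2$W_p) == 1))
  # dam must be known
  ph3 <- ph; ph3$dam <- "0"
  expect_error(build_design(ph3, ped), "dam")
})

test_that("solve_mme matches a dense GLS oracle on a small dataset", {
  sm <- small_dataset(seed = 7)
  ped <- sm$ds$ped
  des <- build_design(sm$ds$phenos, ped)
  Ai <- build_A_inverse(ped)
  vc <- variance_components(2, 1, 0.5, 4)
  fit <- solve_mme(des, Ai, vc)
  A <- build_A(ped)
  Za <- as.matrix(des$Z_a); S <- as.matrix(des$S_m)
  W <- as.matrix(des$W_p); X <- des$X; y <- des$y
  V <- Za %*% A %*% t(Za) * vc$sigma2_a + S %*% A %*% t(S) * vc$sigma2_m +
    W %*% t(W) * vc$sigma2_p + diag(length(y)) * vc$sigma2_e
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  Py <- Vi %*% (y - X %*% b)
  expect_lt(max(abs(fit$fixed - b)), 1e-6)
  expect_lt(max(abs(fit$a_hat - vc$sigma2_a * A %*% t(Za) %*% Py)), 1e-6)
  expect_lt(max(abs(fit$m_hat - vc$sigma2_m * A %*% t(S) %*% Py)), 1e-6)
  expect_lt(max(abs(fit$p_hat - vc$sigma2_p * t(W) %*% Py)), 1e-6)
  # residuals orthogonal to the fixed-effect columns
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-6)
})

test_that("extreme shrinkage drives breeding values to zero", {
  sm <- small_dataset(seed = 8)
  des <- build_design(sm$ds$phenos, sm$ds$ped)
  Ai <- build_A_inverse(sm$ds$ped)
  fit <- solve_mme(des, Ai, variance_components(1e-8, 1e-8, 1e-8, 1))
  expect_lt(max(abs(fit$a_hat)), 1e-4)
  expect_lt(max(abs(fit$m_hat)), 1e-4)
})

test_that("H-inverse MME with G_omega = A22 equals pedigree BLUP", {
  sm <- small_dataset(seed = 9, n_founders = 30, n_matings = 15)
  ped <- sm$ds$ped
  des <- build_design(sm$ds$phenos, ped)
  Ai <- build_A_inverse(ped)
  gids <- sample(ped$animal, 12)
  A22 <- extract_A22(build_A(ped), gids)
  Hi <- build_H_inverse(Ai, g_omega = A22, a22 = A22, genotyped_ids = gids)
  vc <- variance_components(2, 1, 0.5, 4)
  fa <- solve_mme(des, Ai, vc)
  fh <- solve_mme(des, Hi, vc)
  expect_lt(max(abs(fa$a_hat - fh$a_hat)), 1e-8)
  expect_lt(max(abs(fa$m_hat - fh$m_hat)), 1e-8)
  expect_lt(max(abs(fa$fixed - fh$fixed)), 1e-8)
})

test_that("REML likelihood from the MME equals the dense-V likelihood", {
  sm <- small_dataset(seed = 10)
  ped <- sm$ds$ped
  des <- build_design(sm$ds$phenos, ped)
  Ai <- build_A_inverse(ped)
  A <- build_A(ped)
  for (vcv in list(c(2, 1, 0.5, 4), c(1, 1, 1, 1), c(3, 0.2, 0.1, 2))) {
    vc <- variance_components(vcv[1], vcv[2], vcv[3], vcv[4])
    Za <- as.matrix(des$Z_a); S <- as.matrix(des$S_m)
    W <- as.matrix(des$W_p); X <- des$X; y <- des$y
    V <- Za %*% A %*% t(Za) * vc$sigma2_a + S %*% A %*% t(S) * vc$sigma2_m +
      W %*% t(W) * vc$sigma2_p + diag(length(y)) * vc$sigma2_e
    Vi <- solve(V)
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    m2ll <- determinant(V)$modulus +
      determinant(t(X) %*% Vi %*% X)$modulus + t(r) %*% Vi %*% r
    expect_equal(reml_loglik(des, Ai, vc), -0.5 * as.numeric(m2ll),
                 tolerance = 1e-8)
  }
})

test_that("EM-REML increases the restricted likelihood monotonically", {
  sm <- small_dataset(seed = 12, n_founders = 30, n_matings = 15,
                      offspring = 3)
  des <- build_design(sm$ds$phenos, sm$ds$ped)
  Ai <- build_A_inverse(sm$ds$ped)
  fit <- suppressWarnings(
    estimate_varcomps_reml(des, Ai, method = "em", max_iter = 25,
                           tol = 1e-10))
  lls <- fit$trace$loglik
  expect_true(all(diff(lls) > -1e-6))
  expect_true(all(fit$trace$step == "em"))
})

test_that("AI-REML reaches a stationary point of the dense likelihood", {
  sm <- small_dataset(seed = 13, n_founders = 60, n_matings = 30,
                      offspring = 4)
  des <- build_design(sm$ds$phenos, sm$ds$ped)
  Ai <- build_A_inverse(sm$ds$ped)
  fit <- suppressWarnings(
    estimate_varcomps_reml(des, Ai, method = "ai", max_iter = 100,
                           tol = 1e-8))
  ll0 <- reml_loglik(des, Ai, fit)
  # perturbing any component in either direction cannot raise the
  # likelihood by more than numerical tolerance
  for (comp in c("sigma2_a", "sigma2_m", "sigma2_p", "sigma2_e")) {
    for (fac in c(0.98, 1.02)) {
      vc2 <- fit
      vc2[[comp]] <- fit[[comp]] * fac
      vc2 <- variance_components(vc2$sigma2_a, vc2$sigma2_m, vc2$sigma2_p,
                                 vc2$sigma2_e)
      expect_lt(reml_loglik(des, Ai, vc2), ll0 + 1e-4)
    }
  }
})

test_that("REML estimates scale with the square of the data scale", {
  sm <- small_dataset(seed = 14, n_founders = 30, n_matings = 15,
                      offspring = 3)
  des1 <- build_design(sm$ds$phenos, sm$ds$ped)
  ph2 <- sm$ds$phenos
  ph2$trait <- ph2$trait * 3
  des2 <- build_design(ph2, sm$ds$ped)
  Ai <- build_A_inverse(sm$ds$ped)
  f1 <- suppressWarnings(estimate_varcomps_reml(des1, Ai, max_iter = 40,
                                                tol = 1e-6))
  f2 <- suppressWarnings(estimate_varcomps_reml(des2, Ai, max_iter = 40,
                                                tol = 1e-6))
  expect_equal(f2$sigma2_a, 9 * f1$sigma2_a, tolerance = 1e-3)
  expect_equal(f2$sigma2_e, 9 * f1$sigma2_e, tolerance = 1e-3)
})
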