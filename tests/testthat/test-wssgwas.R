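test_that("backsolve reproduces GEBVs when Z is square and unblended", {
  set.seed(21)
  n <- 12
  p <- runif(n, 0.2, 0.8)
  counts <- matrix(rbinom(n * n, 2, p), n, n)
  # centering by reference (not observed) frequencies keeps Z full rank;
  # observed-frequency centering always leaves the ones vector in the
  # null space of Z'
  f <- p
  Z <- sweep(counts, 2, 2 * f, `-`)
  lam <- 1 / sum(2 * f * (1 - f))
  d <- rep(1, n)
  G <- build_G(Z, d, f)
  gebv <- rnorm(n)
  u <- backsolve_snp_effects(Z, d, G, gebv, lam)
  expect_lt(max(abs(Z %*% u - gebv)), 1e-8)
  expect_equal(unname(backsolve_snp_effects(Z, d, G, rep(0, n), lam)),
               rep(0, n))
})

test_that("backsolve matches an independent dense-algebra evaluation", {
  set.seed(22)
  n <- 15; m <- 30
  counts <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)), n, m)
  f <- colMeans(counts) / 2
  Z <- sweep(counts, 2, 2 * f, `-`)
  lam <- 1 / sum(2 * f * (1 - f))
  d <- runif(m, 0.5, 2)
  G <- build_G(Z, d, f)
  A22 <- diag(n) + 0.1
  Gw <- 0.95 * G + 0.05 * A22
  gebv <- rnorm(n)
  u <- backsolve_snp_effects(Z, d, Gw, gebv, lam)
  oracle <- lam * diag(d) %*% t(Z) %*% solve(Gw) %*% gebv
  expect_lt(max(abs(u - oracle)), 1e-10)
})

test_that("nonlinearA weights follow the capped power rule", {
  # construct effects with sd 1 and chosen |u|/sd values
  u <- c(-10, -1, 0, 1, 10)
  s <- sd(u)
  w <- nonlinearA_weights(u)
  expect_equal(unname(w), 1.125^(pmin(abs(u) / s, 7) - 2))
  # exact anchor points: this vector has sd exactly 1, so the elements at
  # |u|/sd = 2, 1 and 0 get weights 1, 1.125^-1 and 1.125^-2
  u1 <- c(2, -2, 1, -1, rep(0, 7))
  stopifnot(sd(u1) == 1)
  w1 <- nonlinearA_weights(u1)
  expect_identical(unname(w1[1]), 1)
  expect_equal(unname(w1[3]), 1.125^-1)
  expect_equal(unname(w1[5]), 1.125^-2)
  expect_equal(unname(w1[5]), 0.790123, tolerance = 1e-6)
  # a lone outlier among 100 zeros sits above the cap: weight 1.125^5
  u2 <- c(1e8, rep(0, 99))
  wc <- nonlinearA_weights(u2)
  expect_equal(unname(wc[1]), 1.125^5)
  expect_equal(unname(wc[1]), 1.802032, tolerance = 1e-6)
  expect_warning(w0 <- nonlinearA_weights(rep(1, 4)), "unit weights")
  expect_equal(unname(w0), rep(1, 4))
  # strictly increasing in |u| below the cap
  uu <- seq(0, 6, by = 0.5)
  ww <- nonlinearA_weights(c(uu, -uu))  # symmetric set, sd fixed
  expect_true(all(diff(ww[seq_along(uu)]) >= 0))
})

test_that("weight normalization preserves the trace", {
  d_prev <- c(1, 1, 1, 1)
  d_new <- c(2, 1, 1, 0.5)
  out <- normalize_weights(d_new, d_prev)
  expect_equal(out, c(16, 8, 8, 4) / 9)
  expect_equal(sum(out), 4)
  expect_equal(normalize_weights(2 * d_prev, d_prev), d_prev)
  expect_equal(normalize_weights(d_prev * 1, d_prev), d_prev)
  expect_error(normalize_weights(c(0, 0), c(1, 1)), "sum")
})

test_that("window variance bins are exclusive, exhaustive and exact", {
  set.seed(23)
  n <- 40; m <- 25
  counts <- matrix(rbinom(n * m, 2, 0.4), n, m)
  chr <- rep(c(1L, 2L), c(15, 10))
  pos <- c(sort(sample.int(3e6, 15)), sort(sample.int(2e6, 10)))
  g <- toy_genotypes(counts, chr = chr, pos = pos)
  f <- allele_frequencies(g)
  Z <- center_gene_content(g, f)
  u <- rnorm(m)
  wt <- window_variance(u, Z, g$map, 1e6, denom_variance = 2)
  # every SNP in exactly one window
  expect_equal(sum(wt$n_snps), m)
  expect_true(all(wt$first_snp_bp >= wt$window_start))
  expect_true(all(wt$last_snp_bp <= wt$window_end))
  key <- paste(wt$chr, wt$window_start)
  expect_false(anyDuplicated(key) > 0)
  # window arithmetic: bin k covers ((k-1)e6, k*1e6]
  expect_true(all((wt$window_start - 1) %% 1e6 == 0))
  # zero effects give zero percentages
  wt0 <- window_variance(rep(0, m), Z, g$map, 1e6, 2)
  expect_equal(wt0$pct_variance, rep(0, nrow(wt0)))
  # single SNP alone in its window
  g1 <- toy_genotypes(counts[, 1, drop = FALSE], chr = 1L, pos = 5e5)
  wt1 <- window_variance(c(3), Z[, 1, drop = FALSE], g1$map, 1e6, 2)
  expect_equal(wt1$pct_variance, 100 * 9 * var(Z[, 1]) / 2)
  # whole genome in one window matches the dense computation
  gall <- toy_genotypes(counts, chr = rep(1L, m),
                        pos = seq_len(m) * 1000)
  wtall <- window_variance(u, Z, gall$map, 1e6, 2)
  expect_equal(nrow(wtall), 1L)
  expect_equal(wtall$pct_variance, 100 * var(as.numeric(Z %*% u)) / 2,
               tolerance = 1e-12)
})

test_that("top_windows ranks by percentage with genome-order ties", {
  wt <- data.frame(chr = c(1, 1, 2, 3), window_start = c(1, 1e6 + 1, 1, 1),
                   window_end = c(1e6, 2e6, 1e6, 1e6),
                   first_snp_bp = 1, last_snp_bp = 2, n_snps = 1,
                   pct_variance = c(0.2, 0.8, 0.2, 0.5))
  top <- top_windows(wt, 1)
  expect_equal(top$pct_variance, 0.8)
  top3 <- top_windows(wt, 3)
  expect_equal(top3$pct_variance, c(0.8, 0.5, 0.2))
  expect_equal(top3$chr[3], 1)  # tie at 0.2 broken by chromosome
  expect_warning(all4 <- top_windows(wt, 10), "exceeds")
  expect_equal(nrow(all4), 4L)
  # equal percentages return genome order
  wte <- wt; wte$pct_variance <- 1
  expect_equal(top_windows(wte, 2)$chr, c(1, 1))
})

test_that("permuting SNP order permutes effects identically", {
  set.seed(24)
  n <- 20; m <- 16
  counts <- matrix(rbinom(n * m, 2, 0.5), n, m)
  g <- toy_genotypes(counts)
  f <- allele_frequencies(g)
  Z <- center_gene_content(g, f)
  lam <- 1 / sum(2 * f * (1 - f))
  d <- runif(m, 0.5, 2)
  G <- build_G(Z, d, f)
  Gw <- 0.95 * G + 0.05 * (diag(n) + 0.05)
  gebv <- rnorm(n)
  u <- backsolve_snp_effects(Z, d, Gw, gebv, lam)
  perm <- sample(m)
  u_p <- backsolve_snp_effects(Z[, perm], d[perm], Gw, gebv, lam)
  expect_equal(unname(u_p), unname(u[perm]), tolerance = 1e-12)
  expect_equal(unname(nonlinearA_weights(u_p)),
               unname(nonlinearA_weights(u)[perm]))
})

test_that("full-rank unblended runs satisfy the reconstruction identity", {
  # n = m fixture with alpha = 1 and reference-frequency centering:
  # Z u must equal a_g at every iteration
  sm <- small_dataset(seed = 25, n_snps = 24,
                      genotyped_fraction_last_gen = 0.6)
  ds <- sm$ds
  geno <- ds$geno
  ng <- nrow(geno$counts)
  keep <- seq_len(ng)  # exactly n genotyped = m SNPs
  geno <- genotypes(geno$counts[, keep], geno$sample_ids, geno$map[keep, ])
  freqs <- attr(ds$geno, "founder_freq")[keep]
  fit <- run_wssgwas(ds$phenos, ds$ped, geno,
                     variance_components(2, 1, 0.5, 4),
                     alpha = 1, beta = 0, n_iter = 3, freqs = freqs)
  Z <- center_gene_content(geno, freqs)
  for (it in fit$iterations) {
    ag <- it$fit$a_hat[fit$genotyped_ids]
    expect_lt(max(abs(Z %*% it$u_direct - ag)), 1e-6)
    mg <- it$fit$m_hat[fit$genotyped_ids]
    expect_lt(max(abs(Z %*% it$u_maternal - mg)), 1e-6)
    expect_lt(abs(sum(it$weights) - ncol(Z)), 1e-8)
  }
})

test_that("iteration 1 with unit weights is the unweighted ssGWAS", {
  sm <- small_dataset(seed = 26)
  ds <- sm$ds
  geno <- impute_missing(apply_qc(ds$geno)$genotypes, seed = 26)
  vc <- variance_components(2, 1, 0.5, 4)
  f3 <- run_wssgwas(ds$phenos, ds$ped, geno, vc, n_iter = 3)
  f1 <- run_wssgwas(ds$phenos, ds$ped, geno, vc, n_iter = 1)
  expect_equal(f3$iterations[[1]]$u_direct, f1$iterations[[1]]$u_direct)
  expect_equal(f3$iterations[[1]]$weights, rep(1, ncol(geno$counts)))
  # weight trace is conserved across iterations
  m <- ncol(geno$counts)
  for (it in f3$iterations) expect_lt(abs(sum(it$weights) - m), 1e-8)
})
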