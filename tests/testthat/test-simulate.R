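test_that("simulate_pedigree builds discrete generations deterministically", {
  cfg <- sim_config(n_founders = 40, n_generations = 3, n_matings = 10,
                    offspring_per_mating = 2, n_snps = 10, seed = 31)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 40 + 3 * 20)
  gen <- attr(ped, "generation")
  idx <- list(sire = match(ped$sire, ped$animal),
              dam = match(ped$dam, ped$animal))
  nonf <- which(!is.na(idx$sire))
  # both parents exactly one generation earlier, no selfing
  expect_true(all(gen[idx$sire[nonf]] == gen[nonf] - 1))
  expect_true(all(gen[idx$dam[nonf]] == gen[nonf] - 1))
  expect_true(all(ped$sire[nonf] != ped$dam[nonf]))
  # determinism
  expect_identical(simulate_pedigree(cfg)$animal, ped$animal)
  # zero generations leaves founders only
  cfg0 <- sim_config(n_founders = 10, n_generations = 0, n_snps = 10,
                     seed = 1)
  expect_equal(nrow(simulate_pedigree(cfg0)), 10)
})

test_that("gene dropping respects Mendelian inheritance and frequencies", {
  cfg <- sim_config(n_founders = 200, n_generations = 1, n_matings = 50,
                    offspring_per_mating = 2, n_snps = 60,
                    n_chromosomes = 3, seed = 32)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  expect_equal(dim(g$counts), c(nrow(ped), 60))
  expect_false(anyNA(g$counts))
  # offspring count lies within what the parents can transmit
  idx <- list(sire = match(ped$sire, ped$animal),
              dam = match(ped$dam, ped$animal))
  for (i in which(!is.na(idx$sire))[1:20]) {
    lo <- pmax(0, (g$counts[idx$sire[i], ] > 1) + (g$counts[idx$dam[i], ] > 1))
    hi <- pmin(2, (g$counts[idx$sire[i], ] > 0) + (g$counts[idx$dam[i], ] > 0))
    expect_true(all(g$counts[i, ] >= lo & g$counts[i, ] <= hi))
  }
  # founder frequencies track the drawn values within 3 binomial SEs
  pf <- attr(g, "founder_freq")
  fo <- which(is.na(ped$sire))
  emp <- colMeans(g$counts[fo, ]) / 2
  se <- sqrt(pf * (1 - pf) / (2 * length(fo)))
  expect_true(all(abs(emp - pf) <= 3 * se + 1e-9))
  # degenerate frequency range
  cfg5 <- sim_config(n_founders = 50, n_generations = 0, n_matings = 1,
                     n_snps = 30, maf_range = c(0.5, 0.5), seed = 3)
  g5 <- simulate_genotypes(simulate_pedigree(cfg5), cfg5)
  expect_true(all(abs(attr(g5, "founder_freq") - 0.5) < 1e-12))
  # map positions strictly increasing within chromosome
  expect_true(all(unlist(tapply(g$map$pos_bp, g$map$chr,
                                function(x) diff(x) > 0))))
})

test_that("phenotypes decompose into the simulated effects", {
  # all variances zero-ish and no QTL: y equals the fixed-effect sum
  cfg <- sim_config(n_founders = 20, n_generations = 2, n_matings = 8,
                    offspring_per_mating = 2, n_snps = 12,
                    n_qtl_direct = 0, n_qtl_maternal = 0, prop_var_qtl = 0,
                    vc = variance_components(1e-12, 1e-12, 1e-12, 1e-12),
                    seed = 33)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  sim <- simulate_phenotypes(ped, g, cfg)
  expect_equal(nrow(sim$phenos), 2 * 8 * 2)
  # reconstruct the fixed part by regression: residual variance ~ 0
  fitlm <- lm(trait ~ sex + birth_type + herd + birth_year + dam_age,
              data = sim$phenos)
  expect_lt(summary(fitlm)$sigma, 1e-4)
  # founders carry no record
  expect_false(any(sim$phenos$animal %in%
                     ped$animal[is.na(ped$sire) & is.na(ped$dam)]))
})

test_that("realized genetic variances are near their targets", {
  cfg <- sim_config(n_founders = 500, n_generations = 3, n_matings = 250,
                    offspring_per_mating = 3, n_snps = 400,
                    n_chromosomes = 2, seed = 34)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  sim <- simulate_phenotypes(ped, g, cfg)
  expect_gt(sim$truth$realized["var_a"] / cfg$vc$sigma2_a, 0.75)
  expect_lt(sim$truth$realized["var_a"] / cfg$vc$sigma2_a, 1.25)
  expect_gt(sim$truth$realized["var_m"] / cfg$vc$sigma2_m, 0.75)
  expect_lt(sim$truth$realized["var_m"] / cfg$vc$sigma2_m, 1.25)
  # offspring true_a regresses on mid-parent with slope near 1
  idx <- list(sire = match(ped$sire, ped$animal),
              dam = match(ped$dam, ped$animal))
  nonf <- which(!is.na(idx$sire))
  mp <- 0.5 * (sim$truth$true_a[idx$sire[nonf]] +
                 sim$truth$true_a[idx$dam[nonf]])
  sl <- coef(lm(sim$truth$true_a[nonf] ~ mp))[2]
  expect_lt(abs(sl - 1), 0.1)
})

test_that("released dataset masks genotypes only for the last generation", {
  cfg <- sim_config(n_founders = 40, n_generations = 2, n_matings = 10,
                    offspring_per_mating = 2, n_snps = 50,
                    genotyped_fraction_last_gen = 0.5,
                    missing_rate = 0.05, seed = 35)
  ds <- simulate_dataset(cfg)
  gen <- attr(ds$ped, "generation")
  expect_equal(nrow(ds$geno$counts), 10)
  expect_true(all(gen[match(ds$geno$sample_ids, ds$ped$animal)] == 2))
  expect_gt(mean(is.na(ds$geno$counts)), 0)
  expect_false(anyNA(ds$geno_full$counts))
  # released counts agree with the internal matrix where observed
  obs <- !is.na(ds$geno$counts)
  full <- ds$geno_full$counts[ds$geno$sample_ids, ]
  expect_true(all(ds$geno$counts[obs] == full[obs]))
})
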