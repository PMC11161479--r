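# Shared fixtures, all built in code.

# unrelated sire/dam with one offspring
trio_pedigree <- function() {
  sort_pedigree(pedigree(c("S", "D", "O"), c(NA, NA, "S"), c(NA, NA, "D")))
}

# mating of two full sibs: X is inbred with F = 0.25
fullsib_pedigree <- function() {
  sort_pedigree(pedigree(c("S", "D", "B1", "B2", "X"),
                         c(NA, NA, "S", "S", "B1"),
                         c(NA, NA, "D", "D", "B2")))
}

# random pedigree: n_founders founders then random parent pairs among
# earlier animals (no selfing)
random_pedigree <- function(n, n_founders = 20, seed = 1) {
  stopifnot(n > n_founders)
  set.seed(seed)
  id <- sprintf("a%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    pr <- sample(seq_len(i - 1L), 2L)
    sire[i] <- id[pr[1]]
    dam[i] <- id[pr[2]]
  }
  sort_pedigree(pedigree(id, sire, dam))
}

# gene-dropping Monte Carlo estimate of A over a small pedigree:
# founders carry unique allele labels; A_ij = 2 * P(random alleles IBD),
# A_ii = 1 + P(the two own alleles IBD).  Returns estimate and MC SEs.
gene_drop_A <- function(ped, n_rep = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  M1 <- matrix(0L, n_rep, n)
  M2 <- matrix(0L, n_rep, n)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      M1[, i] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_rep) < 0.5
      M1[, i] <- ifelse(pick, M1[, si[i]], M2[, si[i]])
    }
    if (is.na(di[i])) {
      M2[, i] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_rep) < 0.5
      M2[, i] <- ifelse(pick, M1[, di[i]], M2[, di[i]])
    }
  }
  est <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  se <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    for (j in i:n) {
      per_rep <- if (i == j) {
        1 + (M1[, i] == M2[, i])
      } else {
        0.5 * ((M1[, i] == M1[, j]) + (M1[, i] == M2[, j]) +
                 (M2[, i] == M1[, j]) + (M2[, i] == M2[, j]))
      }
      est[i, j] <- est[j, i] <- mean(per_rep)
      se[i, j] <- se[j, i] <- stats::sd(per_rep) / sqrt(n_rep)
    }
  }
  list(A = est, se = se)
}

# exact HWE tail probability by direct enumeration: multinomial count of
# genotype configurations over the hypergeometric count of allele splits;
# independent of the lgamma-based hwe_exact_p
hwe_brute_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  rare <- min(nA, 2 * n - nA)
  hs <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hs, function(h) {
    nhr <- (rare - h) / 2
    nhc <- n - nhr - h
    factorial(n) / (factorial(nhr) * factorial(h) * factorial(nhc)) *
      2^h / choose(2 * n, rare)
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_Aa, hs)] * (1 + 1e-12)])
}

# genotype object from a counts matrix with evenly spaced positions
toy_genotypes <- function(counts, chr = NULL, pos = NULL) {
  m <- ncol(counts)
  map <- data.frame(snp_id = sprintf("s%03d", seq_len(m)),
                    chr = chr %||% rep(1L, m),
                    pos_bp = pos %||% seq(1e5, by = 1e5, length.out = m))
  genotypes(counts, rownames(counts) %||% sprintf("i%03d", seq_len(nrow(counts))),
            map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small complete dataset for MME-level tests
small_dataset <- function(seed = 7, n_founders = 20, n_generations = 2,
                          n_matings = 10, offspring = 2, n_snps = 40,
                          ...) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                    n_matings = n_matings,
                    offspring_per_mating = offspring, n_snps = n_snps,
                    n_chromosomes = 2, missing_rate = 0, seed = seed, ...)
  list(cfg = cfg, ds = simulate_dataset(cfg))
}
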