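#' Simulation configuration
#'
#' Defines the desk-scale study the generator emulates: a multi-generation
#' pedigree where every animal is phenotyped but only a fraction of the last
#' generation is genotyped, direct and maternal QTL embedded among neutral
#' unlinked SNPs, and the four variance components of the maternal-effects
#' animal model.  The default preset is 400 founders plus 4 discrete
#' generations of 100 matings x 4 offspring (2,000 animals; every dam
#' raises 4 recorded progeny, which is what identifies the maternal
#' permanent-environment variance), 5,000 SNPs on 5 chromosomes of 100 Mb,
#' and 75% of the last generation genotyped (300 animals).
#'
#' @param n_founders even number of founders (half male, half female).
#' @param n_generations number of discrete offspring generations.
#' @param n_matings matings per generation.
#' @param offspring_per_mating offspring per mating.
#' @param n_snps,n_chromosomes,chrom_length_bp marker panel layout.
#' @param maf_range founder allele-frequency range (uniform draw).
#' @param n_qtl_direct,n_qtl_maternal number of QTL per effect type.
#' @param prop_var_qtl proportion of each genetic variance due to QTL.
#' @param vc true [variance_components()].
#' @param fixed_effect_levels named integer vector: number of levels per
#'   fixed effect.
#' @param fixed_effect_sd standard deviation (kg) of the level effects.
#' @param genotyped_fraction_last_gen fraction of the last generation whose
#'   genotypes are released.
#' @param missing_rate genotype missingness applied to released data.
#' @param seed integer seed driving everything.
#' @return List of class \code{"sim_config"}.
#' @export
sim_config <- function(n_founders = 400, n_generations = 4, n_matings = 100,
                       offspring_per_mating = 4, n_snps = 5000,
                       n_chromosomes = 5, chrom_length_bp = 1e8,
                       maf_range = c(0.05, 0.5),
                       n_qtl_direct = 5, n_qtl_maternal = 5,
                       prop_var_qtl = 0.5,
                       vc = variance_components(2, 1, 0.5, 4),
                       fixed_effect_levels = c(sex = 2, birth_type = 2,
                                               herd = 4, birth_year = 0,
                                               dam_age = 3),
                       fixed_effect_sd = 1,
                       genotyped_fraction_last_gen = 0.75,
                       missing_rate = 0.01, seed = 1) {
  if (n_founders %% 2 != 0) stop("n_founders must be even")
  if (any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie in (0, 0.5] with lo <= hi")
  if (prop_var_qtl < 0 || prop_var_qtl > 1)
    stop("prop_var_qtl must lie in [0, 1]")
  if (n_qtl_direct + n_qtl_maternal > n_snps)
    stop("more QTL than SNPs")
  if (!inherits(vc, "varcomps")) stop("vc must be variance_components()")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a discrete-generation pedigree
#'
#' Founders are half males, half females; each generation draws
#' \code{n_matings} sire/dam pairs at random (no selfing, parents from the
#' previous generation only) with \code{offspring_per_mating} offspring of
#' random sex each.  Deterministic given \code{cfg$seed}.
#'
#' @param cfg a [sim_config()].
#' @return A sorted [pedigree()] with attributes \code{"sex"} (named "M"/"F"
#'   vector) and \code{"generation"} (named integer vector, founders = 0).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    id <- sprintf("F%04d", seq_len(cfg$n_founders))
    sire <- rep(NA_character_, cfg$n_founders)
    dam <- rep(NA_character_, cfg$n_founders)
    sex <- rep(c("M", "F"), length.out = cfg$n_founders)
    gen <- rep(0L, cfg$n_founders)
    prev <- id
    prev_sex <- sex
    for (g in seq_len(cfg$n_generations)) {
      males <- prev[prev_sex == "M"]
      females <- prev[prev_sex == "F"]
      if (!length(males) || !length(females))
        stop("a generation ran out of one sex; increase sizes")
      si <- sample(males, cfg$n_matings, replace = TRUE)
      # one mating per dam when enough ewes are available
      di <- sample(females, cfg$n_matings,
                   replace = length(females) < cfg$n_matings)
      noff <- cfg$n_matings * cfg$offspring_per_mating
      oid <- sprintf("G%d_%04d", g, seq_len(noff))
      osire <- rep(si, each = cfg$offspring_per_mating)
      odam <- rep(di, each = cfg$offspring_per_mating)
      osex <- sample(c("M", "F"), noff, replace = TRUE)
      id <- c(id, oid); sire <- c(sire, osire); dam <- c(dam, odam)
      sex <- c(sex, osex); gen <- c(gen, rep(g, noff))
      prev <- oid
      prev_sex <- osex
    }
    ped <- sort_pedigree(pedigree(id, sire, dam))
    attr(ped, "sex") <- stats::setNames(sex, id)[ped$animal]
    attr(ped, "generation") <- stats::setNames(gen, id)[ped$animal]
    ped
  })
}

#' Simulate genotypes by gene dropping
#'
#' Founder alleles are drawn per SNP at a frequency sampled uniformly from
#' \code{cfg$maf_range}; each offspring inherits one uniformly chosen allele
#' from each parent (unlinked SNPs, no recombination map).  Marker positions
#' are drawn uniformly per chromosome and sorted.  Returns the complete
#' internal matrix for all animals; masking and subsetting to the released
#' genotyped panel happens in [simulate_phenotypes()]/[simulate_dataset()].
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cfg a [sim_config()].
#' @return A complete [genotypes()] object covering every animal, with
#'   attribute \code{"founder_freq"} (the drawn founder frequencies).
#' @export
simulate_genotypes <- function(ped, cfg) {
  check_sorted(ped)
  with_seed(cfg$seed + 1L, {
    n <- nrow(ped)
    m <- cfg$n_snps
    idx <- ped_indices(ped)
    pfreq <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    h1 <- matrix(0L, n, m)
    h2 <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      s <- idx$sire[i]; d <- idx$dam[i]
      if (is.na(s) || is.na(d)) {
        h1[i, ] <- stats::rbinom(m, 1L, pfreq)
        h2[i, ] <- stats::rbinom(m, 1L, pfreq)
      } else {
        pick1 <- stats::runif(m) < 0.5
        h1[i, ] <- ifelse(pick1, h1[s, ], h2[s, ])
        pick2 <- stats::runif(m) < 0.5
        h2[i, ] <- ifelse(pick2, h1[d, ], h2[d, ])
      }
    }
    counts <- h1 + h2
    chr <- sort(rep_len(seq_len(cfg$n_chromosomes), m))
    pos <- unlist(lapply(split(seq_len(m), chr), function(jj)
      sort(sample.int(cfg$chrom_length_bp, length(jj)))), use.names = FALSE)
    map <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                      chr = chr, pos_bp = pos,
                      allele_a = "A", allele_b = "B")
    g <- genotypes(counts, ped$animal, map)
    attr(g, "founder_freq") <- pfreq
    g
  })
}

#' Simulate phenotypes under the maternal-effects animal model
#'
#' True direct and maternal breeding values are the sum of a QTL part
#' (allele counts at the sampled QTL times rescaled effects, so the QTL
#' explain \code{prop_var_qtl} of the component) and an infinitesimal
#' polygenic part bred down the pedigree (parent average plus Mendelian
#' sampling with variance \eqn{(0.5 - 0.25(F_s + F_d))\sigma^2_{poly}}).
#' Each non-founder record is
#' \eqn{y = fixed + a_{animal} + m_{dam} + pe_{dam} + e}; founders have no
#' dam and get no record.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param g complete all-animal [genotypes()] from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return List with \code{phenos} (data frame: animal, dam, sex,
#'   birth_type, herd, birth_year, dam_age, trait) and \code{truth} (list:
#'   true_a, true_m, pe, qtl table, realized variances).
#' @export
simulate_phenotypes <- function(ped, g, cfg) {
  check_sorted(ped)
  stopifnot(inherits(g, "genotypes"))
  n <- nrow(ped)
  idx <- ped_indices(ped)
  FF <- inbreeding(ped)
  with_seed(cfg$seed + 2L, {
    qtl_all <- if (cfg$n_qtl_direct + cfg$n_qtl_maternal > 0)
      sample.int(cfg$n_snps, cfg$n_qtl_direct + cfg$n_qtl_maternal)
    else integer(0)
    qtl_d <- qtl_all[seq_len(cfg$n_qtl_direct)]
    qtl_m <- qtl_all[cfg$n_qtl_direct + seq_len(cfg$n_qtl_maternal)]

    qtl_component <- function(qtl, sigma2, label) {
      if (!length(qtl) || cfg$prop_var_qtl == 0)
        return(list(value = numeric(n), effects = numeric(0),
                    qtl = integer(0)))
      beta <- stats::rnorm(length(qtl))
      gv <- as.numeric(g$counts[, qtl, drop = FALSE] %*% beta)
      target <- cfg$prop_var_qtl * sigma2
      sc <- sqrt(target / stats::var(gv))
      list(value = gv * sc - mean(gv * sc), effects = beta * sc, qtl = qtl)
    }

    polygenic <- function(sigma2_poly) {
      a <- numeric(n)
      for (i in seq_len(n)) {
        s <- idx$sire[i]; d <- idx$dam[i]
        if (is.na(s) || is.na(d)) {
          a[i] <- stats::rnorm(1, 0, sqrt(sigma2_poly))
        } else {
          msv <- (0.5 - 0.25 * (FF[s] + FF[d])) * sigma2_poly
          a[i] <- 0.5 * (a[s] + a[d]) + stats::rnorm(1, 0, sqrt(msv))
        }
      }
      a
    }

    qc_d <- qtl_component(qtl_d, cfg$vc$sigma2_a, "direct")
    qc_m <- qtl_component(qtl_m, cfg$vc$sigma2_m, "maternal")
    pd <- if (length(qc_d$qtl)) 1 - cfg$prop_var_qtl else 1
    pm <- if (length(qc_m$qtl)) 1 - cfg$prop_var_qtl else 1
    true_a <- qc_d$value + polygenic(pd * cfg$vc$sigma2_a)
    true_m <- qc_m$value + polygenic(pm * cfg$vc$sigma2_m)
    names(true_a) <- names(true_m) <- ped$animal

    rec <- which(!is.na(idx$dam))
    dam_of <- idx$dam[rec]
    pe <- stats::setNames(stats::rnorm(n, 0, sqrt(cfg$vc$sigma2_p)),
                          ped$animal)

    lev <- cfg$fixed_effect_levels
    gen <- attr(ped, "generation")
    sex <- attr(ped, "sex")
    draw_fac <- function(name, nlev, nrec) {
      levels <- paste0(name, seq_len(nlev))
      eff <- stats::setNames(stats::rnorm(nlev, 0, cfg$fixed_effect_sd),
                             levels)
      val <- sample(levels, nrec, replace = TRUE)
      list(value = val, effect = eff[val])
    }
    nrec <- length(rec)
    # sex and birth year come from the pedigree itself; their level effects
    # are still random constants
    sex_lev <- if (!is.null(sex)) sex[rec] else
      sample(c("M", "F"), nrec, replace = TRUE)
    sex_eff <- stats::setNames(stats::rnorm(2, 0, cfg$fixed_effect_sd),
                               c("M", "F"))
    year_lev <- if (!is.null(gen)) paste0("y", gen[rec]) else
      rep("y1", nrec)
    uyear <- unique(year_lev)
    year_eff <- stats::setNames(stats::rnorm(length(uyear), 0,
                                             cfg$fixed_effect_sd), uyear)
    bt <- draw_fac("bt", max(2L, lev[["birth_type"]]), nrec)
    herd <- draw_fac("h", max(2L, lev[["herd"]]), nrec)
    dam_age <- draw_fac("da", max(2L, lev[["dam_age"]]), nrec)

    e <- stats::rnorm(nrec, 0, sqrt(cfg$vc$sigma2_e))
    y <- sex_eff[sex_lev] + year_eff[year_lev] + bt$effect + herd$effect +
      dam_age$effect + true_a[rec] + true_m[dam_of] + pe[dam_of] + e

    phenos <- data.frame(animal = ped$animal[rec],
                         dam = ped$animal[dam_of],
                         sex = sex_lev, birth_type = bt$value,
                         herd = herd$value, birth_year = year_lev,
                         dam_age = dam_age$value,
                         trait = as.numeric(y),
                         stringsAsFactors = FALSE)
    qtl_tab <- rbind(
      if (length(qc_d$qtl))
        data.frame(snp_id = g$map$snp_id[qc_d$qtl],
                   chr = g$map$chr[qc_d$qtl],
                   pos_bp = g$map$pos_bp[qc_d$qtl],
                   effect = qc_d$effects, type = "direct"),
      if (length(qc_m$qtl))
        data.frame(snp_id = g$map$snp_id[qc_m$qtl],
                   chr = g$map$chr[qc_m$qtl],
                   pos_bp = g$map$pos_bp[qc_m$qtl],
                   effect = qc_m$effects, type = "maternal"))
    truth <- list(true_a = true_a, true_m = true_m, pe = pe,
                  qtl = qtl_tab,
                  realized = c(var_a = stats::var(true_a),
                               var_m = stats::var(true_m)))
    list(phenos = phenos, truth = truth)
  })
}

#' Simulate a complete released dataset
#'
#' Convenience wrapper: pedigree, internal genotypes, phenotypes, then the
#' released genotyped panel (a random fraction of the last generation, with
#' genotypes masked at \code{missing_rate}).
#'
#' @param cfg a [sim_config()].
#' @return List with \code{ped}, \code{phenos}, \code{geno} (released,
#'   possibly with missing entries), \code{geno_full} (internal, complete),
#'   \code{truth}.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  sim <- simulate_phenotypes(ped, g, cfg)
  gen <- attr(ped, "generation")
  last <- ped$animal[gen == max(gen)]
  with_seed(cfg$seed + 3L, {
    ng <- round(cfg$genotyped_fraction_last_gen * length(last))
    gids <- sort(sample(last, ng))
    counts <- g$counts[gids, , drop = FALSE]
    if (cfg$missing_rate > 0) {
      mask <- matrix(stats::runif(length(counts)) < cfg$missing_rate,
                     nrow(counts), ncol(counts))
      counts[mask] <- NA
    }
    geno <- genotypes(counts, gids, g$map)
    attr(geno, "founder_freq") <- attr(g, "founder_freq")
    list(ped = ped, phenos = sim$phenos, geno = geno, geno_full = g,
         truth = sim$truth)
  })
}
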