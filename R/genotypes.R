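#' Construct a genotype matrix object
#'
#' Holds reference-allele counts (0/1/2, \code{NA} = missing) for a panel of
#' individuals together with the marker map.
#'
#' @param counts integer/numeric matrix, individuals in rows, SNPs in
#'   columns; entries in \{0, 1, 2, NA\}.
#' @param sample_ids character vector of individual ids (row labels).
#' @param map data frame with columns \code{snp_id}, \code{chr},
#'   \code{pos_bp}, and optionally \code{allele_a}, \code{allele_b}
#'   (the counted allele is \code{allele_a}).
#' @return Object of class \code{"genotypes"}.
#' @export
genotypes <- function(counts, sample_ids, map) {
  counts <- as.matrix(counts)
  sample_ids <- as.character(sample_ids)
  if (nrow(counts) != length(sample_ids))
    stop("nrow(counts) != length(sample_ids)")
  req <- c("snp_id", "chr", "pos_bp")
  if (!all(req %in% names(map)))
    stop("map must have columns ", paste(req, collapse = ", "))
  if (ncol(counts) != nrow(map))
    stop("ncol(counts) != nrow(map)")
  bad <- counts[!is.na(counts) & !(counts %in% 0:2)]
  if (length(bad)) stop("genotype counts must be 0, 1, 2 or NA")
  if (is.null(map$allele_a)) map$allele_a <- "A"
  if (is.null(map$allele_b)) map$allele_b <- "B"
  map$snp_id <- as.character(map$snp_id)
  rownames(map) <- NULL
  dimnames(counts) <- list(sample_ids, map$snp_id)
  structure(list(counts = counts, sample_ids = sample_ids, map = map),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("Genotypes: %d individuals x %d SNPs (%d chromosome%s), %.2f%% missing\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$map$chr)),
              if (length(unique(x$map$chr)) == 1L) "" else "s",
              100 * mean(is.na(x$counts))))
  invisible(x)
}

#' Quality-control thresholds
#'
#' Defaults are the conventional 50K-chip filters: individual and SNP call
#' rates at least 0.95, minor allele frequency at least 0.05, and exact
#' Hardy-Weinberg test p-value at least 1e-6.
#'
#' @param min_ind_call_rate,min_snp_call_rate,min_maf,min_hwe_p fractions in
#'   \[0, 1\].
#' @param autosomes integer vector of chromosome codes retained as autosomal
#'   (default 1:26, the sheep autosomes).
#' @return A list of class \code{"qc_thresholds"}.
#' @export
qc_thresholds <- function(min_ind_call_rate = 0.95, min_snp_call_rate = 0.95,
                          min_maf = 0.05, min_hwe_p = 1e-6,
                          autosomes = 1:26) {
  vals <- c(min_ind_call_rate, min_snp_call_rate, min_maf, min_hwe_p)
  if (any(vals < 0 | vals > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(min_ind_call_rate = min_ind_call_rate,
                 min_snp_call_rate = min_snp_call_rate,
                 min_maf = min_maf, min_hwe_p = min_hwe_p,
                 autosomes = as.integer(autosomes)),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the total probability of heterozygote counts whose conditional
#' probability does not exceed that of the observed count
#' (Wigginton-Cutler-Abecasis formulation, as used by PLINK).
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return p-value in \[0, 1\].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  nA <- 2 * n_AA + n_Aa
  rare <- min(nA, 2 * n - nA)
  # possible heterozygote counts share the parity of the rare allele count
  h <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) - lfactorial((rare - h) / 2) - lfactorial(h) -
    lfactorial(n - (rare + h) / 2) + h * log(2) +
    lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, h)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Per-SNP counted-allele frequencies
#'
#' @param g a [genotypes()] object with no missing entries (use
#'   [impute_missing()] first), or any 0/1/2 matrix.
#' @return Numeric vector of allele frequencies (mean count / 2).
#' @export
allele_frequencies <- function(g) {
  counts <- if (inherits(g, "genotypes")) g$counts else as.matrix(g)
  if (anyNA(counts)) stop("missing genotypes present; impute first")
  colMeans(counts) / 2
}

#' Apply SNP and individual quality control
#'
#' Filters in the conventional order: (1) drop SNPs with unknown map position
#' or outside the autosomes; (2) drop individuals with call rate below
#' threshold; (3) drop SNPs with call rate below threshold; (4) drop SNPs
#' with minor allele frequency below threshold; (5) drop SNPs failing the
#' exact Hardy-Weinberg test.
#'
#' @param g a [genotypes()] object (may contain missing values).
#' @param thr a [qc_thresholds()] object.
#' @return List with elements \code{genotypes} (filtered object) and
#'   \code{report} (data frame: step, item_type, removed, remaining).
#' @export
apply_qc <- function(g, thr = qc_thresholds()) {
  stopifnot(inherits(g, "genotypes"))
  if (!inherits(thr, "qc_thresholds")) stop("thr must be qc_thresholds()")
  counts <- g$counts
  map <- g$map
  report <- data.frame(step = character(0), item_type = character(0),
                       removed = integer(0), remaining = integer(0))
  log_step <- function(step, type, removed, remaining) {
    report <<- rbind(report, data.frame(step = step, item_type = type,
                                        removed = removed,
                                        remaining = remaining))
  }

  keep <- !is.na(map$chr) & map$chr %in% thr$autosomes &
    !is.na(map$pos_bp) & map$pos_bp > 0
  log_step("map", "snp", sum(!keep), sum(keep))
  counts <- counts[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]

  ind_cr <- rowMeans(!is.na(counts))
  keep_ind <- ind_cr >= thr$min_ind_call_rate
  log_step("ind_call_rate", "individual", sum(!keep_ind), sum(keep_ind))
  counts <- counts[keep_ind, , drop = FALSE]

  snp_cr <- colMeans(!is.na(counts))
  keep <- snp_cr >= thr$min_snp_call_rate
  log_step("snp_call_rate", "snp", sum(!keep), sum(keep))
  counts <- counts[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]

  p <- colMeans(counts, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= thr$min_maf
  log_step("maf", "snp", sum(!keep), sum(keep))
  counts <- counts[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]

  hwe <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    hwe_exact_p(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                sum(x == 0, na.rm = TRUE))
  }, numeric(1))
  keep <- hwe >= thr$min_hwe_p
  log_step("hwe", "snp", sum(!keep), sum(keep))
  counts <- counts[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]

  if (ncol(counts) == 0L) stop("no SNPs survive quality control")
  if (nrow(counts) == 0L) stop("no individuals survive quality control")
  list(genotypes = genotypes(counts, rownames(counts), map),
       report = report)
}

#' Impute missing genotypes by Hardy-Weinberg draws
#'
#' Each missing entry is drawn from \{0, 1, 2\} with probabilities
#' \eqn{(1-p)^2, 2p(1-p), p^2} at the SNP's observed counted-allele
#' frequency p.  Deterministic given \code{seed}.
#'
#' @param g a post-QC [genotypes()] object.
#' @param seed integer seed.
#' @return A complete [genotypes()] object.
#' @export
impute_missing <- function(g, seed) {
  stopifnot(inherits(g, "genotypes"))
  counts <- g$counts
  if (!anyNA(counts)) return(g)
  with_seed(seed, {
    for (j in which(colSums(is.na(counts)) > 0L)) {
      x <- counts[, j]
      obs <- x[!is.na(x)]
      if (!length(obs))
        stop("SNP ", g$map$snp_id[j], " has no observed genotypes")
      p <- mean(obs) / 2
      nm <- sum(is.na(x))
      x[is.na(x)] <- sample(0:2, nm, replace = TRUE,
                            prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
      counts[, j] <- x
    }
  })
  genotypes(counts, g$sample_ids, g$map)
}

#' Centered gene-content matrix Z
#'
#' Z codes genotypes as 0-2p, 1-2p and 2-2p, so that columns have mean zero
#' when \code{freqs} are the observed frequencies.
#'
#' @param g complete [genotypes()] object or 0/1/2 matrix.
#' @param freqs per-SNP frequencies used for centering (defaults to the
#'   observed frequencies).
#' @return Dense numeric matrix with the same dimnames as the counts.
#' @export
center_gene_content <- function(g, freqs = allele_frequencies(g)) {
  counts <- if (inherits(g, "genotypes")) g$counts else as.matrix(g)
  if (anyNA(counts)) stop("missing genotypes present; impute first")
  if (length(freqs) != ncol(counts))
    stop("length(freqs) != number of SNPs")
  sweep(counts, 2L, 2 * freqs, `-`)
}
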