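#' Back-solve SNP effects from genotyped-animal GEBVs
#'
#' \deqn{\hat u = \lambda D Z' G^{-1} \hat a_g}
#' converts the genotyped animals' breeding values into per-SNP allele
#' substitution effects.  \code{G_used} should be the same (blended) matrix
#' whose inverse enters the single-step H-inverse.
#'
#' @param Z centered gene-content matrix of the genotyped animals.
#' @param d per-SNP weights (diagonal of D).
#' @param G_used genomic relationship matrix to invert (usually
#'   [blend_G()] output).
#' @param gebv named vector of GEBVs for the genotyped animals, in row
#'   order of Z.
#' @param lam scaling constant \eqn{1/\sum_i 2 p_i (1-p_i)}; defaults from
#'   \code{freqs}.
#' @param freqs counted-allele frequencies, used when \code{lam} is missing.
#' @return Numeric vector of SNP effects, named by Z's column names.
#' @export
backsolve_snp_effects <- function(Z, d, G_used, gebv, lam = NULL,
                                  freqs = NULL) {
  Z <- as.matrix(Z)
  if (length(d) != ncol(Z)) stop("length(d) != ncol(Z)")
  if (length(gebv) != nrow(Z)) stop("length(gebv) != nrow(Z)")
  if (is.null(lam)) {
    if (is.null(freqs)) stop("supply lam or freqs")
    lam <- 1 / sum(2 * freqs * (1 - freqs))
  }
  Ginv_a <- tryCatch(solve(as.matrix(G_used), as.numeric(gebv)),
                     error = function(e)
                       stop("G_used is singular; blend with A22 first",
                            call. = FALSE))
  u <- lam * d * as.numeric(crossprod(Z, Ginv_a))
  names(u) <- colnames(Z)
  u
}

#' nonlinearA SNP weights
#'
#' \deqn{d_i = CT^{\,\min(|\hat u_i|/sd(\hat u),\; cap + 2) - 2}}
#' with CT = 1.125 by default; the exponent is capped so the weights stay in
#' \eqn{[CT^{-2}, CT^{cap}]}, which avoids extreme weights and stabilizes
#' the iteration.
#'
#' @param u_hat vector of estimated SNP effects.
#' @param ct base constant controlling the departure from normality.
#' @param cap maximum value of the exponent \eqn{|\hat u|/sd(\hat u) - 2}.
#' @return Positive weight vector of the same length (and names) as
#'   \code{u_hat}.
#' @export
nonlinearA_weights <- function(u_hat, ct = 1.125, cap = 5) {
  s <- stats::sd(u_hat)
  if (!is.finite(s) || s == 0) {
    warning("sd of SNP effects is zero; returning unit weights")
    return(stats::setNames(rep(1, length(u_hat)), names(u_hat)))
  }
  expo <- pmin(abs(u_hat) / s, cap + 2) - 2
  stats::setNames(ct^expo, names(u_hat))
}

#' Normalize SNP weights to preserve the trace of D
#'
#' Rescales the new weights so their sum equals the previous iteration's,
#' keeping the total genetic variance captured by \eqn{G = \lambda Z D Z'}
#' constant across iterations (trace m when D starts at identity).
#'
#' @param d_new,d_prev positive weight vectors of equal length.
#' @return Rescaled \code{d_new}.
#' @export
normalize_weights <- function(d_new, d_prev) {
  if (length(d_new) != length(d_prev)) stop("weight vectors differ in length")
  sn <- sum(d_new)
  if (!is.finite(sn) || sn <= 0) stop("new weights have non-positive sum")
  d_new * (sum(d_prev) / sn)
}

#' Genetic variance explained by non-overlapping genomic windows
#'
#' Assigns every SNP to a fixed 1-Mb bin per chromosome (bin k covers
#' \eqn{[(k-1)\cdot 10^6 + 1,\; k\cdot 10^6]} bp) and reports, per
#' non-empty bin, \eqn{100 \cdot var(\sum_j Z_j \hat u_j) / \sigma^2}
#' where the variance is taken across the genotyped individuals.
#'
#' @param u per-SNP effects (same order as Z columns / map rows).
#' @param Z centered gene-content matrix of the genotyped animals.
#' @param map marker map data frame (\code{snp_id}, \code{chr},
#'   \code{pos_bp}).
#' @param window_bp window length in bp (default 1 Mb).
#' @param denom_variance the genetic variance in the denominator
#'   (\eqn{\sigma^2_a} for direct effects, \eqn{\sigma^2_m} for maternal).
#' @return Data frame of class \code{"window_table"}: chr, window_start,
#'   window_end, first_snp_bp, last_snp_bp, n_snps, pct_variance.
#' @export
window_variance <- function(u, Z, map, window_bp = 1e6, denom_variance) {
  Z <- as.matrix(Z)
  if (length(u) != ncol(Z) || nrow(map) != ncol(Z))
    stop("u, Z and map dimensions disagree")
  if (ncol(Z) == 0L) stop("empty SNP set")
  if (!is.numeric(denom_variance) || denom_variance <= 0)
    stop("denom_variance must be positive")
  bin <- (map$pos_bp - 1) %/% window_bp
  key <- paste(map$chr, bin, sep = ":")
  groups <- split(seq_len(nrow(map)), key)
  rows <- lapply(groups, function(jj) {
    gv <- Z[, jj, drop = FALSE] %*% u[jj]
    data.frame(chr = map$chr[jj[1]],
               window_start = bin[jj[1]] * window_bp + 1,
               window_end = (bin[jj[1]] + 1) * window_bp,
               first_snp_bp = min(map$pos_bp[jj]),
               last_snp_bp = max(map$pos_bp[jj]),
               n_snps = length(jj),
               pct_variance = 100 * stats::var(as.numeric(gv)) /
                 denom_variance)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chr, out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("window_table", "data.frame")
  out
}

#' Top-k windows by percentage of variance explained
#'
#' @param wt a [window_variance()] table.
#' @param k number of windows to keep (default 10); ties are broken by
#'   genome order (chromosome, then start).
#' @return The k rows with the largest \code{pct_variance}, sorted
#'   descending.
#' @export
top_windows <- function(wt, k = 10) {
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(wt)) {
    warning("k exceeds the number of windows; returning all ", nrow(wt))
    k <- nrow(wt)
  }
  ord <- order(-wt$pct_variance, wt$chr, wt$window_start)
  out <- wt[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the iterative weighted single-step GWAS
#'
#' Per iteration t = 1..n_iter (D starts at identity): build
#' \eqn{G_{(t)} = \lambda Z D_{(t)} Z'}, blend with \eqn{A_{22}}, assemble
#' \eqn{H^{-1}}, solve the maternal-effects MME for GEBVs, back-solve
#' direct SNP effects from the genotyped animals' \eqn{\hat a_g} and
#' maternal effects from \eqn{\hat m_g}, then update the weights by the
#' nonlinearA rule on the direct effects and renormalize to constant trace.
#' After the final iteration the genetic variance is decomposed into
#' non-overlapping windows per effect type.
#'
#' @param phenos phenotype data frame (see [build_design()]).
#' @param ped sorted [pedigree()].
#' @param geno complete post-QC [genotypes()] object for the genotyped
#'   subset.
#' @param vc [variance_components()] (from [estimate_varcomps_reml()] or
#'   known truth).
#' @param n_iter number of weighting iterations (default 3).
#' @param alpha,beta G/A22 blending weights (defaults 0.95/0.05).
#' @param ct,cap nonlinearA parameters (defaults 1.125 and 5).
#' @param window_bp window size for the variance decomposition.
#' @param top_k how many top windows to flag per effect type.
#' @param fixed,trait passed to [build_design()].
#' @param freqs optional reference allele frequencies for centering and the
#'   G denominator; defaults to the panel's observed frequencies.  Observed
#'   frequencies leave the ones vector in the null space of Z', so the
#'   unblended G (alpha = 1) is only invertible with external reference
#'   frequencies and a square full-rank gene-content matrix.
#' @return List of class \code{"wssgwas_fit"}: per-iteration list
#'   \code{iterations} (weights, solutions, u_direct, u_maternal),
#'   \code{windows_direct}, \code{windows_maternal},
#'   \code{top_direct}, \code{top_maternal}, \code{snp_effects} (long data
#'   frame over iterations), plus the inputs' metadata.
#' @export
run_wssgwas <- function(phenos, ped, geno, vc, n_iter = 3,
                        alpha = 0.95, beta = 0.05, ct = 1.125, cap = 5,
                        window_bp = 1e6, top_k = 10,
                        fixed = c("sex", "birth_type", "herd",
                                  "birth_year", "dam_age"),
                        trait = "trait", freqs = NULL) {
  check_sorted(ped)
  stopifnot(inherits(geno, "genotypes"))
  if (anyNA(geno$counts)) stop("genotypes contain missing values; impute first")
  gids <- geno$sample_ids
  if (!all(gids %in% ped$animal))
    stop("genotyped animals missing from the pedigree")

  if (is.null(freqs)) freqs <- allele_frequencies(geno)
  if (length(freqs) != ncol(geno$counts))
    stop("length(freqs) != number of SNPs")
  Z <- center_gene_content(geno, freqs)
  m <- ncol(Z)
  lam <- 1 / sum(2 * freqs * (1 - freqs))

  A <- build_A(ped)
  A22 <- extract_A22(A, gids)
  a_inv <- build_A_inverse(ped)
  a22_inv <- chol2inv(chol(A22))
  design <- build_design(phenos, ped, fixed = fixed, trait = trait)

  d <- rep(1, m)
  iterations <- vector("list", n_iter)
  for (t in seq_len(n_iter)) {
    G <- build_G(Z, d, freqs)
    G_omega <- blend_G(G, A22, alpha, beta)
    H_inv <- build_H_inverse(a_inv, genotyped_ids = gids,
                             g_omega = G_omega, a22_inv = a22_inv)
    fit <- solve_mme(design, H_inv, vc)
    u_dir <- backsolve_snp_effects(Z, d, G_omega, fit$a_hat[gids], lam)
    u_mat <- backsolve_snp_effects(Z, d, G_omega, fit$m_hat[gids], lam)
    iterations[[t]] <- list(iteration = t, weights = d, fit = fit,
                            u_direct = u_dir, u_maternal = u_mat)
    if (t < n_iter)
      d <- normalize_weights(nonlinearA_weights(u_dir, ct, cap), d)
  }
  last <- iterations[[n_iter]]
  win_d <- window_variance(last$u_direct, Z, geno$map, window_bp,
                           vc$sigma2_a)
  win_m <- window_variance(last$u_maternal, Z, geno$map, window_bp,
                           vc$sigma2_m)
  snp_effects <- do.call(rbind, lapply(iterations, function(itr)
    data.frame(snp_id = geno$map$snp_id, chr = geno$map$chr,
               pos_bp = geno$map$pos_bp,
               u_direct = unname(itr$u_direct),
               u_maternal = unname(itr$u_maternal),
               weight = unname(itr$weights),
               iteration = itr$iteration)))
  structure(list(iterations = iterations,
                 windows_direct = win_d, windows_maternal = win_m,
                 top_direct = top_windows(win_d, min(top_k, nrow(win_d))),
                 top_maternal = top_windows(win_m, min(top_k, nrow(win_m))),
                 snp_effects = snp_effects,
                 genotyped_ids = gids, freqs = freqs, lam = lam,
                 vc = vc,
                 params = list(n_iter = n_iter, alpha = alpha, beta = beta,
                               ct = ct, cap = cap, window_bp = window_bp,
                               top_k = top_k)),
            class = "wssgwas_fit")
}

#' @export
print.wssgwas_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "WssGWAS fit: %d genotyped animals, %d SNPs, %d iterations (alpha=%.2f, CT=%.3f)\n",
    length(x$genotyped_ids), nrow(x$snp_effects) / p$n_iter, p$n_iter,
    p$alpha, p$ct))
  cat(sprintf("Top direct windows explain %.2f%% of sigma2_a; top maternal %.2f%% of sigma2_m\n",
              sum(x$top_direct$pct_variance),
              sum(x$top_maternal$pct_variance)))
  invisible(x)
}
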