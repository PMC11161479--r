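#' Adjust weaning weight to 90 days of age
#'
#' \deqn{WW_{90} = \frac{WW - BW}{age} \times 90}
#' i.e. birth weight plus pre-weaning average daily gain projected to a
#' common 90-day age is replaced by the gain-only standardization used for
#' lamb weaning records (daily gain times 90).
#'
#' @param ww_raw unadjusted weaning weight (kg).
#' @param bw birth weight (kg).
#' @param age_days age at weighing (days), positive.
#' @return Adjusted 90-day weight (kg).
#' @export
adjust_weaning_weight <- function(ww_raw, bw, age_days) {
  if (any(age_days <= 0)) stop("age_days must be positive")
  (ww_raw - bw) / age_days * 90
}

#' Variance components for the maternal-effects animal model
#'
#' @param sigma2_a direct additive genetic variance (kg^2).
#' @param sigma2_m maternal genetic variance (kg^2).
#' @param sigma2_p maternal permanent-environment variance (kg^2).
#' @param sigma2_e residual variance (kg^2), strictly positive.
#' @return Named list of class \code{"varcomps"}.
#' @export
variance_components <- function(sigma2_a, sigma2_m, sigma2_p, sigma2_e) {
  v <- c(sigma2_a, sigma2_m, sigma2_p, sigma2_e)
  if (any(!is.finite(v)) || any(v < 0) || sigma2_e <= 0)
    stop("variance components must be non-negative with sigma2_e > 0")
  structure(list(sigma2_a = sigma2_a, sigma2_m = sigma2_m,
                 sigma2_p = sigma2_p, sigma2_e = sigma2_e),
            class = "varcomps")
}

#' @export
print.varcomps <- function(x, ...) {
  tot <- x$sigma2_a + x$sigma2_m + x$sigma2_p + x$sigma2_e
  cat(sprintf(
    "Variance components: a=%.4g m=%.4g pe=%.4g e=%.4g (h2_a=%.3f, h2_m=%.3f)\n",
    x$sigma2_a, x$sigma2_m, x$sigma2_p, x$sigma2_e,
    x$sigma2_a / tot, x$sigma2_m / tot))
  if (!is.null(x$converged))
    cat(sprintf("  REML: %s after %d iterations, logL = %.4f\n",
                if (x$converged) "converged" else "NOT converged",
                x$iterations, x$loglik))
  invisible(x)
}

#' Build design matrices for the maternal-effects animal model
#'
#' Constructs y and the incidence matrices of
#' \eqn{y = Xb + Z_a a + W p + S m + e}: X dummy-codes the fixed effects with
#' an intercept and the first level of each effect dropped; \eqn{Z_a} links
#' each record to the animal's direct additive effect, S to the dam's
#' maternal genetic effect (both spanning every pedigree animal), and W to
#' the dam's permanent-environment effect (spanning the dams with records).
#'
#' @param phenos data frame with columns \code{animal}, \code{dam}, the
#'   fixed-effect columns and the trait column.
#' @param ped a sorted [pedigree()] covering all animals and dams.
#' @param fixed character vector of fixed-effect column names (treated as
#'   categorical).
#' @param trait name of the trait column.
#' @return List of class \code{"mme_design"} with elements \code{y},
#'   \code{X}, \code{Z_a}, \code{S_m}, \code{W_p}, \code{animal_ids},
#'   \code{dam_ids}.
#' @export
build_design <- function(phenos, ped,
                         fixed = c("sex", "birth_type", "herd",
                                   "birth_year", "dam_age"),
                         trait = "trait") {
  check_sorted(ped)
  need <- c("animal", "dam", fixed, trait)
  miss <- setdiff(need, names(phenos))
  if (length(miss)) stop("phenotype columns missing: ",
                         paste(miss, collapse = ", "))
  if (anyNA(phenos$dam) || any(phenos$dam %in% c("0", "")))
    stop("maternal model requires a known dam for every record")
  y <- phenos[[trait]]
  if (any(!is.finite(y))) stop("trait values must be finite")
  nrec <- nrow(phenos)
  ai <- match(as.character(phenos$animal), ped$animal)
  di <- match(as.character(phenos$dam), ped$animal)
  if (anyNA(ai)) stop("animals not in pedigree: ",
                      paste(unique(phenos$animal[is.na(ai)]), collapse = ", "))
  if (anyNA(di)) stop("dams not in pedigree: ",
                      paste(unique(phenos$dam[is.na(di)]), collapse = ", "))

  fdat <- phenos[fixed]
  fdat[] <- lapply(fdat, function(x) factor(as.character(x)))
  varying <- vapply(fdat, function(f) nlevels(f) >= 2L, logical(1))
  X <- if (any(varying)) {
    stats::model.matrix(stats::reformulate(fixed[varying]),
                        data = fdat[varying])
  } else {
    matrix(1, nrec, 1, dimnames = list(NULL, "(Intercept)"))
  }

  nped <- nrow(ped)
  dam_ids <- ped$animal[sort(unique(di))]
  Z_a <- Matrix::sparseMatrix(i = seq_len(nrec), j = ai, x = 1,
                              dims = c(nrec, nped),
                              dimnames = list(NULL, ped$animal))
  S_m <- Matrix::sparseMatrix(i = seq_len(nrec), j = di, x = 1,
                              dims = c(nrec, nped),
                              dimnames = list(NULL, ped$animal))
  W_p <- Matrix::sparseMatrix(i = seq_len(nrec),
                              j = match(ped$animal[di], dam_ids), x = 1,
                              dims = c(nrec, length(dam_ids)),
                              dimnames = list(NULL, dam_ids))
  structure(list(y = as.numeric(y), X = X, Z_a = Z_a, S_m = S_m, W_p = W_p,
                 animal_ids = ped$animal, dam_ids = dam_ids),
            class = "mme_design")
}

# stack the full design [X Za S W] once; shared by solve_mme and REML
mme_setup <- function(design, K_inv) {
  stopifnot(inherits(design, "mme_design"))
  q <- length(design$animal_ids)
  if (!all(dim(K_inv) == c(q, q)))
    stop("K_inv dimension does not match the pedigree")
  if (!is.null(rownames(K_inv)) &&
      !identical(rownames(K_inv), design$animal_ids))
    stop("K_inv animal ordering does not match the design")
  Wmat <- cbind(methods::as(Matrix::Matrix(design$X, sparse = TRUE),
                            "CsparseMatrix"),
                design$Z_a, design$S_m, design$W_p)
  p <- ncol(design$X)
  qp <- ncol(design$W_p)
  list(Wmat = Wmat, WtW = Matrix::crossprod(Wmat),
       Wty = as.numeric(Matrix::crossprod(Wmat, design$y)),
       yty = sum(design$y^2), n = length(design$y),
       p = p, q = q, qp = qp,
       idx_b = seq_len(p), idx_a = p + seq_len(q),
       idx_m = p + q + seq_len(q), idx_p = p + 2L * q + seq_len(qp),
       K_inv = methods::as(K_inv, "CsparseMatrix"))
}

mme_coefmat <- function(setup, vc) {
  Ginv <- Matrix::bdiag(Matrix::Diagonal(setup$p, 0),
                        setup$K_inv / vc$sigma2_a,
                        setup$K_inv / vc$sigma2_m,
                        Matrix::Diagonal(setup$qp) / vc$sigma2_p)
  Matrix::forceSymmetric(setup$WtW / vc$sigma2_e + Ginv)
}

#' Solve the mixed model equations
#'
#' Henderson's MME for the maternal-effects animal model, with the direct
#' and maternal genetic effects sharing the relationship structure
#' \code{K_inv} (pedigree \eqn{A^{-1}} or single-step \eqn{H^{-1}}), the
#' permanent-environment block an identity, and the direct-maternal genetic
#' covariance fixed at zero.
#'
#' @param design an [build_design()] object.
#' @param K_inv sparse inverse relationship matrix over all pedigree animals.
#' @param vc a [variance_components()] object (all components positive).
#' @return List of class \code{"mme_fit"}: \code{fixed} (named vector),
#'   \code{a_hat}, \code{m_hat} (named, every pedigree animal), \code{p_hat}
#'   (named, dams), \code{fitted}, \code{residuals}.
#' @export
solve_mme <- function(design, K_inv, vc) {
  if (!inherits(vc, "varcomps")) stop("vc must be variance_components()")
  if (min(vc$sigma2_a, vc$sigma2_m, vc$sigma2_p) <= 0)
    stop("solve_mme requires strictly positive variance components")
  setup <- mme_setup(design, K_inv)
  C <- mme_coefmat(setup, vc)
  ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE),
                 error = function(e)
                   stop("singular MME coefficient matrix: ",
                        conditionMessage(e), call. = FALSE))
  theta <- as.numeric(Matrix::solve(ch, setup$Wty / vc$sigma2_e))
  fitted <- as.numeric(setup$Wmat %*% theta)
  sol <- list(
    fixed = stats::setNames(theta[setup$idx_b], colnames(design$X)),
    a_hat = stats::setNames(theta[setup$idx_a], design$animal_ids),
    m_hat = stats::setNames(theta[setup$idx_m], design$animal_ids),
    p_hat = stats::setNames(theta[setup$idx_p], design$dam_ids),
    fitted = fitted, residuals = design$y - fitted)
  structure(sol, class = "mme_fit")
}

#' @export
print.mme_fit <- function(x, ...) {
  cat(sprintf("MME solutions: %d fixed, %d direct, %d maternal, %d PE\n",
              length(x$fixed), length(x$a_hat), length(x$m_hat),
              length(x$p_hat)))
  invisible(x)
}

# tr(K_inv %*% Cinv[block, block]) via chunked solves against identity
# columns of the block; K_inv = NULL means identity (plain trace)
block_trace <- function(ch, N, offset, qb, K_inv = NULL, chunk = 512L) {
  tr <- 0
  for (start in seq(1L, qb, by = chunk)) {
    cols <- start:min(start + chunk - 1L, qb)
    E <- Matrix::sparseMatrix(i = offset + cols, j = seq_along(cols), x = 1,
                              dims = c(N, length(cols)))
    S <- as.matrix(Matrix::solve(ch, E))
    tr <- tr + if (is.null(K_inv)) {
      sum(S[offset + cols, ][cbind(seq_along(cols), seq_along(cols))])
    } else {
      sparse_dense_dotsum(K_inv[, cols, drop = FALSE],
                          S[offset + seq_len(qb), , drop = FALSE])
    }
  }
  tr
}

#' REML variance components for the maternal-effects animal model
#'
#' Restricted maximum likelihood via average-information (AI) updates with
#' monotone EM-REML safeguarding: an AI step is taken only when it stays in
#' the parameter space and does not decrease the REML log-likelihood,
#' otherwise the (always monotone) EM update is used.  \code{method = "em"}
#' uses pure EM-REML.  Components falling below \code{1e-8 * var(y)} are
#' pinned to that floor.
#'
#' @param design an [build_design()] object.
#' @param K_inv sparse inverse relationship matrix (usually \eqn{A^{-1}}).
#' @param init starting [variance_components()]; default splits the
#'   phenotypic variance 35/15/10/40 across a/m/pe/e.
#' @param method \code{"ai"} (default) or \code{"em"}.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the maximum relative component change.
#' @param verbose print per-iteration progress.
#' @return A [variance_components()] object with extra fields
#'   \code{loglik}, \code{iterations}, \code{converged}, \code{trace}
#'   (per-iteration data frame).
#' @export
estimate_varcomps_reml <- function(design, K_inv, init = NULL,
                                   method = c("ai", "em"),
                                   max_iter = 100L, tol = 1e-4,
                                   verbose = FALSE) {
  method <- match.arg(method)
  setup <- mme_setup(design, K_inv)
  n <- setup$n; q <- setup$q; qp <- setup$qp
  p_rank <- qr(design$X)$rank
  if (p_rank < ncol(design$X))
    stop("fixed-effect design is rank deficient beyond the dropped-level convention")
  vy <- stats::var(design$y)
  floor_v <- 1e-8 * vy
  if (is.null(init))
    init <- variance_components(0.35 * vy, 0.15 * vy, 0.10 * vy, 0.40 * vy)
  if (min(init$sigma2_a, init$sigma2_m, init$sigma2_p, init$sigma2_e) <= 0)
    stop("init components must be strictly positive")
  ldK <- -as.numeric(Matrix::determinant(setup$K_inv, logarithm = TRUE)$modulus)

  ch <- NULL
  state <- function(vc) {
    C <- mme_coefmat(setup, vc)
    if (is.null(ch)) ch <<- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    else ch <<- Matrix::update(ch, C)
    theta <- as.numeric(Matrix::solve(ch, setup$Wty / vc$sigma2_e))
    yPy <- (setup$yty - sum(theta * setup$Wty)) / vc$sigma2_e
    ldC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    m2ll <- n * log(vc$sigma2_e) + q * (log(vc$sigma2_a) + log(vc$sigma2_m)) +
      qp * log(vc$sigma2_p) + 2 * ldK + ldC + yPy
    list(theta = theta, yPy = yPy, ll = -0.5 * m2ll)
  }

  vc <- init
  st <- state(vc)
  hist <- data.frame()
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    theta <- st$theta
    ua <- theta[setup$idx_a]; um <- theta[setup$idx_m]
    up <- theta[setup$idx_p]
    quad_a <- as.numeric(Matrix::crossprod(ua, setup$K_inv %*% ua))
    quad_m <- as.numeric(Matrix::crossprod(um, setup$K_inv %*% um))
    quad_p <- sum(up^2)
    N <- length(theta)
    tr_a <- block_trace(ch, N, setup$p, q, setup$K_inv)
    tr_m <- block_trace(ch, N, setup$p + q, q, setup$K_inv)
    tr_p <- block_trace(ch, N, setup$p + 2L * q, qp)
    resid_ss <- setup$yty - sum(theta * setup$Wty)

    em <- variance_components(
      max(floor_v, (quad_a + tr_a) / q),
      max(floor_v, (quad_m + tr_m) / q),
      max(floor_v, (quad_p + tr_p) / qp),
      max(floor_v, resid_ss / (n - p_rank)))

    vc_new <- em
    step_kind <- "em"
    if (method == "ai") {
      sc <- c(
        a = -0.5 * ((q - tr_a / vc$sigma2_a) / vc$sigma2_a -
                      quad_a / vc$sigma2_a^2),
        m = -0.5 * ((q - tr_m / vc$sigma2_m) / vc$sigma2_m -
                      quad_m / vc$sigma2_m^2),
        p = -0.5 * ((qp - tr_p / vc$sigma2_p) / vc$sigma2_p -
                      quad_p / vc$sigma2_p^2),
        e = NA)
      ehat <- design$y - as.numeric(setup$Wmat %*% theta)
      trP <- (n - p_rank - (q - tr_a / vc$sigma2_a) -
                (q - tr_m / vc$sigma2_m) - (qp - tr_p / vc$sigma2_p)) /
        vc$sigma2_e
      sc["e"] <- -0.5 * (trP - sum(ehat^2) / vc$sigma2_e^2)
      Fmat <- cbind(as.numeric(design$Z_a %*% ua) / vc$sigma2_a,
                    as.numeric(design$S_m %*% um) / vc$sigma2_m,
                    as.numeric(design$W_p %*% up) / vc$sigma2_p,
                    ehat / vc$sigma2_e)
      WtF <- as.matrix(Matrix::crossprod(setup$Wmat, Fmat)) / vc$sigma2_e
      PF <- (Fmat - as.matrix(setup$Wmat %*%
                                as.matrix(Matrix::solve(ch, WtF)))) /
        vc$sigma2_e
      AI <- 0.5 * crossprod(Fmat, PF)
      AI <- (AI + t(AI)) / 2
      dir <- tryCatch(solve(AI, sc), error = function(e) NULL)
      if (!is.null(dir) && all(is.finite(dir))) {
        # full AI step, halved until it stays in the parameter space and
        # does not lower the restricted likelihood
        step <- 1
        for (half in 1:6) {
          prop <- unlist(vc[1:4]) + step * dir
          if (all(prop > floor_v)) {
            cand <- variance_components(prop[1], prop[2], prop[3], prop[4])
            st_cand <- tryCatch(state(cand), error = function(e) NULL)
            if (!is.null(st_cand) && is.finite(st_cand$ll) &&
                st_cand$ll >= st$ll - 1e-8) {
              vc_new <- cand
              st_new <- st_cand
              step_kind <- "ai"
              break
            }
          }
          step <- step / 2
        }
      }
    }
    if (step_kind == "em") st_new <- state(vc_new)

    rel <- max(abs(unlist(vc_new[1:4]) - unlist(vc[1:4])) /
                 pmax(unlist(vc[1:4]), floor_v))
    hist <- rbind(hist, data.frame(iter = it, step = step_kind,
                                   sigma2_a = vc_new$sigma2_a,
                                   sigma2_m = vc_new$sigma2_m,
                                   sigma2_p = vc_new$sigma2_p,
                                   sigma2_e = vc_new$sigma2_e,
                                   loglik = st_new$ll))
    if (verbose)
      message(sprintf("it %2d [%s] a=%.4g m=%.4g p=%.4g e=%.4g ll=%.4f",
                      it, step_kind, vc_new$sigma2_a, vc_new$sigma2_m,
                      vc_new$sigma2_p, vc_new$sigma2_e, st_new$ll))
    vc <- vc_new
    st <- st_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter,
            " iterations; returning the last iterate")
  out <- variance_components(vc$sigma2_a, vc$sigma2_m, vc$sigma2_p,
                             vc$sigma2_e)
  out$loglik <- st$ll
  out$iterations <- it
  out$converged <- converged
  out$trace <- hist
  out
}

#' REML log-likelihood at given variance components
#'
#' Computed through the mixed-model-equations identity
#' \eqn{-2\ell = \log|R| + \log|G| + \log|C| + y'Py} (constants in n
#' dropped); useful for profiling and for verifying REML stationary points.
#'
#' @inheritParams estimate_varcomps_reml
#' @param vc a [variance_components()] object.
#' @return Scalar log-likelihood (up to an additive constant).
#' @export
reml_loglik <- function(design, K_inv, vc) {
  setup <- mme_setup(design, K_inv)
  ldK <- -as.numeric(Matrix::determinant(setup$K_inv, logarithm = TRUE)$modulus)
  C <- mme_coefmat(setup, vc)
  ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
  theta <- as.numeric(Matrix::solve(ch, setup$Wty / vc$sigma2_e))
  yPy <- (setup$yty - sum(theta * setup$Wty)) / vc$sigma2_e
  ldC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  -0.5 * (setup$n * log(vc$sigma2_e) +
            setup$q * (log(vc$sigma2_a) + log(vc$sigma2_m)) +
            setup$qp * log(vc$sigma2_p) + 2 * ldK + ldC + yPy)
}
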