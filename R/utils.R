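#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded package functions do not disturb the global
#' random number stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# sum over the nonzeros of a sparse matrix of S * D for a conformable dense
# matrix D; used for trace terms tr(S' D) restricted to the pattern of S
sparse_dense_dotsum <- function(S, D) {
  S <- methods::as(methods::as(S, "CsparseMatrix"), "generalMatrix")
  if (!all(dim(S) == dim(D))) stop("dimension mismatch")
  if (length(S@x) == 0L) return(0)
  j <- rep.int(seq_len(ncol(S)), diff(S@p))
  sum(S@x * D[cbind(S@i + 1L, j)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
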