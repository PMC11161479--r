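#' Construct a pedigree object
#'
#' A pedigree is a set of (animal, sire, dam) triplets.  Unknown parents are
#' coded \code{NA}; on input, \code{"0"} and \code{""} are treated as unknown.
#' Animals that appear only as parents are added as founders.
#'
#' @param animal character vector of animal identifiers (unique).
#' @param sire,dam character vectors of parent identifiers; \code{NA},
#'   \code{"0"} or \code{""} mean unknown.
#' @return An object of class \code{"pedigree"}: a data frame with character
#'   columns \code{animal}, \code{sire}, \code{dam} (\code{NA} = unknown) and
#'   a logical attribute \code{"sorted"}.
#' @seealso [sort_pedigree()], [build_A()], [build_A_inverse()]
#' @export
pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  clean <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
    x
  }
  sire <- clean(sire)
  dam <- clean(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have equal length")
  if (anyDuplicated(animal))
    stop("duplicated animal ids: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  if (anyNA(animal)) stop("animal ids must not be missing")
  # parents never listed as animals become founders
  parents <- unique(c(sire, dam))
  parents <- parents[!is.na(parents)]
  extra <- setdiff(parents, animal)
  if (length(extra)) {
    animal <- c(extra, animal)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
  }
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  structure(ped, class = c("pedigree", "data.frame"), sorted = FALSE)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d animals (%d founders)%s\n", nrow(x),
              sum(is.na(x$sire) & is.na(x$dam)),
              if (isTRUE(attr(x, "sorted"))) ", sorted" else ""))
  utils::str(unclass(x)[c("animal", "sire", "dam")])
  invisible(x)
}

# integer parent indices (NA = unknown) relative to the pedigree's own order
ped_indices <- function(ped) {
  list(sire = match(ped$sire, ped$animal),
       dam  = match(ped$dam, ped$animal))
}

#' Topologically sort a pedigree
#'
#' Reorders the records so that every parent precedes all of its offspring
#' (a requirement of the tabular method and of Henderson's inverse rules).
#' Founders keep their relative input order, as do animals within the same
#' pedigree depth.
#'
#' @param ped a [pedigree()] object.
#' @return The sorted pedigree, with attribute \code{"sorted"} set.
#' @export
sort_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- ped_indices(ped)
  # generation number = 1 + max(parent generation); cycle if it fails to fix
  gen <- rep(0L, n)
  repeat {
    g2 <- pmax(ifelse(is.na(idx$sire), 0L, gen[idx$sire] + 1L),
               ifelse(is.na(idx$dam),  0L, gen[idx$dam]  + 1L))
    if (all(g2 == gen)) break
    if (any(g2 > n)) {
      bad <- ped$animal[which(g2 > n)[1L]]
      stop("pedigree contains a cycle involving animal '", bad, "'")
    }
    gen <- g2
  }
  ord <- order(gen, seq_len(n))
  out <- ped[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pedigree", "data.frame"), sorted = TRUE)
}

check_sorted <- function(ped) {
  if (!inherits(ped, "pedigree")) stop("not a pedigree object")
  if (!isTRUE(attr(ped, "sorted")))
    stop("pedigree must be sorted first; call sort_pedigree()")
  invisible(ped)
}

#' Numerator relationship matrix A (tabular method)
#'
#' Builds the additive (numerator) relationship matrix by the tabular
#' recursion: for animal i with parents s and d listed earlier,
#' \eqn{a_{ij} = (a_{js} + a_{jd})/2} for j < i and
#' \eqn{a_{ii} = 1 + a_{sd}/2}; unknown parents contribute zero.
#' Diagonal entries equal one plus the animal's inbreeding coefficient.
#'
#' @param ped a sorted [pedigree()].
#' @return A dense symmetric base matrix with animal ids as dimnames.
#' @export
build_A <- function(ped) {
  check_sorted(ped)
  n <- nrow(ped)
  idx <- ped_indices(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- idx$sire[i]; d <- idx$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[j, s]
      if (!is.na(d)) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes per-animal inbreeding coefficients F without forming the full A
#' matrix, by accumulating the L-row contributions over each animal's
#' ancestors (A_ii = sum_j L_ij^2 d_j = 1 + F_i).
#'
#' @param ped a sorted [pedigree()].
#' @return Named numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreeding <- function(ped) {
  check_sorted(ped)
  n <- nrow(ped)
  idx <- ped_indices(ped)
  si <- idx$sire; di <- idx$dam
  FF <- numeric(n)
  # Mendelian sampling variance d_j; F of an unknown parent is -1 by
  # convention so that d = 0.5 - 0.25(F_s + F_d) covers all cases
  dvar <- numeric(n)
  Fp <- function(k) if (is.na(k)) -1 else FF[k]
  for (i in seq_len(n)) {
    dvar[i] <- 0.5 - 0.25 * (Fp(si[i]) + Fp(di[i]))
    if (is.na(si[i]) || is.na(di[i])) {
      FF[i] <- 0
      next
    }
    L <- numeric(i)
    L[i] <- 1
    acc <- 0
    for (j in i:1) {
      lj <- L[j]
      if (lj == 0) next
      acc <- acc + lj * lj * dvar[j]
      if (!is.na(si[j])) L[si[j]] <- L[si[j]] + 0.5 * lj
      if (!is.na(di[j])) L[di[j]] <- L[di[j]] + 0.5 * lj
    }
    FF[i] <- acc - 1
  }
  names(FF) <- ped$animal
  FF
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding accounted for: each animal contributes
#' \eqn{b_i = 1/d_i} to its own diagonal, \eqn{-b_i/2} to animal-parent
#' cells and \eqn{b_i/4} to parent-parent cells, where the Mendelian
#' sampling variance \eqn{d_i = 0.5 - 0.25(F_s + F_d)} uses the parental
#' inbreeding coefficients from [inbreeding()] (Meuwissen-Luo).
#'
#' @param ped a sorted [pedigree()].
#' @return A sparse symmetric \code{Matrix::dsCMatrix} with animal dimnames.
#' @export
build_A_inverse <- function(ped) {
  check_sorted(ped)
  n <- nrow(ped)
  idx <- ped_indices(ped)
  FF <- inbreeding(ped)
  Fp <- ifelse(is.na(idx$sire), -1, FF[idx$sire])
  Fd <- ifelse(is.na(idx$dam),  -1, FF[idx$dam])
  b <- 1 / (0.5 - 0.25 * (Fp + Fd))
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    s <- idx$sire[i]; d <- idx$dam[i]
    add(i, i, b[i])
    if (!is.na(s)) {
      add(i, s, -b[i] / 2); add(s, i, -b[i] / 2)
      add(s, s, b[i] / 4)
    }
    if (!is.na(d)) {
      add(i, d, -b[i] / 2); add(d, i, -b[i] / 2)
      add(d, d, b[i] / 4)
    }
    if (!is.na(s) && !is.na(d)) {
      add(s, d, b[i] / 4); add(d, s, b[i] / 4)
    }
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' Extract the genotyped-animal submatrix A22
#'
#' @param A relationship matrix with id dimnames (from [build_A()]).
#' @param genotyped_ids character vector of animal ids, in the order the
#'   genomic matrix uses.
#' @return Dense principal submatrix in the order of \code{genotyped_ids}.
#' @export
extract_A22 <- function(A, genotyped_ids) {
  ids <- rownames(A)
  genotyped_ids <- as.character(genotyped_ids)
  miss <- setdiff(genotyped_ids, ids)
  if (length(miss))
    stop("ids not present in A: ", paste(miss, collapse = ", "))
  A[genotyped_ids, genotyped_ids, drop = FALSE]
}
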