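#' Read a pedigree CSV
#'
#' Expects a header line \code{animal,sire,dam}; \code{"0"} or an empty
#' field means an unknown parent.
#'
#' @param path file path.
#' @return An (unsorted) [pedigree()] object.
#' @export
read_pedigree_csv <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree CSV must have columns animal,sire,dam")
  pedigree(df$animal, df$sire, df$dam)
}

#' Write a pedigree CSV
#' @param ped a [pedigree()].
#' @param path output path.
#' @export
write_pedigree_csv <- function(ped, path) {
  df <- data.frame(animal = ped$animal,
                   sire = ifelse(is.na(ped$sire), "0", ped$sire),
                   dam = ifelse(is.na(ped$dam), "0", ped$dam))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype CSV
#'
#' Columns: \code{animal,dam,sex,birth_type,herd,birth_year,dam_age,trait}
#' (header required).  Reports the first malformed row.
#'
#' @param path file path.
#' @return Data frame suitable for [build_design()].
#' @export
read_phenotypes_csv <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("animal", "dam", "sex", "birth_type", "herd", "birth_year",
            "dam_age", "trait")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype CSV missing columns: ", paste(miss, collapse = ", "))
  tv <- suppressWarnings(as.numeric(df$trait))
  if (anyNA(tv))
    stop("non-numeric trait value at line ", which(is.na(tv))[1] + 1L)
  df$trait <- tv
  df
}

#' Write a phenotype CSV
#' @param phenos phenotype data frame.
#' @param path output path.
#' @export
write_phenotypes_csv <- function(phenos, path) {
  utils::write.csv(phenos, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read PLINK genotype files
#'
#' Reads either the text pair \code{prefix.ped}/\code{prefix.map} or the
#' binary trio \code{prefix.bed}/\code{prefix.bim}/\code{prefix.fam}
#' (v1.00, SNP-major).  For the binary format the counted allele is A1 from
#' the .bim file (2-bit codes 00 = two copies of A1, 10 = heterozygote,
#' 11 = zero copies, 01 = missing).  The text .map format carries no allele
#' labels, so there the counted allele is the lexicographically smallest
#' allele observed at each SNP; a SNP where only the other allele is
#' observed therefore reads back with flipped coding (the genomic
#' relationship matrix is invariant to this relabelling).
#'
#' @param prefix path prefix without extension.
#' @return A [genotypes()] object (may contain missing values).
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) read_plink_bed(prefix)
  else if (file.exists(paste0(prefix, ".ped"))) read_plink_text(prefix)
  else stop("no .bed or .ped file found for prefix: ", prefix)
}

read_map_like <- function(path, bim = FALSE) {
  cols <- if (bim) c("chr", "snp_id", "cm", "pos_bp", "a1", "a2")
  else c("chr", "snp_id", "cm", "pos_bp")
  df <- utils::read.table(path, colClasses = "character",
                          col.names = cols)
  df$chr <- suppressWarnings(as.integer(df$chr))
  df$pos_bp <- as.numeric(df$pos_bp)
  df
}

#' @rdname read_plink
#' @export
read_plink_text <- function(prefix) {
  pedf <- paste0(prefix, ".ped")
  mapf <- paste0(prefix, ".map")
  if (!file.exists(pedf)) stop("file not found: ", pedf)
  if (!file.exists(mapf)) stop("file not found: ", mapf)
  map <- read_map_like(mapf)
  m <- nrow(map)
  lines <- readLines(pedf)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf != 6L + 2L * m)
  if (length(bad))
    stop("malformed .ped row at line ", bad[1], ": expected ",
         6L + 2L * m, " fields, found ", nf[bad[1]])
  ids <- vapply(fields, `[`, character(1), 2L)
  al <- t(vapply(fields, function(f) f[-(1:6)], character(2L * m)))
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  counts <- matrix(NA_real_, length(ids), m)
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    missing <- x1 == "0" | x2 == "0"
    obs <- sort(unique(c(x1[!missing], x2[!missing])))
    if (length(obs) > 2L)
      stop("SNP ", map$snp_id[j], " has more than two alleles")
    if (length(obs) == 0L) obs <- c("?", "?")
    ca <- obs[1]
    allele_a[j] <- ca
    allele_b[j] <- if (length(obs) == 2L) obs[2] else ca
    counts[, j] <- (x1 == ca) + (x2 == ca)
    counts[missing, j] <- NA
  }
  map$allele_a <- allele_a
  map$allele_b <- allele_b
  genotypes(counts, ids, map[c("snp_id", "chr", "pos_bp",
                               "allele_a", "allele_b")])
}

#' @rdname read_plink
#' @export
read_plink_bed <- function(prefix) {
  bedf <- paste0(prefix, ".bed")
  bimf <- paste0(prefix, ".bim")
  famf <- paste0(prefix, ".fam")
  for (f in c(bedf, bimf, famf))
    if (!file.exists(f)) stop("file not found: ", f)
  bim <- read_map_like(bimf, bim = TRUE)
  fam <- utils::read.table(famf, colClasses = "character",
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bedf, "raw", n = file.size(bedf))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop(".bed magic number mismatch: not a PLINK v1 .bed file")
  if (raw[3] != as.raw(0x01))
    stop(".bed is not in SNP-major order")
  bps <- ceiling(n / 4)
  if (length(raw) - 3L != bps * m)
    stop(".bed size does not match .bim/.fam dimensions")
  # 2-bit genotype codes per byte, lowest bits = first individual
  code_map <- c(2, NA, 1, 0)  # 00, 01, 10, 11 -> A1 count
  lut <- matrix(0, 256, 4)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      lut[b + 1, k] <- code_map[v %% 4 + 1]
      v <- v %/% 4
    }
  }
  dat <- matrix(as.integer(raw[-(1:3)]), nrow = bps)
  counts <- matrix(NA_real_, n, m)
  for (k in 1:4) {
    rows <- seq(k, by = 4, length.out = bps)
    rows <- rows[rows <= n]
    counts[rows, ] <- lut[dat[seq_along(rows), , drop = FALSE] + 1, k]
  }
  map <- data.frame(snp_id = bim$snp_id, chr = bim$chr, pos_bp = bim$pos_bp,
                    allele_a = bim$a1, allele_b = bim$a2)
  genotypes(counts, fam$iid, map)
}

#' Write PLINK text files (.ped/.map)
#'
#' The counted allele is written as \code{allele_a} from the map (label
#' sorting ahead of \code{allele_b} keeps the text round trip faithful);
#' missing genotypes are written \code{0 0}.
#'
#' @param g a [genotypes()] object.
#' @param prefix output path prefix.
#' @export
write_plink_text <- function(g, prefix) {
  stopifnot(inherits(g, "genotypes"))
  map <- g$map
  utils::write.table(
    data.frame(map$chr, map$snp_id, 0, format(map$pos_bp, scientific = FALSE,
                                              trim = TRUE)),
    paste0(prefix, ".map"), row.names = FALSE, col.names = FALSE,
    quote = FALSE, sep = "\t")
  n <- nrow(g$counts)
  m <- ncol(g$counts)
  al <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    x <- g$counts[, j]
    a <- map$allele_a[j]; b <- map$allele_b[j]
    c1 <- ifelse(is.na(x), "0", ifelse(x >= 1, a, b))
    c2 <- ifelse(is.na(x), "0", ifelse(x == 2, a, b))
    al[, 2L * j - 1L] <- c1
    al[, 2L * j] <- c2
  }
  lines <- paste(g$sample_ids, g$sample_ids, "0", "0", "0", "-9",
                 apply(al, 1L, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Write PLINK binary files (.bed/.bim/.fam)
#'
#' SNP-major v1.00 layout; the counted allele becomes A1 in the .bim.
#'
#' @param g a [genotypes()] object.
#' @param prefix output path prefix.
#' @export
write_plink_bed <- function(g, prefix) {
  stopifnot(inherits(g, "genotypes"))
  map <- g$map
  utils::write.table(
    data.frame(map$chr, map$snp_id, 0, format(map$pos_bp, scientific = FALSE,
                                              trim = TRUE),
               map$allele_a, map$allele_b),
    paste0(prefix, ".bim"), row.names = FALSE, col.names = FALSE,
    quote = FALSE, sep = "\t")
  utils::write.table(
    data.frame(g$sample_ids, g$sample_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), row.names = FALSE, col.names = FALSE,
    quote = FALSE, sep = " ")
  n <- nrow(g$counts)
  m <- ncol(g$counts)
  bps <- ceiling(n / 4)
  # A1-count -> 2-bit code: 2->00, 1->10, 0->11, NA->01
  code <- matrix(1L, 4L * bps, m)  # pad positions read as missing-safe 0b00?
  code[] <- 0L
  codes <- ifelse(is.na(g$counts), 1L, c(3L, 2L, 0L)[g$counts + 1L])
  code[seq_len(n), ] <- codes
  shift <- rep(c(1L, 4L, 16L, 64L), bps)
  bytes <- rowsum(code * shift, rep(seq_len(bps), each = 4L))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Write a window-variance table as TSV
#' @param wt a [window_variance()] table (optionally with extra columns).
#' @param path output path.
#' @export
write_windows_tsv <- function(wt, path) {
  utils::write.table(wt, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-SNP effects and weights as TSV
#' @param snp_effects the \code{snp_effects} data frame of a
#'   [run_wssgwas()] fit.
#' @param path output path.
#' @export
write_snp_effects_tsv <- function(snp_effects, path) {
  utils::write.table(snp_effects, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
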