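#' Read genotypes from PLINK bed/bim/fam or the TSV dialect
#'
#' Two on-disk formats are supported: PLINK 1 binary (`.bed` SNP-major with
#' its `.bim`/`.fam` companions) and a plain TSV dialect (header row of SNP
#' ids, first column `id`, cells 0/1/2/NA counting copies of allele 1).
#' Both round-trip bit-exactly with [write_genotypes()].
#'
#' @param path For `plink-bed`, the path prefix (without extension) or the
#'   `.bed` path; for `tsv`, the genotype TSV. A sidecar `<path>.map.tsv` /
#'   `<path>.meta.tsv` pair is read for the TSV dialect when present.
#' @param format `"plink-bed"` or `"tsv"`.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("plink-bed", "tsv")) {
  format <- match.arg(format)
  if (format == "plink-bed") read_plink_bed(path) else read_genotype_tsv(path)
}

#' Write genotypes to PLINK bed/bim/fam or the TSV dialect
#'
#' @param d A [genotype_dataset()].
#' @param path Output prefix (`plink-bed`) or TSV path (`tsv`).
#' @param format `"plink-bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(d, path, format = c("plink-bed", "tsv")) {
  format <- match.arg(format)
  if (format == "plink-bed") write_plink_bed(d, path) else write_genotype_tsv(d, path)
  invisible(path)
}

## --- PLINK 1 binary codec -------------------------------------------------
## SNP-major .bed: magic bytes 0x6c 0x1b 0x01, then per SNP ceil(n/4) bytes,
## 2 bits per sample, low bits first. Codes: 00 = hom a1 (dosage 2),
## 10 = het (1), 11 = hom a2 (0), 01 = missing.

bed_code_to_dosage <- c(2L, NA_integer_, 1L, 0L)  # index by code + 1

read_plink_bed <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)

  bim_df <- utils::read.table(bim, header = FALSE, sep = "\t",
                              colClasses = c("character", "character", "numeric",
                                             "integer", "character", "character"))
  if (ncol(bim_df) != 6) stop("malformed bim: expected 6 columns")
  map <- tibble::tibble(snp = bim_df[[2]], chr = bim_df[[1]],
                        pos = bim_df[[4]], a1 = bim_df[[5]], a2 = bim_df[[6]])
  fam_df <- utils::read.table(fam, header = FALSE, colClasses = "character")
  sex <- dplyr::case_match(fam_df[[5]], "1" ~ "M", "2" ~ "F", .default = NA)
  meta <- tibble::tibble(id = fam_df[[2]], sex = sex, origin = fam_df[[1]])

  n <- nrow(meta); m <- nrow(map)
  raw <- readBin(bed, what = "raw", n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file (bad magic bytes): ", bed)
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  body <- raw[-(1:3)]
  bpp <- ceiling(n / 4)
  if (length(body) != bpp * m) stop("bed payload size mismatch")
  ints <- as.integer(body)
  # unpack 2-bit fields, low bits first
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, ints %/% 64L)
  dim(codes) <- c(4L * bpp, m)
  dosage <- matrix(bed_code_to_dosage[codes[seq_len(n), , drop = FALSE] + 1L],
                   nrow = n, ncol = m,
                   dimnames = list(meta$id, map$snp))
  genotype_dataset(dosage, map, meta)
}

write_plink_bed <- function(d, prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  n <- n_samples(d); m <- n_snps(d)
  sexcode <- dplyr::case_match(d$meta$sex, "M" ~ "1", "F" ~ "2", .default = "0")
  fam <- data.frame(d$meta$origin, d$meta$id, "0", "0", sexcode, "-9")
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(d$map$chr, d$map$snp, 0, d$map$pos, d$map$a1, d$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  dosage_to_code <- function(x) {
    out <- integer(length(x))
    out[is.na(x)] <- 1L
    out[!is.na(x) & x == 2L] <- 0L
    out[!is.na(x) & x == 1L] <- 2L
    out[!is.na(x) & x == 0L] <- 3L
    out
  }
  bpp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * bpp - n
  for (j in seq_len(m)) {
    codes <- c(dosage_to_code(d$dosage[, j]), rep(0L, pad))
    dim(codes) <- c(4L, bpp)
    bytes <- codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] + 64L * codes[4, ]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

## --- TSV dialect ----------------------------------------------------------

read_genotype_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "id") stop("TSV dialect requires first column 'id'")
  ids <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad_na <- !is.na(cells) & cells != "NA" & is.na(num)
  bad_int <- !is.na(num) & (num != round(num) | !(num %in% 0:2))
  bad <- bad_na | bad_int
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-integer or out-of-range dosage at row ", w[1],
         " (sample ", ids[w[1]], "), column ", colnames(cells)[w[2]])
  }
  dosage <- matrix(as.integer(num), nrow = nrow(cells),
                   dimnames = list(ids, colnames(cells)))

  map_path <- paste0(path, ".map.tsv")
  meta_path <- paste0(path, ".meta.tsv")
  map <- if (file.exists(map_path)) {
    readr::read_tsv(map_path, show_col_types = FALSE,
                    col_types = readr::cols(snp = "c", chr = "c", pos = "d",
                                            a1 = "c", a2 = "c"))
  } else {
    tibble::tibble(snp = colnames(dosage), chr = "1",
                   pos = seq_len(ncol(dosage)), a1 = "A", a2 = "B")
  }
  meta <- if (file.exists(meta_path)) {
    readr::read_tsv(meta_path, show_col_types = FALSE)
  } else {
    tibble::tibble(id = ids, sex = NA_character_, origin = NA_character_)
  }
  genotype_dataset(dosage, map, meta)
}

write_genotype_tsv <- function(d, path) {
  df <- data.frame(id = d$meta$id, d$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  readr::write_tsv(d$map, paste0(path, ".map.tsv"))
  readr::write_tsv(d$meta, paste0(path, ".meta.tsv"))
  invisible(path)
}

## --- merging and filtering ------------------------------------------------

#' Merge two genotype datasets on shared marker positions
#'
#' SNPs are matched by (chromosome, position). Allele labels are harmonized:
#' when the two inputs carry the same pair of alleles but with allele 1 and
#' allele 2 swapped, the second dataset's dosages are flipped (`2 - d`).
#' SNPs whose allele pairs can be reconciled neither directly nor by swap,
#' and strand-ambiguous A/T or C/G SNPs, are dropped with a message.
#'
#' @param a,b [genotype_dataset()] objects sharing a position convention.
#' @param drop_ambiguous Drop A/T and C/G SNPs (strand cannot be verified)?
#' @return A merged [genotype_dataset()] containing the intersection of
#'   markers and the union of samples (origin tags preserved).
#' @export
merge_datasets <- function(a, b, drop_ambiguous = TRUE) {
  if (any(b$meta$id %in% a$meta$id)) {
    stop("duplicate sample id(s) across inputs: ",
         paste(utils::head(intersect(a$meta$id, b$meta$id), 3), collapse = ", "))
  }
  key_a <- paste(a$map$chr, a$map$pos)
  key_b <- paste(b$map$chr, b$map$pos)
  shared <- intersect(key_a, key_b)
  if (length(shared) == 0) stop("no SNPs in common between the two datasets")
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)

  a1a <- a$map$a1[ia]; a2a <- a$map$a2[ia]
  a1b <- b$map$a1[ib]; a2b <- b$map$a2[ib]
  same <- a1a == a1b & a2a == a2b
  swap <- a1a == a2b & a2a == a1b & !same
  ambiguous <- drop_ambiguous & is_strand_ambiguous(a1a, a2a)
  keep <- (same | swap) & !ambiguous
  n_bad <- sum(!(same | swap))
  if (n_bad > 0) message(n_bad, " SNP(s) dropped: irreconcilable allele pairs")
  n_amb <- sum(ambiguous & (same | swap))
  if (n_amb > 0) message(n_amb, " strand-ambiguous SNP(s) (A/T or C/G) dropped")
  if (!any(keep)) stop("no SNPs in common after allele harmonization")

  ia <- ia[keep]; ib <- ib[keep]; swap <- swap[keep]
  db <- b$dosage[, ib, drop = FALSE]
  if (any(swap)) db[, swap] <- 2L - db[, swap]
  dosage <- rbind(a$dosage[, ia, drop = FALSE], db)
  colnames(dosage) <- a$map$snp[ia]
  genotype_dataset(dosage, a$map[ia, , drop = FALSE],
                   dplyr::bind_rows(a$meta, b$meta))
}

is_strand_ambiguous <- function(a1, a2) {
  p <- paste0(a1, a2)
  p %in% c("AT", "TA", "CG", "GC")
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs whose minor allele frequency, computed over all non-missing
#' dosages in the current sample set, strictly exceeds `threshold`.
#' Frequencies are always recomputed on the dataset as passed; subsetting
#' samples and re-filtering can therefore retain a different SNP set.
#'
#' @param d A [genotype_dataset()].
#' @param threshold MAF threshold in `[0, 0.5)`; SNPs with
#'   `min(p, 1 - p) > threshold` are kept.
#' @return A filtered [genotype_dataset()].
#' @export
maf_filter <- function(d, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold < 0.5)
  p <- allele_freqs(d)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > threshold
  if (!any(keep)) message("maf_filter: no SNPs retained at threshold ", threshold)
  subset_genotypes(d, snps = which(keep))
}

## --- Norberg-angle score conversion --------------------------------------

#' Norberg-angle score scale
#'
#' The UK (BVA/KC) scheme scores each hip 0-6 from the Norberg angle: a
#' healthy hip with angle above 105 degrees scores 0 and the most severe
#' hips, below 79 degrees, score 6. The intermediate band edges are not
#' standardized in the public literature, so the default divides (79, 105]
#' into six equal-width bands; users holding the original conversion table
#' can supply their own breakpoints.
#'
#' @param breakpoints Six strictly decreasing angle thresholds (degrees)
#'   delimiting scores 0..6; the first must be 105 and the last 79. The
#'   default spaces them evenly.
#' @return An object of class `score_scale`.
#' @export
score_scale <- function(breakpoints = seq(105, 79, length.out = 6)) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) != 6) stop("need exactly 6 breakpoints")
  if (any(diff(breakpoints) >= 0)) stop("breakpoints must be strictly decreasing")
  if (breakpoints[1] != 105 || breakpoints[6] != 79) {
    stop("breakpoints must run from 105 (healthy) down to 79 (severe)")
  }
  structure(list(breakpoints = breakpoints, upper_healthy = 105,
                 lower_severe = 79),
            class = "score_scale")
}

#' Convert Norberg angles to ordinal 0-6 scores
#'
#' Score 0 for angles above 105 degrees, score 6 below 79 degrees; in
#' between, scores increase as the angle decreases through the scale's
#' breakpoints. An angle exactly on a breakpoint takes the lower
#' (healthier) score.
#'
#' @param angle Numeric vector of Norberg angles in degrees.
#' @param scale A [score_scale()].
#' @return Integer scores in 0..6, same length as `angle`.
#' @export
angle_to_score <- function(angle, scale = score_scale()) {
  stopifnot(inherits(scale, "score_scale"), all(is.finite(angle)))
  # score = number of thresholds strictly above the angle; an angle exactly
  # on a threshold therefore takes the lower (healthier) score.
  score <- vapply(angle, function(a) sum(scale$breakpoints > a), integer(1))
  score
}

#' Average left/right hip scores
#'
#' The analysis phenotype is the mean of the left- and right-hip ordinal
#' scores, so values are multiples of 0.5. When one side is missing the
#' available side is used and flagged.
#'
#' @param left,right Integer scores in 0..6 (NA allowed on one side).
#' @return A tibble with columns `score_mean` and `one_sided` (logical flag).
#' @export
mean_lr_score <- function(left, right) {
  stopifnot(length(left) == length(right))
  chk <- function(x) all(is.na(x) | (x >= 0 & x <= 6))
  if (!chk(left) || !chk(right)) stop("scores must be in 0..6")
  both_na <- is.na(left) & is.na(right)
  if (any(both_na)) stop("both sides missing for ", sum(both_na), " record(s)")
  one_sided <- xor(is.na(left), is.na(right))
  m <- rowMeans(cbind(left, right), na.rm = TRUE)
  tibble::tibble(score_mean = m, one_sided = one_sided)
}
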