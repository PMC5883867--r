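#' Genotype dataset container
#'
#' A `genotype_dataset` bundles an individuals-by-SNPs allele-dosage matrix
#' with its marker map and sample metadata. Dosages count copies of `a1`
#' (allele 1) and take values 0, 1, 2 or `NA`.
#'
#' @param dosage Integer matrix, individuals in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids). Values in `{0, 1, 2, NA}`.
#' @param map Tibble with one row per SNP: columns `snp`, `chr`, `pos`
#'   (base pairs, 1-based), `a1`, `a2`. Positions must be strictly
#'   increasing within chromosome.
#' @param meta Tibble with one row per sample: columns `id`, `sex`
#'   (`"M"`/`"F"`), `origin` (population label, e.g. `"POP1"`/`"POP2"`).
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosage, map, meta) {
  map <- tibble::as_tibble(map)
  meta <- tibble::as_tibble(meta)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) rownames(dosage) <- meta$id
  if (is.null(colnames(dosage))) colnames(dosage) <- map$snp
  obj <- structure(
    list(dosage = dosage, map = map, meta = meta),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(obj)
}

validate_genotype_dataset <- function(x) {
  stopifnot(inherits(x, "genotype_dataset"))
  d <- x$dosage
  if (nrow(d) != nrow(x$meta)) {
    stop("dosage rows (", nrow(d), ") != samples in meta (", nrow(x$meta), ")")
  }
  if (ncol(d) != nrow(x$map)) {
    stop("dosage columns (", ncol(d), ") != SNPs in map (", nrow(x$map), ")")
  }
  bad <- d[!is.na(d) & !(d %in% 0:2)]
  if (length(bad) > 0) {
    stop("dosage values must be 0, 1, 2 or NA; found: ",
         paste(utils::head(unique(bad), 3), collapse = ", "))
  }
  if (anyDuplicated(x$meta$id)) stop("duplicate sample ids")
  if (anyDuplicated(x$map$snp)) stop("duplicate SNP ids")
  ord <- x$map |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0) || dplyr::n() == 1L)
  if (!all(ord$ok)) {
    stop("marker positions must be strictly increasing within chromosome")
  }
  x
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " SNPs on ", length(unique(x$map$chr)), " chromosome(s)\n", sep = "")
  if ("origin" %in% names(x$meta)) {
    tab <- table(x$meta$origin)
    cat("  origins:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosage)

#' Number of samples / SNPs in a genotype dataset
#' @param d A `genotype_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(d) nrow(d$dosage)

#' @rdname n_samples
#' @export
n_snps <- function(d) ncol(d$dosage)

#' Subset a genotype dataset by samples and/or SNPs
#'
#' @param d A `genotype_dataset`.
#' @param samples Sample ids (character) or indices to keep; `NULL` keeps all.
#' @param snps SNP ids (character) or indices to keep; `NULL` keeps all.
#' @return A `genotype_dataset` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(d, samples = NULL, snps = NULL) {
  ri <- if (is.null(samples)) seq_len(nrow(d$dosage)) else {
    if (is.character(samples)) match(samples, d$meta$id) else samples
  }
  ci <- if (is.null(snps)) seq_len(ncol(d$dosage)) else {
    if (is.character(snps)) match(snps, d$map$snp) else snps
  }
  if (anyNA(ri)) stop("unknown sample id(s)")
  if (anyNA(ci)) stop("unknown SNP id(s)")
  genotype_dataset(
    d$dosage[ri, ci, drop = FALSE],
    d$map[ci, , drop = FALSE],
    d$meta[ri, , drop = FALSE]
  )
}

#' Per-SNP allele frequencies
#'
#' Frequency of allele 1 computed over non-missing dosages.
#'
#' @param d A `genotype_dataset`.
#' @return Named numeric vector of allele-1 frequencies, one per SNP.
#' @export
allele_freqs <- function(d) {
  colMeans(d$dosage, na.rm = TRUE) / 2
}
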