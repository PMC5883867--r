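#' Pipeline run configuration
#'
#' Bundles either on-disk inputs (genotypes + phenotypes) or a
#' [sim_config()] together with the analysis constants. Every constant
#' the analysis relies on is a named default here: GRM ridge 0.01, MAF
#' threshold 0.01, 5 folds, 10 cross-validation replicates, 20 random
#' subset replicates, REML tolerance 1e-5.
#'
#' @param sim A [sim_config()], or `NULL` when reading real inputs.
#' @param genotype_path,phenotype_path Paths to inputs (mutually exclusive
#'   with `sim`). `genotype_format` as in [read_genotypes()].
#' @param genotype_format `"tsv"` or `"plink-bed"`.
#' @param ridge GRM diagonal ridge.
#' @param maf MAF threshold.
#' @param k Folds.
#' @param cv_replicates Replicates of the fold split.
#' @param schemes Training schemes to run (see [cv_config()]).
#' @param subset_fractions SNP fractions for the subset experiment;
#'   `NULL` skips it.
#' @param subset_random_replicates Random-subset replicates.
#' @param run_blocks Compute haplotype blocks and coverage?
#' @param seed Base seed for all randomized stages.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = NULL, genotype_path = NULL,
                       phenotype_path = NULL, genotype_format = "tsv",
                       ridge = 0.01, maf = 0.01, k = 5, cv_replicates = 10,
                       schemes = c("joint", "pop1-only", "pop2-only"),
                       subset_fractions = NULL,
                       subset_random_replicates = 20,
                       run_blocks = FALSE, seed = 1) {
  has_sim <- !is.null(sim)
  has_real <- !is.null(genotype_path) || !is.null(phenotype_path)
  if (has_sim == has_real) {
    stop("exactly one of `sim` or (genotype_path, phenotype_path) required")
  }
  if (has_real && (is.null(genotype_path) || is.null(phenotype_path))) {
    stop("both genotype_path and phenotype_path are required")
  }
  structure(as.list(environment())[c(
    "sim", "genotype_path", "phenotype_path", "genotype_format", "ridge",
    "maf", "k", "cv_replicates", "schemes", "subset_fractions",
    "subset_random_replicates", "run_blocks", "seed")],
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `sim:` mapping
#' is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) -> MAF filter -> joint GRM -> replicated k-fold
#' cross-validation under each training scheme -> optional SNP-subset
#' experiment -> optional haplotype blocks and coverage. All numeric
#' artifacts are written as TSV/JSON under `out_dir` together with a
#' manifest recording the seed and configuration, so a rerun with the
#' same config is byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return A list: `cv` (named list of `cv_report` per scheme, and a
#'   combined Table-2-shaped `grid`), `grm_summary`, `fst`, `h2_full`,
#'   `subset` (or NULL), `coverage` (or NULL), `cohort`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- ingest / simulate
  if (!is.null(config$sim)) {
    cohort <- stage("simulate", simulate_cohort(config$sim))
    geno <- cohort$genotypes
    phen <- cohort$phenotypes
  } else {
    geno <- stage("ingest", read_genotypes(config$genotype_path,
                                           config$genotype_format))
    phen <- stage("ingest", readr::read_tsv(config$phenotype_path,
                                            show_col_types = FALSE))
    cohort <- NULL
  }

  # --- filter
  geno <- stage("maf_filter", {
    g <- maf_filter(geno, config$maf)
    if (n_snps(g) == 0) stop("no SNPs retained at MAF ", config$maf)
    g
  })

  # --- relationships
  grm <- stage("grm", compute_grm(geno, ridge = config$ridge))
  grm_summary <- grm_group_summary(grm, geno$meta$origin)
  fst_out <- if (length(unique(geno$meta$origin)) == 2) {
    stage("fst", fst(geno))
  } else NULL

  # --- full-data heritability
  h2_full <- stage("reml_full", {
    W <- design_matrix(phen)
    fit <- fit_aireml(phen$score_mean, W, grm$K[phen$id, phen$id])
    glance(fit)
  })

  # --- cross-validation grid
  cv <- stage("cv", {
    reports <- purrr::map(config$schemes, function(s) {
      run_cv(phen, grm,
             cv_config(scheme = s, k = config$k,
                       replicates = config$cv_replicates,
                       ridge = 0,  # ridge already in grm
                       seed = config$seed))
    })
    names(reports) <- config$schemes
    grid <- purrr::map_dfr(reports, ~ .x$summary)
    list(reports = reports, grid = grid)
  })

  # --- SNP-subset experiment
  subset_out <- if (!is.null(config$subset_fractions)) {
    stage("subset", subset_prediction_experiment(
      phen, geno, fractions = config$subset_fractions,
      k = config$k, random_replicates = config$subset_random_replicates,
      ridge = config$ridge, seed = config$seed))
  } else NULL

  # --- haplotype blocks / coverage
  coverage_out <- if (isTRUE(config$run_blocks)) {
    stage("blocks", {
      blocks <- estimate_blocks(geno)
      if (nrow(blocks) == 0) NULL else {
        frs <- config$subset_fractions %||% c(0.25, 0.5, 1)
        purrr::map_dfr(frs, function(fr) {
          sub <- select_subset(geno, fr, "random", seed = config$seed)
          tibble::tibble(fraction = fr, mode = "random",
                         coverage = coverage_fraction(blocks, sub)$genome)
        })
      }
    })
  } else NULL

  out <- list(cv = cv, grm_summary = grm_summary, fst = fst_out,
              h2_full = h2_full, subset = subset_out,
              coverage = coverage_out, cohort = cohort)
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(out$cv$grid, file.path(out_dir, "cv_grid.tsv"))
  purrr::iwalk(out$cv$reports, function(rep, nm) {
    readr::write_tsv(rep$folds, file.path(out_dir, paste0("cv_folds_", nm, ".tsv")))
  })
  readr::write_tsv(out$grm_summary, file.path(out_dir, "grm_summary.tsv"))
  if (!is.null(out$fst)) {
    readr::write_tsv(out$fst$per_snp, file.path(out_dir, "fst_per_snp.tsv"))
  }
  readr::write_tsv(out$h2_full, file.path(out_dir, "h2_full.tsv"))
  if (!is.null(out$subset)) {
    readr::write_tsv(out$subset, file.path(out_dir, "subset_experiment.tsv"))
  }
  if (!is.null(out$coverage)) {
    readr::write_tsv(out$coverage, file.path(out_dir, "block_coverage.tsv"))
  }
  manifest <- list(
    seed = config$seed,
    config = config[setdiff(names(config), "sim")],
    sim = if (!is.null(config$sim)) unclass(config$sim) else NULL,
    mean_fst = if (!is.null(out$fst)) out$fst$mean_fst else NULL,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("jointgp")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
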