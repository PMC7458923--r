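#' Pipeline configuration
#'
#' Assembles the full study workflow over one compound table: diversity
#' summary, Bray-Curtis dissimilarity, nMDS + PCoA ordination, dispersion
#' homogeneity with Tukey screening, PERMANOVA, per-season SIMPER with the
#' consistent-marker intersection, PCA reduction, and the RF stability
#' protocol. Defaults are desk-scale (999 permutations, 100 RF runs); the
#' study-scale settings are 9,999 and 1,000.
#'
#' @param spec a [synthetic_spec()] to generate data from, or NULL when
#'   `matrix_path`/`meta_path` are given.
#' @param matrix_path,meta_path,annotation_path optional input files read
#'   with [read_compound_table()] / [read_sample_metadata()].
#' @param simper_years years treated as the reproductive seasons for the
#'   per-season SIMPER runs.
#' @param permanova_terms,n_perm,strata passed to [permanova()].
#' @param simper_n_perm,simper_alpha SIMPER permutations and the
#'   cross-season consistency threshold.
#' @param pca_threshold cumulative-variance cutoff for [pca_select()].
#' @param rf passed as [rf_config()] fields (seed is overridden by the
#'   master seed fan-out).
#' @param nmds_k,nmds_starts nMDS dimension and starts.
#' @param master_seed one seed fanning out deterministic per-stage seeds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = NULL, matrix_path = NULL,
                            meta_path = NULL, annotation_path = NULL,
                            simper_years = c(2012L, 2014L),
                            permanova_terms = c("year", "species", "sex",
                                                "year:species", "year:sex",
                                                "species:sex",
                                                "year:species:sex"),
                            n_perm = 999, strata = "year",
                            simper_n_perm = 999, simper_alpha = 0.01,
                            pca_threshold = 0.75,
                            rf = list(n_runs = 100, n_trees = 500,
                                      mtry = 17),
                            nmds_k = 3, nmds_starts = 5,
                            master_seed = 1L) {
  if (is.null(spec) && (is.null(matrix_path) || is.null(meta_path)))
    stop("provide either a synthetic spec or matrix_path + meta_path")
  if (!is.null(matrix_path) && !file.exists(matrix_path))
    stop("matrix file not found: ", matrix_path)
  if (!is.null(meta_path) && !file.exists(meta_path))
    stop("metadata file not found: ", meta_path)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full study workflow
#'
#' Executes every stage on the same in-memory table (downstream stages
#' never re-parse files, so report sections cannot drift). All randomness
#' fans out from `master_seed`; rerunning with the same config reproduces
#' the report exactly. A failing stage is recorded in `$errors` and later
#' independent stages still run.
#'
#' @param config a [pipeline_config()].
#' @return list of class `study_report` with sections `data`, `diversity`,
#'   `ordination`, `dispersion`, `permanova`, `simper`, `markers`, `pca`,
#'   `rf`, `errors`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$master_seed, 8L)
  report <- list(errors = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  if (!is.null(config$spec)) {
    gen <- generate_profiles(config$spec)
    tab <- gen$table; md <- gen$metadata
  } else {
    tab <- read_compound_table(config$matrix_path, config$annotation_path)
    tab <- normalize_rows(tab)
    md <- read_sample_metadata(config$meta_path, tab)
  }
  report$data <- list(n_samples = nrow(tab$abundances),
                      n_compounds = ncol(tab$abundances),
                      groups = table(md$year, md$species, md$sex))

  report$diversity <- stage("diversity", summarize_by_group(tab, md))
  d <- bray_curtis_matrix(tab)
  report$ordination <- stage("ordination", {
    pc <- pcoa(d)
    nm <- nmds(d, k = config$nmds_k, n_starts = config$nmds_starts,
               seed = seeds[1])
    list(pcoa = pc, nmds = nm,
         pcoa_pct = 100 * pc$variance_explained[1:2])
  })
  report$dispersion <- stage("dispersion", {
    grp <- interaction(md$year, md$species, md$sex, drop = TRUE)
    disp <- permdisp(d, grp)
    c(list(dispersion = disp), tukey_hsd_dispersion(disp))
  })
  report$permanova <- stage("permanova",
    permanova(d, md, terms = config$permanova_terms,
              n_perm = config$n_perm, strata = config$strata,
              seed = seeds[2]))
  report$simper <- stage("simper", {
    res <- list()
    for (i in seq_along(config$simper_years)) {
      yr <- config$simper_years[i]
      sub <- subset_samples(tab, md, year == yr)
      res[[as.character(yr)]] <- simper(sub$table, sub$metadata$species,
                                        n_perm = config$simper_n_perm,
                                        seed = seeds[3] + i)
    }
    res
  })
  report$markers <- stage("markers",
    consistent_markers(report$simper, alpha = config$simper_alpha))
  report$pca <- stage("pca", {
    mk <- report$markers$markers
    if (length(mk) >= 2)
      pca_select(tab, mk, cumulative_threshold = config$pca_threshold)
    else list(skipped = "fewer than 2 consistent markers")
  })
  report$rf <- stage("rf", {
    cfg <- do.call(rf_config, c(config$rf, list(master_seed = seeds[4])))
    rf_protocol(tab, md$species, cfg)
  })
  report$provenance <- list(
    master_seed = config$master_seed,
    package_version = as.character(utils::packageVersion("iguanachem")),
    n_perm = config$n_perm, simper_n_perm = config$simper_n_perm,
    rf = config$rf, strata = config$strata)
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n")
  cat(sprintf("  data: %d samples x %d compounds\n",
              x$data$n_samples, x$data$n_compounds))
  if (!is.null(x$diversity))
    cat(sprintf("  diversity groups: %d\n", nrow(x$diversity)))
  if (!is.null(x$dispersion))
    cat(sprintf("  dispersion F = %.2f (p = %.3g), homogeneous pairs: %.0f%%\n",
                x$dispersion$dispersion$anova_f,
                x$dispersion$dispersion$anova_p,
                100 * x$dispersion$percent_homogeneous))
  if (!is.null(x$markers))
    cat(sprintf("  consistent markers: %d\n", length(x$markers$markers)))
  if (!is.null(x$rf))
    cat(sprintf("  RF mean accuracy %.3f, kappa %.3f, AUC %.3f\n",
                x$rf$metrics[["accuracy"]], x$rf$metrics[["kappa"]],
                x$rf$auc))
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
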