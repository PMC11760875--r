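# End-to-end analysis driver: simulate (optional) -> digitize -> QC -> GPA
# -> symmetry decomposition -> PCA -> Procrustes ANCOVA with RRPP ->
# dispersion homogeneity check. Mirrors the stage order of the published
# workflow and emits a machine-readable report.

#' Run the full spore-shape analysis pipeline
#'
#' @param config A list (or path to a YAML file, requiring the `yaml`
#'   package) with components:
#'   \describe{
#'     \item{spec}{a [population_spec()]; when absent,
#'       [default_calibration()] is used}
#'     \item{seed}{root seed overriding the spec's}
#'     \item{dataset}{an existing `landmark_dataset` to analyse instead of
#'       simulating}
#'     \item{n_perm}{RRPP iterations (default 10000)}
#'     \item{out_dir}{optional directory: aligned coordinates, scores and
#'       the JSON report are written there}
#'   }
#' @return Object of class `pipeline_report` with elements `qc`, `gpa`
#'   (summary), `tangent_check`, `symmetry`, `pca`, `meaningful_pcs`,
#'   `ancova`, `size_anova`, `dispersion`, `seeds`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_cm("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  spec <- config$spec %||% default_calibration()
  if (!is.null(config$seed)) spec$seed <- as.integer(config$seed)
  n_perm <- config$n_perm %||% 10000L
  stage <- "simulate"
  report <- tryCatch({
    if (is.null(config$dataset)) {
      specimens <- sample_population(spec)
      dataset <- digitize_replicates(specimens)
    } else {
      dataset <- config$dataset
    }

    stage <- "qc"
    qc <- qc_report(dataset)

    stage <- "gpa"
    avg <- average_replicates(dataset)
    g <- gpa(avg)
    tcheck <- tangent_space_check(g)

    stage <- "symmetry"
    sym <- decompose_symmetry(dataset)

    stage <- "pca"
    X <- tangent_projection(g)
    pca <- shape_pca(X)
    n_meaningful <- meaningful_pcs(pca$eigenvalues)
    hulls <- convex_hulls(pca$scores[, 1:2], dataset$host_id)

    stage <- "ancova"
    sizes <- g$centroid_sizes
    ancova <- rrpp_test(model_spec(sym$symmetric_tangent, size = sizes,
                                   host = dataset$host_id,
                                   terms = c("size", "host", "size:host"),
                                   n_perm = n_perm, seed = spec$seed))
    size_tab <- size_anova(sizes, dataset$host_id, n_perm = n_perm,
                           seed = spec$seed)

    stage <- "dispersion"
    disp <- dispersion_test(X, dataset$host_id, n_perm = min(n_perm, 999L),
                            seed = spec$seed)

    list(qc = qc,
         gpa = list(iterations = g$iterations, converged = g$converged,
                    centroid_sizes = sizes),
         tangent_check = tcheck, symmetry = sym, pca = pca,
         meaningful_pcs = n_meaningful, hulls = hulls,
         ancova = ancova, size_anova = size_tab, dispersion = disp,
         seeds = list(root = spec$seed, n_perm = n_perm))
  }, error = function(e) {
    stop_cm("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  class(report) <- "pipeline_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(specimen = seq_along(report$gpa$centroid_sizes),
                                centroid_size = report$gpa$centroid_sizes),
                     file.path(config$out_dir, "centroid_sizes.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report$pca$scores),
                     file.path(config$out_dir, "pc_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(pipeline_summary(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# flat numeric summary of a pipeline report (used for the JSON output)
pipeline_summary <- function(report) {
  list(
    rpt_average = report$qc$rpt_average,
    pct_me = report$qc$pct_me,
    n_outliers = length(report$qc$outlier_ids),
    tangent_correlation = report$tangent_check$correlation,
    pct_symmetric = report$symmetry$pct_symmetric,
    pct_asymmetric = report$symmetry$pct_asymmetric,
    pc1_pct = report$pca$variance_pct[1],
    pc12_pct = sum(report$pca$variance_pct[1:2]),
    meaningful_pcs = report$meaningful_pcs,
    size_cv_pct = 100 * stats::sd(report$gpa$centroid_sizes) /
      mean(report$gpa$centroid_sizes),
    ancova = lapply(seq_len(nrow(report$ancova)), function(i) {
      as.list(report$ancova[i, c("Df", "SS", "MS", "Rsq", "F", "Z", "p")])
    }),
    size_host_rsq_pct = 100 * report$size_anova["host", "Rsq"],
    size_host_p = report$size_anova["host", "p"],
    dispersion_F = report$dispersion$F,
    dispersion_p = report$dispersion$p
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Spore-shape analysis report\n")
  cat(sprintf("  RPT %.4f | %%ME %.3f | outliers %d\n", x$qc$rpt_average,
              x$qc$pct_me, length(x$qc$outlier_ids)))
  cat(sprintf("  symmetric %.1f %% | PC1 %.1f %% | PC1+2 %.1f %% | %d meaningful PCs\n",
              x$symmetry$pct_symmetric, x$pca$variance_pct[1],
              sum(x$pca$variance_pct[1:2]), x$meaningful_pcs))
  cat(sprintf("  size CV %.1f %% | host R2 (size) %.1f %% | dispersion p %.3f\n",
              100 * stats::sd(x$gpa$centroid_sizes) / mean(x$gpa$centroid_sizes),
              100 * x$size_anova["host", "Rsq"], x$dispersion$p))
  cat("  ANCOVA (shape ~ size * host):\n")
  tab <- x$ancova
  for (i in seq_len(nrow(tab) - 2L))
    cat(sprintf("    %-16s F = %6.2f  Z = %5.2f  p = %s\n", rownames(tab)[i],
                tab$F[i], tab$Z[i], format.pval(tab$p[i], digits = 3)))
  invisible(x)
}
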