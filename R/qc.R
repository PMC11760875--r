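# Digitization quality control: repeatability (intraclass correlation of
# Procrustes coordinates across replicates), percent measurement error from
# a Procrustes ANOVA, and outlier screening by Procrustes distance from the
# mean shape. All replicates are superimposed in one joint GPA so that
# replicate placements are compared in a common frame.

qc_tangent <- function(dataset) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  r <- dim(dataset$coords)[2]
  if (r < 2L) stop_cm("quality control needs at least 2 replicates")
  g <- gpa(dataset)
  X <- tangent_projection(g)
  list(X = X, specimen = g$info$specimen, r = r, gpa = g)
}

# one-way random-effects variance components for a vector of observations
# grouped by specimen; r_eff is the harmonic-mean replicate count
anova_components <- function(y, specimen, r_eff) {
  n_g <- length(unique(specimen))
  N <- length(y)
  gm <- mean(y)
  means <- tapply(y, specimen, mean)
  counts <- tapply(y, specimen, length)
  ss_among <- sum(counts * (means - gm)^2)
  ss_within <- sum((y - means[as.character(specimen)])^2)
  ms_among <- ss_among / (n_g - 1L)
  ms_within <- ss_within / (N - n_g)
  s2_among <- max((ms_among - ms_within) / r_eff, 0)
  list(ms_among = ms_among, ms_within = ms_within,
       s2_among = s2_among, s2_within = ms_within,
       ss_among = ss_among, ss_within = ss_within,
       df_among = n_g - 1L, df_within = N - n_g)
}

#' Repeatability of Procrustes coordinates across digitization replicates
#'
#' All replicate configurations are jointly superimposed; each tangent-space
#' coordinate is then submitted to a one-way random-effects ANOVA with
#' specimen as the grouping factor. The repeatability of a coordinate is the
#' intraclass correlation ICC = s2_among / (s2_among + s2_within), with the
#' among-specimen variance component truncated at zero.
#'
#' @param dataset A `landmark_dataset` with at least 2 replicates.
#' @return List with `rpt_per_coordinate` (length 16, in `[0, 1]`) and
#'   `rpt_average`, their mean.
#' @export
repeatability <- function(dataset) {
  qt <- qc_tangent(dataset)
  specimen <- factor(qt$specimen)
  r_eff <- harmonic_mean(tabulate(specimen))
  icc <- apply(qt$X, 2L, function(y) {
    vc <- anova_components(y, specimen, r_eff)
    if (vc$s2_among + vc$s2_within == 0) return(1)
    vc$s2_among / (vc$s2_among + vc$s2_within)
  })
  list(rpt_per_coordinate = icc, rpt_average = mean(icc))
}

harmonic_mean <- function(x) length(x) / sum(1 / x)

#' Percent measurement error from a Procrustes ANOVA
#'
#' Pools the tangent-space sums of squares over all coordinates into a
#' Procrustes ANOVA with specimens as groups and replicates within, and
#' expresses the within-specimen (digitization) variance component as a
#' percentage of the total: `%ME = 100 s2_within / (s2_among + s2_within)`.
#'
#' @param dataset A `landmark_dataset` with at least 2 replicates.
#' @return Percent measurement error in `[0, 100]`.
#' @export
measurement_error <- function(dataset) {
  qt <- qc_tangent(dataset)
  specimen <- factor(qt$specimen)
  r_eff <- harmonic_mean(tabulate(specimen))
  n_g <- nlevels(specimen); N <- length(specimen)
  ss_among <- 0; ss_within <- 0
  for (j in seq_len(ncol(qt$X))) {
    y <- qt$X[, j]
    means <- stats::ave(y, specimen)
    gm <- mean(y)
    ss_among <- ss_among + sum((means - gm)^2)
    ss_within <- ss_within + sum((y - means)^2)
  }
  ms_among <- ss_among / (n_g - 1L)
  ms_within <- ss_within / (N - n_g)
  s2_among <- max((ms_among - ms_within) / r_eff, 0)
  s2_within <- ms_within
  if (s2_among + s2_within == 0) return(0)
  100 * s2_within / (s2_among + s2_within)
}

#' Screen for aberrant configurations
#'
#' Orders specimens by their Procrustes distance from the consensus and
#' flags potential outliers. The default rule is the Tukey fence
#' (`d > Q3 + 1.5 IQR`); the literal upper-quartile rule (`d > Q3`), which
#' by construction flags about a quarter of any sample, is available for
#' comparison.
#'
#' @param gpa_res A converged [gpa()] result.
#' @param rule `"iqr_fence"` (default) or `"literal_upper_quartile"`.
#' @return List with `outlier_ids` (indices into the configuration list)
#'   and `distances_to_mean` (geodesic Procrustes distances, ordered as the
#'   input).
#' @export
flag_outliers <- function(gpa_res, rule = c("iqr_fence", "literal_upper_quartile")) {
  stopifnot(inherits(gpa_res, "gpa_result"))
  rule <- match.arg(rule)
  m <- dim(gpa_res$aligned)[1]
  d <- vapply(seq_len(m), function(i) {
    procrustes_distance(gpa_res$aligned[i, , ], gpa_res$consensus)$rho
  }, numeric(1))
  q3 <- stats::quantile(d, 0.75, names = FALSE)
  cut <- if (rule == "iqr_fence") {
    q3 + 1.5 * (q3 - stats::quantile(d, 0.25, names = FALSE))
  } else q3
  list(outlier_ids = which(d > cut), distances_to_mean = d, rule = rule,
       threshold = cut)
}

#' Full digitization quality-control report
#'
#' @param dataset A `landmark_dataset` with at least 2 replicates.
#' @param rule Outlier rule passed to [flag_outliers()]; outliers are
#'   screened on the replicate-averaged configurations.
#' @return Object of class `qc_report` combining [repeatability()],
#'   [measurement_error()] and [flag_outliers()].
#' @export
qc_report <- function(dataset, rule = "iqr_fence") {
  rpt <- repeatability(dataset)
  pct_me <- measurement_error(dataset)
  g_avg <- gpa(average_replicates(dataset))
  fl <- flag_outliers(g_avg, rule)
  out <- list(rpt_per_coordinate = rpt$rpt_per_coordinate,
              rpt_average = rpt$rpt_average, pct_me = pct_me,
              outlier_ids = fl$outlier_ids,
              distances_to_mean = fl$distances_to_mean)
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Digitization quality control\n")
  cat(sprintf("  average repeatability (ICC): %.4f\n", x$rpt_average))
  cat(sprintf("  measurement error:           %.3f %%\n", x$pct_me))
  cat(sprintf("  potential outliers:          %s\n",
              if (length(x$outlier_ids)) paste(x$outlier_ids, collapse = ", ")
              else "none"))
  invisible(x)
}
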