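# Procrustes ANOVA/ANCOVA with residual-randomization permutation (RRPP)
# inference. Sums of squares are sequential (type I) and, for a
# multivariate shape response, are traces of residual cross-products, i.e.
# sums of squared Procrustes residual distances in tangent space. For each
# term, RRPP permutes the residuals of the reduced model (the terms
# preceding it), adds them back to the reduced-model fitted values and
# recomputes the pseudo-F; the observed arrangement counts as one
# iteration, so the smallest attainable p is 1/n_perm.

#' Specify a shape-or-size model for RRPP inference
#'
#' @param response m x p response matrix: tangent-space shape coordinates
#'   (typically the symmetric component) or an m x 1 matrix of centroid
#'   sizes.
#' @param size Optional length-m covariate (centroid size). Raw centroid
#'   size is the conventional covariate; set `log_size = TRUE` to use its
#'   logarithm.
#' @param host Optional length-m group factor (host identity).
#' @param terms Ordered character vector from `"size"`, `"host"`,
#'   `"size:host"`; order matters because sums of squares are sequential.
#' @param n_perm Number of permutation iterations, observed arrangement
#'   included (default 10000).
#' @param seed Seed for the permutation schedule.
#' @param log_size Use log centroid size as the covariate.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(response, size = NULL, host = NULL,
                       terms = c("size", "host", "size:host"),
                       n_perm = 10000L, seed = 1L, log_size = FALSE) {
  Y <- as.matrix(response)
  m <- nrow(Y)
  terms <- match.arg(terms, c("size", "host", "size:host"), several.ok = TRUE)
  if ("size:host" %in% terms && !all(c("size", "host") %in% terms))
    stop_cm("the size:host interaction requires both main effects")
  if (any(c("size", "size:host") %in% terms)) {
    if (is.null(size) || length(size) != m) stop_cm("size covariate missing or wrong length")
    if (log_size) size <- log(size)
  }
  if (any(c("host", "size:host") %in% terms)) {
    if (is.null(host) || length(host) != m) stop_cm("host factor missing or wrong length")
    host <- factor(host)
    if (nlevels(host) < 2L) stop_cm("host must have at least 2 levels")
  }
  spec <- list(response = Y, size = size, host = host, terms = terms,
               n_perm = as.integer(n_perm), seed = as.integer(seed))
  class(spec) <- "model_spec"
  spec
}

# sequential orthonormal bases: intercept, then each term's added columns
model_bases <- function(model) {
  Y <- model$response
  m <- nrow(Y)
  blocks <- list()
  for (tm in model$terms) {
    blocks[[tm]] <- switch(tm,
      size = matrix(model$size, m, 1L),
      host = stats::model.matrix(~ model$host)[, -1L, drop = FALSE],
      `size:host` = {
        H <- stats::model.matrix(~ model$host)[, -1L, drop = FALSE]
        H * model$size
      })
  }
  X <- matrix(1, m, 1L)
  qr_prev <- qr(X)
  rank_prev <- qr_prev$rank
  Qs <- list(qr.Q(qr_prev)[, seq_len(rank_prev), drop = FALSE])
  df <- integer(0)
  for (j in seq_along(blocks)) {
    expected <- ncol(blocks[[j]])
    X <- cbind(X, blocks[[j]])
    qr_j <- qr(X)
    added <- qr_j$rank - rank_prev
    if (added < expected)
      stop_cm("rank-deficient design: term '", model$terms[j],
              "' is aliased with preceding terms")
    df <- c(df, added)
    rank_prev <- qr_j$rank
    Qs[[j + 1L]] <- qr.Q(qr_j)[, seq_len(rank_prev), drop = FALSE]
  }
  if (m <= rank_prev) stop_cm("more model degrees of freedom than specimens")
  list(Qs = Qs, df = df, rank_full = rank_prev)
}

rss_of <- function(Q, Y) sum(Y^2) - sum(crossprod(Q, Y)^2)

#' Fit a sequential (type I) Procrustes ANOVA/ANCOVA
#'
#' Computes sequential sums of squares based on Procrustes distance: the SS
#' of each term is the drop in residual SS (trace of the residual
#' cross-product) when the term is added to the preceding ones. Pseudo-F
#' statistics use the full-model residual mean square.
#'
#' @param model A [model_spec()].
#' @return Object of class `rrpp_table` (data frame with Df, SS, MS, Rsq,
#'   F per term plus Residuals and Total rows); no permutation columns yet.
#' @export
fit_sequential <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  Y <- model$response
  m <- nrow(Y)
  bases <- model_bases(model)
  n_terms <- length(model$terms)
  rss <- vapply(bases$Qs, rss_of, numeric(1), Y = Y)
  ss_total <- rss[1L]
  ss_terms <- rss[-length(rss)] - rss[-1L]
  rss_full <- rss[length(rss)]
  df_res <- m - bases$rank_full
  ms_res <- rss_full / df_res
  tab <- data.frame(
    Df = c(bases$df, df_res, m - 1L),
    SS = c(ss_terms, rss_full, ss_total),
    MS = c(ss_terms / bases$df, ms_res, NA),
    Rsq = c(ss_terms / ss_total, rss_full / ss_total, NA),
    F = c((ss_terms / bases$df) / ms_res, NA, NA),
    row.names = c(model$terms, "Residuals", "Total")
  )
  attr(tab, "bases") <- bases
  attr(tab, "model") <- model
  class(tab) <- c("rrpp_table", "data.frame")
  tab
}

#' RRPP permutation inference for a sequential model
#'
#' Adds permutation p-values and effect sizes to [fit_sequential()]. For
#' term k, residuals of the reduced model (terms 1..k-1) are row-permuted
#' and added to the reduced-model fitted values; the term's pseudo-F is
#' recomputed on each permuted dataset. `p` is the proportion of the
#' `n_perm` statistics (observed included) at least as large as the
#' observed; `Z = (log F_obs - mean log F*) / sd log F*`.
#'
#' @param model A [model_spec()].
#' @return An `rrpp_table` with `Z` and `p` columns filled in.
#' @export
rrpp_test <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  if (model$n_perm < 100L)
    warning("n_perm < 100 gives a very coarse permutation p-value")
  tab <- fit_sequential(model)
  bases <- attr(tab, "bases")
  Y <- model$response
  m <- nrow(Y)
  n_terms <- length(model$terms)
  df_res <- m - bases$rank_full
  set.seed(model$seed)
  perms <- replicate(model$n_perm - 1L, sample.int(m))
  Qfull <- bases$Qs[[n_terms + 1L]]
  Z <- p <- numeric(n_terms)
  for (k in seq_len(n_terms)) {
    Qred <- bases$Qs[[k]]
    Qk <- bases$Qs[[k + 1L]]
    fit_red <- Qred %*% crossprod(Qred, Y)
    res_red <- Y - fit_red
    Fs <- numeric(model$n_perm)
    Fs[1L] <- tab$F[k]
    if (model$n_perm > 1L) for (i in seq_len(model$n_perm - 1L)) {
      Yp <- fit_red + res_red[perms[, i], , drop = FALSE]
      ss_k <- sum(crossprod(Qk, Yp)^2) - sum(crossprod(Qred, Yp)^2)
      rss_full <- sum(Yp^2) - sum(crossprod(Qfull, Yp)^2)
      Fs[i + 1L] <- (ss_k / bases$df[k]) / (rss_full / df_res)
    }
    p[k] <- mean(Fs >= tab$F[k] - 1e-12)
    logf <- log(pmax(Fs, .Machine$double.xmin))
    s <- stats::sd(logf)
    Z[k] <- if (is.finite(s) && s > 0) (logf[1L] - mean(logf)) / s else 0
  }
  tab$Z <- c(Z, NA, NA)
  tab$p <- c(p, NA, NA)
  attr(tab, "n_perm") <- model$n_perm
  tab
}

#' @export
print.rrpp_table <- function(x, digits = 4L, ...) {
  cat("Sequential (type I) RRPP table\n")
  if (!is.null(attr(x, "n_perm")))
    cat(sprintf("  %d permutation iterations (observed included)\n",
                attr(x, "n_perm")))
  df <- as.data.frame(x)
  print(format(df, digits = digits), ...)
  invisible(x)
}

#' One-way permutation ANOVA of centroid size among hosts
#'
#' Univariate special case of the sequential RRPP machinery: tests whether
#' spore size (centroid size) differs among host individuals and reports the
#' host R-squared.
#'
#' @param sizes Length-m centroid sizes.
#' @param host_id Length-m host factor.
#' @param n_perm Permutation iterations (observed included).
#' @param seed Permutation seed.
#' @return An `rrpp_table` with a single host term.
#' @export
size_anova <- function(sizes, host_id, n_perm = 10000L, seed = 1L) {
  model <- model_spec(matrix(as.numeric(sizes), ncol = 1L), host = host_id,
                      terms = "host", n_perm = n_perm, seed = seed)
  rrpp_test(model)
}

#' Permutational test of multivariate dispersion homogeneity
#'
#' Computes each specimen's Euclidean distance to its group centroid in
#' tangent space, then tests equality of mean distances among groups with a
#' one-way ANOVA F whose p-value is obtained by permuting group labels
#' (observed arrangement included). This is the homogeneity check that
#' permutation ANOVA/ANCOVA designs are sensitive to.
#'
#' @param coords m x p matrix of tangent coordinates.
#' @param groups Length-m group factor (at least 2 groups, each with at
#'   least 2 members).
#' @param n_perm Permutation iterations (observed included).
#' @param seed Permutation seed.
#' @return List with `F`, `p`, `per_group_mean_distance` and `distances`.
#' @export
dispersion_test <- function(coords, groups, n_perm = 999L, seed = 1L) {
  X <- as.matrix(coords)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_cm("need at least 2 groups")
  if (any(tabulate(groups) < 2L)) stop_cm("singleton group: dispersion undefined")
  centroids <- apply(X, 2L, function(col) tapply(col, groups, mean))
  d <- sqrt(rowSums((X - centroids[as.integer(groups), , drop = FALSE])^2))
  f_stat <- function(lab) {
    gm <- mean(d)
    means <- tapply(d, lab, mean)
    counts <- tabulate(lab)
    ss_b <- sum(counts * (means - gm)^2)
    ss_w <- sum((d - means[as.integer(lab)])^2)
    ((ss_b / (nlevels(lab) - 1L)) / (ss_w / (length(d) - nlevels(lab))))
  }
  f_obs <- f_stat(groups)
  set.seed(seed)
  fs <- numeric(n_perm)
  fs[1L] <- f_obs
  if (n_perm > 1L) for (i in seq_len(n_perm - 1L)) {
    fs[i + 1L] <- f_stat(groups[sample.int(length(d))])
  }
  list(F = f_obs, p = mean(fs >= f_obs - 1e-12),
       per_group_mean_distance = tapply(d, groups, mean),
       distances = d)
}
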