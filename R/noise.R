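#' Fit the CV-versus-mean trend
#'
#' Penalized cubic regression spline with shrinkage (`mgcv::gam`,
#' `y ~ s(x, bs = "cs")`, GCV-selected penalty) of `log2(CV + 1)` on the
#' per-gene mean. The fitted trend is the mean-dependent component of
#' expression noise; its residuals define the adjusted CV. When the
#' means are (nearly) constant the fit degenerates to a constant at the
#' mean of `log2(CV + 1)` (documented behaviour rather than an error).
#'
#' @param stats data.frame with `mean` and `cv` columns (e.g. from
#'   [gene_stats()]); rows with undefined CV are dropped.
#' @param min_genes minimum number of genes with defined CV (default 50).
#' @param k spline basis dimension (default 10).
#' @return object of class `cv_trend` with a `predict` method mapping
#'   means to fitted `log2(CV + 1)` values; means outside the observed
#'   range are clamped to it.
#' @export
fit_cv_mean_trend <- function(stats, min_genes = 50, k = 10) {
  stopifnot(all(c("mean", "cv") %in% names(stats)))
  ok <- is.finite(stats$mean) & is.finite(stats$cv)
  x <- stats$mean[ok]
  y <- log2(stats$cv[ok] + 1)
  if (length(x) < min_genes) {
    stopf("need >= %d genes with defined CV, got %d", min_genes, length(x))
  }
  rng <- range(x)
  n_unique <- length(unique(x))
  if (n_unique < 4) {
    fit <- NULL
    const <- mean(y)
  } else {
    kk <- min(k, n_unique - 1)
    fit <- mgcv::gam(y ~ s(x, bs = "cs", k = kk),
                     data = data.frame(x = x, y = y), method = "GCV.Cp")
    const <- NULL
  }
  structure(list(fit = fit, const = const, range = rng),
            class = "cv_trend")
}

#' @export
predict.cv_trend <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$mean else newdata
  x <- pmin(pmax(x, object$range[1]), object$range[2])
  if (is.null(object$fit)) {
    return(rep(object$const, length(x)))
  }
  as.numeric(mgcv::predict.gam(object$fit, newdata = data.frame(x = x)))
}

#' @export
print.cv_trend <- function(x, ...) {
  cat(sprintf("cv_trend over mean range [%.4g, %.4g]%s\n",
              x$range[1], x$range[2],
              if (is.null(x$fit)) " (degenerate: constant fit)" else ""))
  invisible(x)
}

#' Mean-adjusted CV
#'
#' Residual of the observed CV around the fitted CV-mean trend,
#' back-transformed to the CV scale: `adjusted = CV - (2^fitted - 1)`,
#' where `fitted` is the trend prediction of `log2(CV + 1)` at the
#' gene's mean. A gene lying exactly on the fitted curve gets adjusted
#' CV 0. A ratio-scale alternative `(CV + 1) / 2^fitted - 1` is
#' available via `backtransform = "ratio"`.
#'
#' @param cv,mean numeric vectors (genes with `NA` CV propagate `NA`).
#' @param model a [fit_cv_mean_trend()] object.
#' @param backtransform `"difference"` (default) or `"ratio"`.
#' @return numeric vector of adjusted CV values.
#' @export
adjusted_cv <- function(cv, mean, model,
                        backtransform = c("difference", "ratio")) {
  backtransform <- match.arg(backtransform)
  stopifnot(inherits(model, "cv_trend"), length(cv) == length(mean))
  fit <- predict(model, mean)
  expected <- 2^fit - 1
  if (backtransform == "difference") cv - expected
  else (cv + 1) / 2^fit - 1
}

#' Assign High/Medium/Low noise labels within mean bins
#'
#' Genes are cut into `n_mean_bins` equal-occupancy bins by mean
#' expression; within each bin the top `tail_frac` by adjusted CV are
#' labeled High, the bottom `tail_frac` Low, and the remainder Medium.
#' `floor`-exact tail sizes; ties broken by stable gene order.
#'
#' @param records data.frame with `gene`, `mean` and `adjusted_cv`
#'   columns (rows with `NA` adjusted CV are dropped with a message).
#' @param n_mean_bins number of mean bins (default 10).
#' @param tail_frac tail fraction (default 0.2).
#' @return the input records (defined rows) with added `mean_bin` and
#'   `label` columns.
#' @export
assign_noise_labels <- function(records, n_mean_bins = 10, tail_frac = 0.2) {
  stopifnot(all(c("gene", "mean", "adjusted_cv") %in% names(records)))
  drop <- !is.finite(records$adjusted_cv)
  if (any(drop)) {
    message(sum(drop), " gene(s) with undefined adjusted CV skipped")
    records <- records[!drop, , drop = FALSE]
  }
  n <- nrow(records)
  records$mean_bin <- occupancy_bins(records$mean, n_mean_bins)
  sizes <- tabulate(records$mean_bin, n_mean_bins)
  if (any(sizes < 5)) {
    stopf("mean bin %d has only %d genes (need >= 5)",
          which(sizes < 5)[1], min(sizes))
  }
  records$label <- "Medium"
  for (b in seq_len(n_mean_bins)) {
    idx <- which(records$mean_bin == b)
    nb <- length(idx)
    n_tail <- floor(tail_frac * nb)
    if (n_tail == 0L) next
    ord <- idx[order(records$adjusted_cv[idx], seq_along(idx))]
    records$label[ord[seq_len(n_tail)]] <- "Low"
    records$label[ord[(nb - n_tail + 1):nb]] <- "High"
  }
  rownames(records) <- NULL
  records
}

#' Full per-group noise table
#'
#' Convenience wrapper chaining [gene_stats()] statistics through
#' [fit_cv_mean_trend()], [adjusted_cv()] and [assign_noise_labels()]
#' within one group of cells (conventionally the untreated 0-h cells of
#' one cell line).
#'
#' @param stats one group's rows from [gene_stats()].
#' @inheritParams adjusted_cv
#' @inheritParams assign_noise_labels
#' @return labeled noise table with `mean`, `cv`, `fitted_log_cv`,
#'   `adjusted_cv`, `mean_bin`, `label`.
#' @export
noise_table <- function(stats, n_mean_bins = 10, tail_frac = 0.2,
                        backtransform = "difference") {
  model <- fit_cv_mean_trend(stats)
  rec <- stats[is.finite(stats$cv), , drop = FALSE]
  rec$fitted_log_cv <- predict(model, rec$mean)
  rec$adjusted_cv <- adjusted_cv(rec$cv, rec$mean, model, backtransform)
  assign_noise_labels(rec, n_mean_bins, tail_frac)
}
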