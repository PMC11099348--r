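# Perturbation time-course analysis: delta-delta-Ct relative
# expression, loess curve fits, time to half-maximal expression, slope
# differentials and targeted-versus-control comparisons.

#' Relative expression by the delta-delta-Ct method
#'
#' `2^-ddCt` with `dCt = Ct_target - Ct_reference` per (condition,
#' replicate, time) sample, and `ddCt` taken relative to the mean `dCt`
#' of the control condition at the 0-h baseline.
#'
#' @param ct_table data.frame with `condition`, `replicate`, `time_h`,
#'   `gene`, `ct`.
#' @param target_gene gene of interest.
#' @param reference_gene housekeeping reference present in every sample
#'   (CTCF in the assay this mirrors).
#' @param control_condition condition supplying the 0-h baseline.
#' @param baseline_time baseline time (default 0).
#' @return data.frame `condition`, `replicate`, `time_h`, `rel_expr`.
#' @export
ddct_relative_expression <- function(ct_table, target_gene, reference_gene,
                                     control_condition,
                                     baseline_time = 0) {
  need <- c("condition", "replicate", "time_h", "gene", "ct")
  stopifnot(all(need %in% names(ct_table)))
  tgt <- ct_table[ct_table$gene == target_gene, ]
  ref <- ct_table[ct_table$gene == reference_gene, ]
  if (nrow(ref) == 0) stopf("no Ct values for reference gene '%s'",
                            reference_gene)
  key <- function(d) paste(d$condition, d$replicate, d$time_h, sep = "\r")
  i <- match(key(tgt), key(ref))
  if (anyNA(i)) stopf("missing reference Ct for %d sample(s)", sum(is.na(i)))
  dct <- tgt$ct - ref$ct[i]
  base <- tgt$condition == control_condition & tgt$time_h == baseline_time
  if (!any(base)) stopf("control condition '%s' has no %g-h baseline",
                        control_condition, baseline_time)
  ddct <- dct - mean(dct[base])
  data.frame(condition = tgt$condition, replicate = tgt$replicate,
             time_h = tgt$time_h, rel_expr = 2^(-ddct),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Loess fit of an expression time course
#'
#' Locally weighted regression (degree 2, tri-cube weights) of
#' expression on time, evaluated on a regular grid. With collinear data
#' and a span covering all points the fit reproduces the line exactly
#' (up to numerical tolerance).
#'
#' @param times,values observed time course (>= 4 distinct times).
#' @param span loess span (default 0.75).
#' @param grid_step evaluation grid step in hours (default 0.1).
#' @param condition label stored on the curve.
#' @return object of class `timing_curve`: `grid`, `fitted`, `max`,
#'   `half_max_time`, `slopes` (first differences / grid step),
#'   `condition`, `span`.
#' @export
loess_fit <- function(times, values, span = 0.75, grid_step = 0.1,
                      condition = NA_character_) {
  if (length(times) != length(values)) stopf("times/values length mismatch")
  if (length(unique(times)) < 4) stopf("need >= 4 distinct time points")
  fit <- stats::loess(values ~ times, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(times), max(times), by = grid_step)
  fitted <- as.numeric(stats::predict(fit, data.frame(times = grid)))
  curve <- structure(list(grid = grid, fitted = fitted,
                          max = max(fitted),
                          condition = condition, span = span),
                     class = "timing_curve")
  curve$half_max_time <- time_to_half_max(curve)
  curve$slopes <- slope_differential(curve)
  curve
}

#' @export
print.timing_curve <- function(x, ...) {
  cat(sprintf("timing_curve%s: grid [%g, %g] h, max %.4g, half-max at %.1f h\n",
              if (is.na(x$condition)) "" else paste0(" (", x$condition, ")"),
              min(x$grid), max(x$grid), x$max, x$half_max_time))
  invisible(x)
}

#' Time to half-maximal expression
#'
#' Earliest grid time at which the fitted curve reaches half of its
#' fitted maximum. A flat zero curve is defined to reach half-max at
#' the first grid point (0 relative to the grid origin); a constant
#' positive curve likewise, since it always exceeds half its maximum.
#' Invariant to positive rescaling of the curve.
#'
#' @param curve a `timing_curve` (or list with `grid` and `fitted`).
#' @return time in hours.
#' @export
time_to_half_max <- function(curve) {
  f <- curve$fitted
  half <- max(f) / 2
  # small relative tolerance so exact-grid crossings are not missed to
  # floating-point rounding
  tol <- 1e-8 * max(abs(f), 1)
  curve$grid[which(f >= half - tol)[1]]
}

#' Slope series of a fitted curve
#'
#' Finite-difference derivative of the fitted values over the grid
#' (length = grid length - 1).
#'
#' @param curve a `timing_curve`.
#' @return numeric vector of slopes (units per hour).
#' @export
slope_differential <- function(curve) {
  step <- diff(curve$grid)
  if (any(step <= 0)) stopf("grid must be strictly increasing")
  diff(curve$fitted) / step
}

#' One-sided comparison of half-max times
#'
#' Two-sample one-sided t-test of targeted versus control half-max
#' times. `direction = "slower"` tests for longer targeted times (the
#' repression expectation), `"faster"` for shorter (activation). With
#' zero variance in both groups and equal means the test is undefined
#' and the symmetric-null value 0.5 is returned.
#'
#' @param targeted,control numeric vectors of half-max times (>= 2
#'   replicates each).
#' @param direction `"slower"` or `"faster"`.
#' @return list with `p_value`, `estimate` (mean difference
#'   targeted - control).
#' @export
compare_half_max <- function(targeted, control,
                             direction = c("slower", "faster")) {
  direction <- match.arg(direction)
  if (length(targeted) < 2 || length(control) < 2) {
    stopf("need >= 2 replicates per group")
  }
  est <- mean(targeted) - mean(control)
  if (stats::sd(targeted) == 0 && stats::sd(control) == 0) {
    if (est == 0) return(list(p_value = 0.5, estimate = 0))
    hit <- (direction == "slower" && est > 0) ||
      (direction == "faster" && est < 0)
    return(list(p_value = if (hit) 0 else 1, estimate = est))
  }
  alt <- if (direction == "slower") "greater" else "less"
  tt <- stats::t.test(targeted, control, alternative = alt)
  list(p_value = tt$p.value, estimate = est)
}

#' Aggregate slope series by group
#'
#' Pointwise mean and 95% confidence interval of the slope series of
#' several fitted curves, per group (targeted versus control). All
#' curves must share one grid.
#'
#' @param targeted,control lists of `timing_curve` objects (>= 1 each).
#' @param conf confidence level (default 0.95).
#' @return data.frame `group`, `time_h` (slope interval midpoints),
#'   `mean_slope`, `ci_lo`, `ci_hi` (NA interval for single curves).
#' @export
aggregate_slopes <- function(targeted, control, conf = 0.95) {
  agg <- function(curves, label) {
    grids <- lapply(curves, `[[`, "grid")
    if (length(unique(vapply(grids, paste, character(1),
                             collapse = ","))) != 1) {
      stopf("curves in group '%s' have mismatched grids", label)
    }
    S <- do.call(rbind, lapply(curves, `[[`, "slopes"))
    g <- grids[[1]]
    mid <- (g[-1] + g[-length(g)]) / 2
    mu <- colMeans(S)
    q <- stats::qnorm(1 - (1 - conf) / 2)
    se <- if (nrow(S) > 1) apply(S, 2, stats::sd) / sqrt(nrow(S)) else
      rep(NA_real_, ncol(S))
    data.frame(group = label, time_h = mid, mean_slope = mu,
               ci_lo = mu - q * se, ci_hi = mu + q * se,
               stringsAsFactors = FALSE)
  }
  if (!identical(targeted[[1]]$grid, control[[1]]$grid)) {
    stopf("targeted and control curves have mismatched grids")
  }
  out <- rbind(agg(targeted, "targeted"), agg(control, "control"))
  rownames(out) <- NULL
  out
}
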