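PARAM_COLS <- c("Dt", "Dp", "f", "S0")

#' Per-voxel estimation errors
#'
#' Signed errors (estimate minus ground truth) and relative errors
#' (error / truth) for each IVIM parameter, row-aligned with the inputs.
#'
#' @param estimates Table with columns Dt, Dp, f, S0 (e.g. from
#'   [predict.ivim_selfsup()] or [fit_volume()]).
#' @param truth Ground-truth [ivim_params()] table of the same length;
#'   a `combo_id` column, if present, is carried through.
#' @return Data frame with columns `err_<p>` and `rel_<p>` per parameter,
#'   plus `combo_id` when available.
#' @export
error_table <- function(estimates, truth) {
  est <- as.data.frame(estimates)
  tr <- as.data.frame(truth)
  if (nrow(est) != nrow(tr))
    stop("estimates and truth are misaligned (different row counts)")
  cols <- list()
  for (p in PARAM_COLS) {
    e <- est[[p]] - tr[[p]]
    cols[[paste0("err_", p)]] <- e
    cols[[paste0("rel_", p)]] <- e / tr[[p]]
  }
  out <- as.data.frame(cols)
  if (!is.null(tr$combo_id)) out$combo_id <- tr$combo_id
  out
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Bias / precision / RMSE per ground-truth combination
#'
#' For each unique ground-truth parameter combination, computes per
#' parameter the bias (mean signed error), the population standard
#' deviation of the error (precision), the RMSE (overall error), and the
#' median and interquartile range of the error. Population definitions are
#' used so that `rmse^2 = bias^2 + std^2` holds exactly on every row.
#'
#' @param errors An [error_table()] with a `combo_id` column (or supply
#'   `truth` to derive one from the unique parameter rows).
#' @param truth Optional truth table used to derive combination ids and to
#'   attach the ground-truth values per combination.
#' @return A `metrics_table` data frame keyed by (`parameter`, `combo_id`)
#'   with columns `bias`, `std`, `rmse`, `median_error`, `iqr`, `n`,
#'   `std_defined` and the ground-truth parameter values.
#' @export
metrics_by_combination <- function(errors, truth = NULL) {
  errors <- as.data.frame(errors)
  if (is.null(errors$combo_id)) {
    if (is.null(truth))
      stop("need combo_id in errors, or a truth table to derive it")
    tr <- as.data.frame(truth)
    errors$combo_id <- as.integer(factor(do.call(paste,
                                                 tr[PARAM_COLS])))
  }
  truth_by_combo <- NULL
  if (!is.null(truth)) {
    tr <- as.data.frame(truth)
    tr$combo_id <- errors$combo_id
    truth_by_combo <- tr[!duplicated(tr$combo_id),
                         c("combo_id", PARAM_COLS)]
    names(truth_by_combo)[-1] <- paste0("true_", PARAM_COLS)
  }
  out <- do.call(rbind, lapply(PARAM_COLS, function(p) {
    e <- errors[[paste0("err_", p)]]
    agg <- do.call(rbind, lapply(split(e, errors$combo_id), function(x) {
      data.frame(bias = mean(x), std = pop_sd(x),
                 rmse = sqrt(mean(x^2)), median_error = median(x),
                 iqr = IQR(x, type = 7), n = length(x),
                 std_defined = length(x) >= 2L)
    }))
    agg$combo_id <- as.integer(rownames(agg))
    agg$parameter <- p
    agg
  }))
  if (any(!out$std_defined))
    warning("some combinations have fewer than 2 instantiations; ",
            "std is undefined there")
  if (!is.null(truth_by_combo)) out <- merge(out, truth_by_combo,
                                             by = "combo_id")
  rownames(out) <- NULL
  class(out) <- c("metrics_table", class(out))
  out[, c("parameter", "combo_id", "bias", "std", "rmse", "median_error",
          "iqr", "n", "std_defined",
          intersect(paste0("true_", PARAM_COLS), names(out)))]
}

#' Marginal metric summaries along one parameter's grid levels
#'
#' The visualisation reduction used for performance-versus-ground-truth
#' plots: for each distinct ground-truth level of `parameter`, the mean and
#' standard deviation of each combination-level metric across all
#' combinations of the remaining parameters.
#'
#' @param metrics A `metrics_table` from [metrics_by_combination()]
#'   (must carry the `true_*` columns).
#' @param parameter Which parameter's levels to summarise over
#'   (`"Dt"`, `"Dp"`, `"f"` or `"S0"`).
#' @return Data frame keyed by level value with `mean_bias`, `sd_bias`,
#'   `mean_std`, `sd_std`, `mean_rmse`, `sd_rmse` and `n_combinations`.
#' @export
metrics_by_level <- function(metrics, parameter = "Dt") {
  stopifnot(parameter %in% PARAM_COLS)
  lvl_col <- paste0("true_", parameter)
  if (is.null(metrics[[lvl_col]]))
    stop("metrics table lacks ground-truth columns; pass truth to ",
         "metrics_by_combination()")
  m <- metrics[metrics$parameter == parameter, ]
  out <- do.call(rbind, lapply(split(m, m[[lvl_col]]), function(g) {
    data.frame(level = g[[lvl_col]][1],
               mean_bias = mean(g$bias), sd_bias = sd(g$bias),
               mean_std = mean(g$std), sd_std = sd(g$std),
               mean_rmse = mean(g$rmse), sd_rmse = sd(g$rmse),
               n_combinations = nrow(g))
  }))
  rownames(out) <- NULL
  out[order(out$level), ]
}

#' Mean relative bias (percent) per ground-truth level
#'
#' Percent bias of one parameter as a function of its own ground-truth grid
#' level: the mean of (estimate - truth)/truth across all voxels at that
#' level, times 100. This is the quantity plotted in
#' performance-versus-ground-truth analyses of accuracy.
#'
#' @param estimates,truth Row-aligned parameter tables.
#' @param parameter Parameter name (default `"Dt"`).
#' @return Data frame with `level` (ascending) and `bias_pct`.
#' @export
relative_bias_by_level <- function(estimates, truth, parameter = "Dt") {
  stopifnot(parameter %in% PARAM_COLS)
  est <- as.data.frame(estimates)
  tr <- as.data.frame(truth)
  if (nrow(est) != nrow(tr)) stop("estimates and truth are misaligned")
  rel <- (est[[parameter]] - tr[[parameter]]) / tr[[parameter]]
  agg <- tapply(rel, tr[[parameter]], mean)
  out <- data.frame(level = as.numeric(names(agg)),
                    bias_pct = 100 * as.numeric(agg))
  out[order(out$level), ]
}

#' Five-number boxplot summaries of errors by group
#'
#' Median, quartiles (linear-interpolation, type-7 quantiles) and whiskers
#' per parameter per group (typically SNR). By default whiskers extend to
#' the most extreme data point within 1.5 interquartile ranges of the
#' *median*; `whiskers = "tukey"` uses the conventional quartile-anchored
#' fences instead.
#'
#' @param errors An [error_table()].
#' @param group Vector of group labels (e.g. SNR values), one per row of
#'   `errors`.
#' @param whiskers `"median"` (default) or `"tukey"`.
#' @return Data frame keyed by (`parameter`, `group`) with `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, `n`.
#' @export
boxplot_summary <- function(errors, group, whiskers = c("median", "tukey")) {
  whiskers <- match.arg(whiskers)
  errors <- as.data.frame(errors)
  if (length(group) != nrow(errors))
    stop("group must have one label per error row")
  out <- do.call(rbind, lapply(PARAM_COLS, function(p) {
    e <- errors[[paste0("err_", p)]]
    s <- do.call(rbind, lapply(split(e, group), function(x) {
      if (length(x) == 0L) stop("empty group")
      q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      anchor_lo <- if (whiskers == "median") q[2] else q[1]
      anchor_hi <- if (whiskers == "median") q[2] else q[3]
      inside <- x[x >= anchor_lo - 1.5 * iqr & x <= anchor_hi + 1.5 * iqr]
      data.frame(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(inside), whisker_high = max(inside),
                 n = length(x))
    }))
    s$group <- rownames(s)
    s$parameter <- p
    s
  }))
  rownames(out) <- NULL
  out[, c("parameter", "group", "median", "q1", "q3", "whisker_low",
          "whisker_high", "n")]
}
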