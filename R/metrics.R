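#' Coefficient of variation (percent)
#'
#' Reproducibility of repeated estimates: 100 x sample SD / sample mean.
#'
#' @param estimates Numeric vector of non-outlier estimates (>= 2 values,
#'   nonzero mean).
#' @return CV in percent.
#' @examples
#' cv_percent(c(9, 10, 11))  # 10
#' @export
cv_percent <- function(estimates) {
  check_metric_input(estimates)
  100 * stats::sd(estimates) / mean(estimates)
}

#' Mean error (percent) of an estimator
#'
#' Accuracy of the ensemble mean: 100 x |mean(estimates) - truth| / truth.
#' Symmetric over- and under-estimation cancels; this measures the error of
#' the mean, not the mean absolute error.
#'
#' @param estimates Numeric vector of non-outlier estimates.
#' @param truth Ground-truth parameter value (nonzero).
#' @return Mean error in percent.
#' @export
mean_error_percent <- function(estimates, truth) {
  check_metric_input(estimates)
  if (!is.numeric(truth) || length(truth) != 1L || truth == 0)
    stop("undefined metric: truth must be a nonzero scalar", call. = FALSE)
  100 * abs(mean(estimates) - truth) / truth
}

#' Bland-Altman bias and limits of agreement against ground truth
#'
#' Per-replicate relative differences d_i = 100 (estimate_i - truth) / truth;
#' bias is their mean and the 95% limits of agreement are
#' bias +/- 1.96 SD(d). Positive bias means overestimation.
#'
#' @param estimates Numeric vector of non-outlier estimates (>= 2 values).
#' @param truth Ground-truth value (nonzero).
#' @return A list with `bias_percent`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(estimates, truth) {
  if (!is.numeric(estimates) || length(estimates) < 2L || anyNA(estimates))
    stop("undefined metric: need >= 2 non-missing estimates", call. = FALSE)
  if (!is.numeric(truth) || length(truth) != 1L || truth == 0)
    stop("undefined metric: truth must be a nonzero scalar", call. = FALSE)
  d <- 100 * (estimates - truth) / truth
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias_percent = bias, loa_low = bias - 1.96 * s,
       loa_high = bias + 1.96 * s)
}

#' Outlier percentage of a batch of fits
#'
#' @param outlier Logical vector of outlier flags (one per fit).
#' @return 100 x fraction flagged.
#' @export
outlier_percent <- function(outlier) {
  if (length(outlier) < 1L)
    stop("undefined metric: need at least one fit", call. = FALSE)
  100 * mean(as.logical(outlier))
}

check_metric_input <- function(estimates) {
  if (!is.numeric(estimates) || length(estimates) < 2L || anyNA(estimates))
    stop("undefined metric: need >= 2 non-missing estimates", call. = FALSE)
  if (mean(estimates) == 0)
    stop("undefined metric: mean of estimates is zero", call. = FALSE)
  invisible(TRUE)
}

#' Cross-method comparison: one-way ANOVA with Tukey HSD
#'
#' Tests whether the three cascades produce different estimates of one
#' parameter at one SNR level, then identifies which pairs differ. Built on
#' `stats::aov()` and `stats::TukeyHSD()` at the conventional 0.05 level.
#'
#' @param groups Named list of numeric vectors, one per fitting method (>= 2
#'   groups with >= 2 values each).
#' @param alpha Significance level for the `significant` flags.
#' @return A list with `f_statistic`, `p_value` and `tukey`, a data frame of
#'   pairwise comparisons (`pair`, `diff`, `p_adj`, `significant`).
#' @examples
#' compare_methods(list(m1 = rnorm(10), m2 = rnorm(10), m3 = rnorm(10, 1)))
#' @export
compare_methods <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("undefined metric: need >= 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("method", seq_along(groups))
  if (any(vapply(groups, length, 0L) < 2L))
    stop("undefined metric: every group needs >= 2 values", call. = FALSE)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    method = factor(rep(names(groups), vapply(groups, length, 0L))))
  if (all(vapply(groups, stats::sd, 0) == 0))
    stop("undefined metric: zero within-group variance in every group",
         call. = FALSE)
  fit <- stats::aov(value ~ method, data = df)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$method
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(f_statistic = tab["method", "F value"],
       p_value = tab["method", "Pr(>F)"],
       tukey = tukey)
}

#' Summarize a batch of fits into the study's metric tables
#'
#' Computes, per (model, snr, method, parameter): the non-outlier count, mean
#' and SD of the estimates, reproducibility CV%, mean error %, Bland-Altman
#' bias and limits of agreement against ground truth, and the outlier
#' percentage of the (model, snr, method) cell. Outlier fits are excluded
#' from every summary statistic and only counted.
#'
#' @param fits Batch data frame from [fit_ensemble()].
#' @param truth Named list mapping each model id in `fits` to its
#'   ground-truth [ivim_params()].
#' @param include_outliers If `TRUE`, outlier fits enter the statistics too
#'   (for sensitivity checks); `n_used` then counts all finite estimates.
#' @return A data frame with one row per (model, snr, method, parameter).
#' @export
metrics_table <- function(fits, truth, include_outliers = FALSE) {
  stopifnot(is.list(truth))
  pars <- c("D", "D_star", "f")
  cells <- unique(fits[c("model", "snr", "method")])
  cells <- cells[order(cells$model, cells$snr, cells$method), , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(cells))) {
    mod <- cells$model[k]; snr <- cells$snr[k]; met <- cells$method[k]
    sub <- fits[fits$model == mod & fits$snr == snr & fits$method == met, ,
                drop = FALSE]
    tp <- truth[[mod]]
    if (is.null(tp))
      stop("no ground truth supplied for model '", mod, "'", call. = FALSE)
    tp <- as.numeric.ivim_params(tp)
    out_pct <- outlier_percent(sub$outlier)
    keep <- if (include_outliers) rep(TRUE, nrow(sub)) else !sub$outlier
    for (p in pars) {
      x <- sub[[p]][keep]
      x <- x[is.finite(x)]
      enough <- length(x) >= 2L && mean(x) != 0
      ba <- if (enough) bland_altman(x, tp[[p]]) else
        list(bias_percent = NA_real_, loa_low = NA_real_, loa_high = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        model = mod, snr = snr, method = met, parameter = p,
        n_used = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
        cv_percent = if (enough) cv_percent(x) else NA_real_,
        mean_error_percent = if (enough) mean_error_percent(x, tp[[p]])
                             else NA_real_,
        bias_percent = ba$bias_percent,
        loa_low_percent = ba$loa_low, loa_high_percent = ba$loa_high,
        outlier_percent = out_pct)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Cross-method ANOVA/Tukey over a batch of fits
#'
#' Applies [compare_methods()] to the non-outlier estimates of every
#' (model, snr, parameter) cell that has at least two methods with two or
#' more usable values.
#'
#' @inheritParams metrics_table
#' @param alpha Significance level.
#' @return A data frame with one row per (model, snr, parameter, pair), plus
#'   the cell-level ANOVA F and p.
#' @export
comparison_table <- function(fits, alpha = 0.05) {
  pars <- c("D", "D_star", "f")
  cells <- unique(fits[c("model", "snr")])
  rows <- list()
  for (k in seq_len(nrow(cells))) {
    mod <- cells$model[k]; snr <- cells$snr[k]
    sub <- fits[fits$model == mod & fits$snr == snr & !fits$outlier, ,
                drop = FALSE]
    for (p in pars) {
      groups <- split(sub[[p]], sub$method)
      groups <- lapply(groups, function(x) x[is.finite(x)])
      groups <- groups[vapply(groups, length, 0L) >= 2L]
      if (length(groups) < 2L) next
      cmp <- tryCatch(compare_methods(groups, alpha = alpha),
                      error = function(e) NULL)
      if (is.null(cmp)) next
      rows[[length(rows) + 1L]] <- data.frame(
        model = mod, snr = snr, parameter = p,
        f_statistic = cmp$f_statistic, p_value = cmp$p_value,
        pair = cmp$tukey$pair, diff = cmp$tukey$diff,
        p_adj = cmp$tukey$p_adj, significant = cmp$tukey$significant)
    }
  }
  if (!length(rows)) return(NULL)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
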