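#' Fit every curve of a Monte-Carlo ensemble
#'
#' Runs one or more fitting cascades over each (model, snr, iteration) curve
#' of a long ensemble data frame (as produced by [generate_ensemble()]) and
#' returns one row per fit, matching the columnar batch interface used by the
#' analysis drivers and [run_study()].
#'
#' @param ensemble Long data frame with columns `model`, `snr`, `iteration`,
#'   `b`, `signal`.
#' @param methods Character vector of cascade ids (any subset of
#'   `"one_parameter"`, `"two_parameter"`, `"three_parameter"`).
#' @param b_threshold,cond_threshold Passed to [method_spec()].
#' @param progress Emit a message per (model, snr) block.
#' @return A data frame with columns `model`, `snr`, `iteration`, `method`,
#'   `D`, `D_star`, `f`, `stderr_D`, `stderr_D_star`, `stderr_f`, `rss`,
#'   `converged`, `outlier`.
#' @export
fit_ensemble <- function(ensemble,
                         methods = c("one_parameter", "two_parameter",
                                     "three_parameter"),
                         b_threshold = 200, cond_threshold = 1e8,
                         progress = FALSE) {
  need <- c("model", "snr", "iteration", "b", "signal")
  if (!all(need %in% names(ensemble)))
    stop("ensemble must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  specs <- lapply(methods, function(m)
    method_spec(m, b_threshold = b_threshold,
                cond_threshold = cond_threshold))
  blocks <- unique(ensemble[c("model", "snr")])
  out <- list()
  for (k in seq_len(nrow(blocks))) {
    mod <- blocks$model[k]; snr <- blocks$snr[k]
    sub <- ensemble[ensemble$model == mod & ensemble$snr == snr, ,
                    drop = FALSE]
    sub <- sub[order(sub$iteration, sub$b), , drop = FALSE]
    b <- unique(sub$b)
    scheme <- acquisition_scheme(b)
    sig <- matrix(sub$signal, nrow = length(b))
    iters <- unique(sub$iteration)
    if (progress)
      message("fitting model=", mod, " snr=", snr, " (", length(iters),
              " iterations)")
    rows <- vector("list", length(iters) * length(specs))
    r <- 0L
    for (j in seq_along(iters)) {
      curve <- signal_curve(scheme, sig[, j])
      for (spec in specs) {
        fit <- fit_ivim(curve, spec)
        r <- r + 1L
        rows[[r]] <- data.frame(
          model = mod, snr = snr, iteration = iters[j],
          method = spec$method_id,
          D = fit$estimate[["D"]], D_star = fit$estimate[["D_star"]],
          f = fit$estimate[["f"]],
          stderr_D = fit$stderr[["D"]],
          stderr_D_star = fit$stderr[["D_star"]],
          stderr_f = fit$stderr[["f"]],
          rss = fit$rss, converged = fit$converged, outlier = fit$outlier)
      }
    }
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
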