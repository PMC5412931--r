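#' F-test probability for fixed-parameter alternate models
#'
#' Converts the residual-sum-of-squares inflation caused by fixing `n_fixed`
#' parameters away from the best fit into a confidence probability via
#' \deqn{F = \frac{\chi^2_{fix} - \chi^2_0}{\chi^2_0} \cdot
#'           \frac{N - P}{P_{fix}}}
#' referred to the F(`n_fixed`, `n_obs - n_free`) distribution. This is the
#' standard comparison of a null model (best fit, `n_free` free parameters
#' over `n_obs` observations) with an alternate model in which some
#' parameters are clamped; the returned probability is the confidence level
#' at which the clamped values are excluded.
#'
#' @param rss_fix Residual sum of squares with the parameters clamped.
#' @param rss_best Residual sum of squares of the best fit (> 0).
#' @param n_obs Number of observations.
#' @param n_free Number of free parameters in the null fit.
#' @param n_fixed Number of clamped parameters.
#' @return Probability in `[0, 1]`.
#' @export
f_test_probability <- function(rss_fix, rss_best, n_obs, n_free,
                               n_fixed = 1L) {
  if (rss_best <= 0)
    stop("degenerate surface: best-fit residual is zero; add noise or ",
         "jitter the data before profiling", call. = FALSE)
  if (n_obs <= n_free)
    stop("degenerate surface: no residual degrees of freedom", call. = FALSE)
  fstat <- pmax((rss_fix - rss_best) / rss_best, 0) * (n_obs - n_free) / n_fixed
  stats::pf(fstat, n_fixed, n_obs - n_free)
}

#' 2D confidence-region grid for a parameter pair
#'
#' Maps the identifiability of two IVIM parameters around a converged fit.
#' At each node of a rectangular grid the paired parameters are clamped to
#' the node values; any parameter the null fit estimated freely and that is
#' not in the pair is re-optimized; parameters the cascade had already fixed
#' stay at their cascade values. The residual inflation is converted to a
#' confidence probability with [f_test_probability()] (2 clamped parameters,
#' `N` = number of b-values, `P` = number of solver-free parameters in the
#' null fit). Closed contours of the resulting surface are the joint
#' confidence regions; elongated or multi-lobed surfaces signal poorly
#' identified parameters.
#'
#' @param curve The fitted [signal_curve()].
#' @param best_fit A converged `ivim_fit` for `curve`.
#' @param pair Character vector of two parameter names from
#'   `c("D", "D_star", "f")`.
#' @param spec The [method_spec()] used for `best_fit` (supplies bounds and
#'   the cascade's fixed values are taken from `best_fit`).
#' @param n_grid Nodes per axis (default 41).
#' @param span_stderr Half-width of each axis in standard errors of the
#'   best-fit estimate (default 5); when the standard error is unavailable
#'   the axis spans +/- `span_frac` of the estimate.
#' @param span_frac Fallback fractional half-width (default 0.5).
#' @return An object of class `confidence_grid`: `pair`, `axis1`, `axis2`
#'   (grid values), `probability` (matrix, axis1 by rows), `best_fit`
#'   estimates and `rss_best`.
#' @export
confidence_grid <- function(curve, best_fit, pair, spec = method_spec(),
                            n_grid = 41, span_stderr = 5, span_frac = 0.5) {
  stopifnot(inherits(curve, "signal_curve"), inherits(best_fit, "ivim_fit"))
  pars <- c("D", "D_star", "f")
  if (length(pair) != 2L || !all(pair %in% pars) || pair[1] == pair[2])
    stop("pair must name two distinct parameters among D, D_star, f",
         call. = FALSE)
  if (!best_fit$converged)
    stop("best_fit must be a converged fit", call. = FALSE)
  if (best_fit$rss <= 0)
    stop("degenerate surface: best-fit residual is zero; add noise or ",
         "jitter the data before profiling", call. = FALSE)
  est <- best_fit$estimate
  free_null <- pars[!best_fit$fixed]           # solver-free in the null fit
  refit <- setdiff(free_null, pair)            # re-optimized at each node
  n_obs <- length(curve$values)
  p_null <- length(free_null)

  axis_for <- function(p) {
    se <- best_fit$stderr[[p]]
    half <- if (is.finite(se) && se > 0) span_stderr * se
            else span_frac * abs(est[[p]])
    lo <- max(est[[p]] - half, spec$lower[[p]])
    hi <- min(est[[p]] + half, spec$upper[[p]])
    if (p %in% c("D", "D_star")) lo <- max(lo, 1e-8)
    seq(lo, hi, length.out = n_grid)
  }
  ax1 <- axis_for(pair[1])
  ax2 <- axis_for(pair[2])

  b <- curve$scheme$b_values
  y <- curve$values
  prob <- matrix(NA_real_, n_grid, n_grid)
  base <- est
  for (i in seq_len(n_grid)) {
    for (j in seq_len(n_grid)) {
      p_node <- base
      p_node[pair[1]] <- ax1[i]
      p_node[pair[2]] <- ax2[j]
      if (length(refit)) {
        resid_fn <- function(q) {
          p_node[refit] <- q
          ivim_model_values(b, p_node[["D"]], p_node[["D_star"]],
                            p_node[["f"]]) - y
        }
        jac_fn <- function(q) {
          p_node[refit] <- q
          ivim_jacobian(b, p_node[["D"]], p_node[["D_star"]], p_node[["f"]],
                        refit)
        }
        sub <- minpack.lm::nls.lm(
          par = est[refit], lower = spec$lower[refit],
          upper = spec$upper[refit], fn = resid_fn, jac = jac_fn,
          control = minpack.lm::nls.lm.control(ptol = 1e-8, ftol = 1e-8,
                                               maxiter = 100))
        rss_fix <- sub$deviance
      } else {
        r <- ivim_model_values(b, p_node[["D"]], p_node[["D_star"]],
                               p_node[["f"]]) - y
        rss_fix <- sum(r^2)
      }
      prob[i, j] <- f_test_probability(rss_fix, best_fit$rss, n_obs, p_null,
                                       n_fixed = 2L)
    }
  }
  structure(list(pair = pair, axis1 = ax1, axis2 = ax2, probability = prob,
                 best_fit = est, rss_best = best_fit$rss,
                 n_obs = n_obs, n_free = p_null),
            class = "confidence_grid")
}

#' Multi-start census of local least-squares minima
#'
#' Launches the configured fitting cascade from a grid of starting points
#' log-spaced across the interior of the bounds box and counts the distinct
#' solutions it converges to. Only converged, interior (not at a bound),
#' well-conditioned solutions qualify as local minima; bound-truncated runs
#' are not stationary points of the objective and are discarded. Converged
#' solutions are merged when every free parameter agrees within the relative
#' `merge_tol`; survivors are returned sorted by cost.
#'
#' @param curve A [signal_curve()].
#' @param spec A [method_spec()] (the three-parameter cascade by default, as
#'   the simultaneous fit is where multiple minima arise).
#' @param n_per_param Starting values per free parameter (default 3, giving
#'   27 starts for the three-parameter cascade).
#' @param merge_tol Relative tolerance under which two solutions are the
#'   same minimum (default 1e-3).
#' @param cost_tol,valley_tol Flat-valley de-jitter: two solutions whose
#'   costs agree within `cost_tol` (relative, default 1e-6) and whose
#'   parameters agree within `valley_tol` (relative, default 0.1) are
#'   stopping-point jitter of one shallow minimum, not distinct minima.
#' @param truth Optional [ivim_params()]; when given, each solution's
#'   distance to truth is reported and `global_is_correct` states whether the
#'   lowest-cost solution is the one nearest the truth.
#' @return An object of class `minima_census`: `solutions` (data frame of
#'   distinct minima with parameters and `rss`), `n_minima`, `n_starts`,
#'   `n_converged`, and optionally `global_is_correct`.
#' @export
minima_census <- function(curve, spec = method_spec("three_parameter"),
                          n_per_param = 3, merge_tol = 1e-3,
                          cost_tol = 1e-6, valley_tol = 0.1, truth = NULL) {
  stopifnot(inherits(curve, "signal_curve"), inherits(spec, "method_spec"))
  free <- switch(spec$method_id,
                 one_parameter = "D_star",
                 two_parameter = c("D_star", "f"),
                 three_parameter = c("D", "D_star", "f"))
  # interior log-spaced start grid per free parameter
  pts <- lapply(free, function(p) {
    lo <- max(spec$lower[[p]], spec$upper[[p]] / 1000)
    g <- exp(seq(log(lo), log(spec$upper[[p]]), length.out = n_per_param + 2))
    g[2:(n_per_param + 1)]
  })
  names(pts) <- free
  starts <- expand.grid(pts, KEEP.OUT.ATTRS = FALSE)
  if (nrow(starts) < 1L) stop("no starts generated", call. = FALSE)

  sols <- list()
  n_conv <- 0L
  for (k in seq_len(nrow(starts))) {
    sk <- spec
    sk$init[free] <- as.numeric(starts[k, free])
    fit <- fit_ivim(curve, sk)
    if (!fit$converged) next
    n_conv <- n_conv + 1L
    if (fit$at_bound || !is.finite(fit$cond) ||
        fit$cond > spec$cond_threshold) next
    par <- fit$estimate[free]
    # The bi-exponential model is invariant under swapping the compartments,
    # (D, D*, f) -> (D*, D, 1 - f): both points trace the identical signal
    # and cost. When D and D* are both free, canonicalize to D <= D* so the
    # mirrored twin is counted as the single minimum it is.
    if (all(c("D", "D_star") %in% free) && par[["D"]] > par[["D_star"]]) {
      par[c("D", "D_star")] <- par[c("D_star", "D")]
      if ("f" %in% free) par[["f"]] <- 1 - par[["f"]]
    }
    sols[[length(sols) + 1L]] <- list(par = par, rss = fit$rss)
  }
  if (n_conv == 0L)
    stop("empty census: no start converged", call. = FALSE)

  # Merge solutions agreeing within relative tolerance on every free
  # parameter; additionally treat two stops as one minimum when their costs
  # are numerically identical and the parameters sit in the same shallow
  # valley (Levenberg-Marquardt stopping jitter, not distinct basins).
  distinct <- list()
  for (s in sols) {
    dup <- FALSE
    for (d in distinct) {
      rel <- abs(s$par - d$par) / pmax(abs(s$par), abs(d$par), 1e-12)
      rel_cost <- abs(s$rss - d$rss) / pmax(s$rss, d$rss, 1e-300)
      if (all(rel <= merge_tol) ||
          (rel_cost <= cost_tol && all(rel <= valley_tol))) {
        dup <- TRUE
        break
      }
    }
    if (!dup) distinct[[length(distinct) + 1L]] <- s
  }
  if (length(distinct)) {
    tab <- do.call(rbind, lapply(distinct, function(d)
      data.frame(t(d$par), rss = d$rss)))
    tab <- tab[order(tab$rss), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- NULL
  }

  global_correct <- NA
  if (!is.null(truth) && !is.null(tab) && nrow(tab) >= 1L) {
    tv <- as.numeric.ivim_params(truth)[free]
    dist <- apply(tab[free], 1, function(p)
      sqrt(sum(((p - tv) / tv)^2)))
    tab$rel_dist_to_truth <- dist
    global_correct <- which.min(dist) == 1L  # rows already sorted by cost
  }
  structure(list(solutions = tab,
                 n_minima = if (is.null(tab)) 0L else nrow(tab),
                 n_starts = nrow(starts), n_converged = n_conv,
                 merge_tol = merge_tol,
                 global_is_correct = global_correct),
            class = "minima_census")
}

#' @export
print.minima_census <- function(x, ...) {
  cat("Multi-start census:", x$n_minima, "distinct minima from", x$n_starts,
      "starts (", x$n_converged, "converged )\n")
  if (!is.null(x$solutions)) print(x$solutions)
  invisible(x)
}

#' Fraction of ensemble curves with multiple local minima
#'
#' Runs [minima_census()] over every iteration of one (model, snr) ensemble
#' arm and reports the percentage of curves whose cost surface shows more
#' than one distinct interior minimum.
#'
#' @param ensemble Long ensemble data frame restricted to (or filtered for)
#'   one model and SNR by the `snr`/`model` arguments.
#' @param snr,model Arm selectors.
#' @param spec,n_per_param,merge_tol Passed to [minima_census()].
#' @param truth Optional ground truth forwarded to the census.
#' @return A list: `percent_multiple`, `n_curves`, `n_multiple`,
#'   `global_correct_in_multiple` (fraction of multi-minimum curves whose
#'   lowest-cost solution is nearest truth; `NA` without truth), and the
#'   per-curve census counts.
#' @export
multiple_minima_fraction <- function(ensemble, snr, model = NULL,
                                     spec = method_spec("three_parameter"),
                                     n_per_param = 3, merge_tol = 1e-3,
                                     truth = NULL) {
  rows <- ensemble$snr == snr
  if (!is.null(model)) rows <- rows & ensemble$model == model
  sub <- ensemble[rows, , drop = FALSE]
  if (!nrow(sub)) stop("no ensemble rows for the requested arm", call. = FALSE)
  iters <- unique(sub$iteration)
  counts <- integer(length(iters))
  correct <- logical(0)
  for (j in seq_along(iters)) {
    curve <- ensemble_curve(sub, snr = snr, iteration = iters[j])
    cen <- tryCatch(
      minima_census(curve, spec, n_per_param, merge_tol, truth = truth),
      error = function(e) NULL)
    counts[j] <- if (is.null(cen)) 0L else cen$n_minima
    if (!is.null(cen) && cen$n_minima > 1L && !is.null(truth))
      correct <- c(correct, isTRUE(cen$global_is_correct))
  }
  n_multi <- sum(counts > 1L)
  list(percent_multiple = 100 * n_multi / length(iters),
       n_curves = length(iters), n_multiple = n_multi,
       global_correct_in_multiple =
         if (length(correct)) mean(correct) else NA_real_,
       minima_counts = counts)
}
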