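#' Fitting-method specification
#'
#' Configures one of the three bi-exponential fitting cascades:
#'
#' * `one_parameter` (fully constrained): D from the high-b mono-exponential
#'   segment, f from its extrapolated intercept, only D* estimated by
#'   nonlinear least squares on the full curve.
#' * `two_parameter` (constrained): D from the segment fit; (f, D*) estimated
#'   jointly on the full curve.
#' * `three_parameter` (simultaneous): (D, D*, f) estimated jointly.
#'
#' The high-b segment comprises b-values strictly above `b_threshold`, where
#' perfusion effects are taken as negligible. Nonlinear steps use damped
#' (Levenberg-Marquardt) least squares with an analytic Jacobian, bound
#' constraints and tight (1e-8) relative tolerances.
#'
#' @param method One of `"one_parameter"`, `"two_parameter"`,
#'   `"three_parameter"`.
#' @param b_threshold Perfusion threshold in s/mm^2 (default 200); points with
#'   b strictly greater enter the segment fit.
#' @param init Named numeric vector of initial values for `D`, `D_star`, `f`.
#' @param lower,upper Named numeric bound vectors for the same parameters.
#' @param cond_threshold Jacobian condition-number threshold above which a
#'   solution is flagged ill-conditioned (default 1e8).
#' @return An object of class `method_spec`.
#' @export
method_spec <- function(method = c("one_parameter", "two_parameter",
                                   "three_parameter"),
                        b_threshold = 200,
                        init = c(D = 1e-3, D_star = 1e-2, f = 0.1),
                        lower = c(D = 1e-5, D_star = 1e-4, f = 0),
                        upper = c(D = 5e-3, D_star = 5e-1, f = 1),
                        cond_threshold = 1e8) {
  method <- match.arg(method)
  nms <- c("D", "D_star", "f")
  for (v in list(init = init, lower = lower, upper = upper)) {
    if (!all(nms %in% names(v)))
      stop("invalid method spec: init/lower/upper must name D, D_star and f",
           call. = FALSE)
  }
  if (any(lower[nms] > init[nms]) || any(init[nms] > upper[nms]))
    stop("invalid method spec: need lower <= init <= upper per parameter",
         call. = FALSE)
  structure(list(method_id = method, b_threshold = b_threshold,
                 init = init[nms], lower = lower[nms], upper = upper[nms],
                 cond_threshold = cond_threshold),
            class = "method_spec")
}

#' High-b mono-exponential segment fit
#'
#' Ordinary least squares on log(signal) versus b over the points with
#' b strictly above the perfusion threshold. The negated slope estimates the
#' tissue diffusion coefficient D and the exponentiated intercept the
#' extrapolated signal S(int) whose gap below S(0) = 1 carries the perfusion
#' fraction. Non-positive signal values cannot enter the log transform and
#' are dropped (and counted); at least two usable points are required.
#'
#' @param curve A [signal_curve()].
#' @param b_threshold Perfusion threshold, s/mm^2 (default 200).
#' @return A list with `D`, `S_int`, `n_used`, `n_dropped` and the residual
#'   sum of squares of the log-linear fit (`rss_log`).
#' @export
fit_high_b_segment <- function(curve, b_threshold = 200) {
  stopifnot(inherits(curve, "signal_curve"))
  b <- curve$scheme$b_values
  s <- curve$values
  high <- b > b_threshold
  if (sum(high) < 2L)
    stop("segment fit infeasible: scheme has fewer than 2 b-values above ",
         b_threshold, " s/mm^2", call. = FALSE)
  usable <- high & s > 0
  n_dropped <- sum(high) - sum(usable)
  if (sum(usable) < 2L)
    stop("segment fit infeasible: fewer than 2 positive signal values above ",
         "the b threshold", call. = FALSE)
  fit <- stats::lm(log(s[usable]) ~ b[usable])
  co <- stats::coef(fit)
  list(D = unname(-co[2]), S_int = unname(exp(co[1])),
       n_used = sum(usable), n_dropped = n_dropped,
       rss_log = sum(stats::resid(fit)^2))
}

# Analytic Jacobian of the bi-exponential model wrt the free parameters.
# Column order follows `free`.
ivim_jacobian <- function(b, D, D_star, f, free) {
  cols <- list(
    D      = -(1 - f) * b * exp(-b * D),
    D_star = -f * b * exp(-b * D_star),
    f      = exp(-b * D_star) - exp(-b * D))
  do.call(cbind, cols[free])
}

# Condition number (ratio of extreme singular values) of the Jacobian;
# Inf when rank-deficient.
jacobian_condition <- function(jac) {
  if (any(!is.finite(jac))) return(Inf)
  d <- svd(jac, nu = 0, nv = 0)$d
  if (length(d) == 0L || min(d) == 0) return(Inf)
  max(d) / min(d)
}

#' Outlier rule for a completed fit
#'
#' A fit is an outlier when the solver did not converge, when the Jacobian at
#' the solution is rank-deficient or has condition number above the
#' configured threshold (ill-conditioned), or when any free estimate sits on
#' a bound (the solution is then not an interior stationary point and the
#' estimate is solver-truncated rather than data-driven).
#'
#' @param jac Jacobian matrix at the solution (free parameters as columns).
#' @param converged Logical solver convergence flag.
#' @param at_bound Logical; any free estimate at a bound.
#' @param cond_threshold Condition-number threshold (default 1e8).
#' @return Logical outlier flag.
#' @export
detect_outlier <- function(jac, converged, at_bound, cond_threshold = 1e8) {
  !converged || at_bound || jacobian_condition(jac) > cond_threshold
}

at_bound_flags <- function(par, lower, upper) {
  tol <- pmax(1e-12, 1e-8 * (upper - lower))
  par <= lower + tol | par >= upper - tol
}

# Shared Levenberg-Marquardt driver over the free parameters, with the fixed
# ones held at `fixed`. Returns the pieces the cascades assemble into a
# fit_result.
lm_fit_free <- function(curve, spec, free, fixed) {
  b <- curve$scheme$b_values
  y <- curve$values
  full <- function(p_free) {
    names(p_free) <- free  # nls.lm can drop names on its way through
    c(fixed, p_free)[c("D", "D_star", "f")]
  }
  resid_fn <- function(p_free) {
    p <- full(p_free)
    ivim_model_values(b, p["D"], p["D_star"], p["f"]) - y
  }
  jac_fn <- function(p_free) {
    p <- full(p_free)
    ivim_jacobian(b, p["D"], p["D_star"], p["f"], free)
  }
  fit <- minpack.lm::nls.lm(
    par = spec$init[free], lower = spec$lower[free], upper = spec$upper[free],
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(ptol = 1e-8, ftol = 1e-8,
                                         maxiter = 200))
  par <- unlist(fit$par)
  names(par) <- free
  jac <- jac_fn(par)
  converged <- fit$info %in% 1:3
  at_bound <- any(at_bound_flags(par, spec$lower[free], spec$upper[free]))
  rss <- sum(resid_fn(par)^2)
  n <- length(y)
  p <- length(free)
  stderr <- rep(NA_real_, p)
  names(stderr) <- free
  cond <- jacobian_condition(jac)
  if (is.finite(cond) && n > p) {
    jtj <- crossprod(jac)
    cov <- tryCatch(solve(jtj) * rss / (n - p), error = function(e) NULL)
    if (!is.null(cov)) stderr <- sqrt(pmax(diag(cov), 0))
  }
  list(par = par, stderr = stderr, rss = rss, n_iter = fit$niter,
       converged = converged, at_bound = at_bound, cond = cond,
       outlier = detect_outlier(jac, converged, at_bound,
                                spec$cond_threshold))
}

make_fit_result <- function(estimate, stderr, fixed_mask, rss, n_iter,
                            converged, outlier, at_bound, cond, method_id,
                            segment = NULL) {
  structure(list(estimate = estimate, stderr = stderr, fixed = fixed_mask,
                 rss = rss, n_iter = n_iter, converged = converged,
                 outlier = outlier, at_bound = at_bound, cond = cond,
                 method_id = method_id, segment = segment),
            class = "ivim_fit")
}

#' @export
print.ivim_fit <- function(x, ...) {
  e <- x$estimate
  cat(sprintf("IVIM fit (%s): D = %.4g, D* = %.4g, f = %.4g\n",
              x$method_id, e["D"], e["D_star"], e["f"]))
  cat(sprintf("  rss = %.3g, converged = %s, outlier = %s\n",
              x$rss, x$converged, x$outlier))
  invisible(x)
}

#' Fit a signal curve with one of the three IVIM cascades
#'
#' `fit_ivim()` dispatches on `spec$method_id`; the `fit_one_parameter()`,
#' `fit_two_parameter()` and `fit_three_parameter()` wrappers fix the method.
#'
#' In the constrained cascades the segment-derived parameters are returned
#' bit-identical to the values they were fixed at, with `NA` standard errors.
#' If the high-b segment fit is infeasible or yields a non-positive D, the
#' constrained cascades return a non-converged outlier result rather than
#' erroring, so ensemble runs keep going.
#'
#' @param curve A [signal_curve()].
#' @param spec A [method_spec()]; defaults to the requested method with
#'   default threshold, bounds and initial values.
#' @return An object of class `ivim_fit`: `estimate` (named vector D, D_star,
#'   f), `stderr` (NA for fixed parameters), `fixed` (logical mask), `rss`,
#'   `n_iter`, `converged`, `outlier`, `at_bound`, `cond` (Jacobian condition
#'   number) and, for constrained methods, the `segment` sub-fit.
#' @examples
#' fit_ivim(ivim_signal(reference_params("gm"), study_scheme()),
#'          method_spec("two_parameter"))
#' @export
fit_ivim <- function(curve, spec = method_spec()) {
  stopifnot(inherits(spec, "method_spec"))
  switch(spec$method_id,
         one_parameter = fit_one_parameter(curve, spec),
         two_parameter = fit_two_parameter(curve, spec),
         three_parameter = fit_three_parameter(curve, spec))
}

segment_or_null <- function(curve, spec) {
  tryCatch(fit_high_b_segment(curve, spec$b_threshold),
           error = function(e) NULL)
}

segment_failure_result <- function(spec, fixed_mask) {
  est <- c(D = NA_real_, D_star = NA_real_, f = NA_real_)
  make_fit_result(est, stats::setNames(rep(NA_real_, 3), names(est)),
                  fixed_mask, NA_real_, 0L, FALSE, TRUE, FALSE, Inf,
                  spec$method_id)
}

#' @rdname fit_ivim
#' @export
fit_one_parameter <- function(curve, spec = method_spec("one_parameter")) {
  spec$method_id <- "one_parameter"
  fixed_mask <- c(D = TRUE, D_star = FALSE, f = TRUE)
  seg <- segment_or_null(curve, spec)
  if (is.null(seg) || seg$D <= 0)
    return(segment_failure_result(spec, fixed_mask))
  f_fix <- as.numeric(perfusion_fraction_from_intercept(1, seg$S_int))
  fit <- lm_fit_free(curve, spec, free = "D_star",
                     fixed = c(D = seg$D, f = f_fix))
  est <- c(D = seg$D, D_star = unname(fit$par["D_star"]), f = f_fix)
  se <- c(D = NA_real_, D_star = unname(fit$stderr["D_star"]), f = NA_real_)
  make_fit_result(est, se, fixed_mask, fit$rss, fit$n_iter, fit$converged,
                  fit$outlier, fit$at_bound, fit$cond, spec$method_id, seg)
}

#' @rdname fit_ivim
#' @export
fit_two_parameter <- function(curve, spec = method_spec("two_parameter")) {
  spec$method_id <- "two_parameter"
  fixed_mask <- c(D = TRUE, D_star = FALSE, f = FALSE)
  seg <- segment_or_null(curve, spec)
  if (is.null(seg) || seg$D <= 0)
    return(segment_failure_result(spec, fixed_mask))
  fit <- lm_fit_free(curve, spec, free = c("D_star", "f"),
                     fixed = c(D = seg$D))
  est <- c(D = seg$D, D_star = unname(fit$par["D_star"]),
           f = unname(fit$par["f"]))
  se <- c(D = NA_real_, D_star = unname(fit$stderr["D_star"]),
          f = unname(fit$stderr["f"]))
  make_fit_result(est, se, fixed_mask, fit$rss, fit$n_iter, fit$converged,
                  fit$outlier, fit$at_bound, fit$cond, spec$method_id, seg)
}

#' @rdname fit_ivim
#' @export
fit_three_parameter <- function(curve, spec = method_spec("three_parameter")) {
  spec$method_id <- "three_parameter"
  fixed_mask <- c(D = FALSE, D_star = FALSE, f = FALSE)
  fit <- lm_fit_free(curve, spec, free = c("D", "D_star", "f"),
                     fixed = c())
  est <- fit$par[c("D", "D_star", "f")]
  se <- fit$stderr[c("D", "D_star", "f")]
  make_fit_result(est, se, fixed_mask, fit$rss, fit$n_iter, fit$converged,
                  fit$outlier, fit$at_bound, fit$cond, spec$method_id)
}
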