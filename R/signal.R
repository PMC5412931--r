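#' Normalized diffusion signal curve
#'
#' Pairs an [acquisition_scheme()] with the normalized signal S(b)/S(0) at
#' each b-value. Noiseless curves generated from valid IVIM parameters start
#' at exactly 1 and decrease strictly with b; noisy curves carry no such
#' guarantee and may exceed 1 or dip below 0.
#'
#' @param scheme An `acquisition_scheme`.
#' @param values Numeric vector of normalized signal values, one per b-value.
#' @return An object of class `signal_curve` with fields `scheme` and `values`.
#' @export
signal_curve <- function(scheme, values) {
  if (!inherits(scheme, "acquisition_scheme"))
    stop("invalid curve: scheme must be an acquisition_scheme", call. = FALSE)
  if (!is.numeric(values) || length(values) != length(scheme$b_values))
    stop("invalid curve: values must be numeric with one entry per b-value",
         call. = FALSE)
  structure(list(scheme = scheme, values = as.numeric(values)),
            class = "signal_curve")
}

#' @export
print.signal_curve <- function(x, ...) {
  cat("Signal curve over", length(x$scheme$b_values), "b-values\n")
  print(stats::setNames(round(x$values, 4), x$scheme$b_values))
  invisible(x)
}

#' Bi-exponential IVIM forward model
#'
#' Evaluates the noiseless normalized IVIM signal
#' \deqn{S(b)/S(0) = f e^{-b D^*} + (1 - f) e^{-b D}}
#' at every b-value of the scheme. At b = 0 the value is exactly 1.
#'
#' @param params An [ivim_params()] object (ground truth or estimate).
#' @param scheme An [acquisition_scheme()].
#' @return A [signal_curve()].
#' @examples
#' ivim_signal(reference_params("gm"), study_scheme())
#' @export
ivim_signal <- function(params, scheme) {
  if (!inherits(params, "ivim_params"))
    stop("invalid params: expected an ivim_params object", call. = FALSE)
  if (!inherits(scheme, "acquisition_scheme"))
    stop("invalid scheme: expected an acquisition_scheme object", call. = FALSE)
  b <- scheme$b_values
  signal_curve(scheme, ivim_model_values(b, params$D, params$D_star, params$f))
}

# raw model evaluation on a plain b vector; shared with the fitting layer
ivim_model_values <- function(b, D, D_star, f) {
  v <- f * exp(-b * D_star) + (1 - f) * exp(-b * D)
  v[b == 0] <- 1  # f + (1 - f): exactly 1 regardless of rounding
  v
}

#' Mono-exponential high-b model
#'
#' Evaluates `intercept * exp(-b D)`, the tissue-only decay used for the
#' segmented high-b sub-fit. The free intercept allows extrapolation back to
#' b = 0, where the gap below S(0) = 1 carries the perfusion fraction.
#'
#' @param D Diffusion coefficient, mm^2/s; must be positive.
#' @param intercept Signal at b = 0 on the normalized scale; must be positive.
#' @param scheme An [acquisition_scheme()].
#' @return A [signal_curve()].
#' @export
mono_exp_signal <- function(D, intercept = 1, scheme) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("invalid mono-exponential model: D must be > 0", call. = FALSE)
  if (!is.numeric(intercept) || length(intercept) != 1L ||
      !is.finite(intercept) || intercept <= 0)
    stop("invalid mono-exponential model: intercept must be > 0", call. = FALSE)
  if (!inherits(scheme, "acquisition_scheme"))
    stop("invalid scheme: expected an acquisition_scheme object", call. = FALSE)
  signal_curve(scheme, intercept * exp(-scheme$b_values * D))
}

#' Perfusion fraction from the extrapolated intercept
#'
#' Converts the y-intercept of the high-b mono-exponential fit, S(int), into
#' the perfusion fraction `f = (S(0) - S(int)) / S(0)`. With no vascular
#' compartment the extrapolated intercept equals S(0) and `f` is 0.
#'
#' Noise can push S(int) outside the physical range (0, S(0)]; the result is
#' then clamped to `[0, 1]` and the returned value carries attribute
#' `clamped = TRUE`.
#'
#' @param S0 Signal at b = 0 (positive; 1 on the normalized scale).
#' @param S_int Extrapolated intercept of the high-b fit.
#' @return The perfusion fraction in `[0, 1]`, with a logical `clamped`
#'   attribute.
#' @examples
#' perfusion_fraction_from_intercept(1, 0.885)
#' @export
perfusion_fraction_from_intercept <- function(S0, S_int) {
  if (!is.numeric(S0) || length(S0) != 1L || !is.finite(S0) || S0 <= 0)
    stop("invalid intercept conversion: S0 must be > 0", call. = FALSE)
  if (!is.numeric(S_int) || length(S_int) != 1L || !is.finite(S_int))
    stop("invalid intercept conversion: S_int must be a finite scalar",
         call. = FALSE)
  f <- (S0 - S_int) / S0
  clamped <- FALSE
  if (S_int <= 0 || S_int > S0) {
    f <- min(max(f, 0), 1)
    clamped <- TRUE
  }
  structure(f, clamped = clamped)
}
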