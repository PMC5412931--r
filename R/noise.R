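#' Gaussian noise specification
#'
#' Noise level expressed as a signal-to-noise ratio SNR = mu / sigma, where mu
#' is the maximum of the normalized signal (1 at b = 0, since noiseless curves
#' decrease monotonically) and sigma the standard deviation of the additive
#' zero-mean Gaussian noise. On the normalized scale sigma = 1 / SNR.
#'
#' @param snr Signal-to-noise ratio, > 0.
#' @return An object of class `noise_spec` with fields `snr` and `sigma`.
#' @examples
#' noise_spec(40)$sigma  # 0.025
#' @export
noise_spec <- function(snr) {
  if (!is.numeric(snr) || length(snr) != 1L || !is.finite(snr) || snr <= 0)
    stop("invalid noise spec: snr must be a positive scalar", call. = FALSE)
  structure(list(snr = snr, sigma = 1 / snr), class = "noise_spec")
}

#' Add white Gaussian noise to a signal curve
#'
#' Adds i.i.d. zero-mean Gaussian deviates with standard deviation
#' `noise$sigma` independently at every b-value. The noise is white: the same
#' sigma applies at every b, so low-signal high-b samples have the lowest
#' effective SNR. Draws come from R's global RNG stream, so results are
#' reproducible under `set.seed()`.
#'
#' @param curve A [signal_curve()] (noiseless or already noisy; composable).
#' @param noise A [noise_spec()].
#' @return A new [signal_curve()]; the input is not modified.
#' @export
add_noise <- function(curve, noise) {
  if (!inherits(curve, "signal_curve"))
    stop("invalid curve: expected a signal_curve", call. = FALSE)
  if (!inherits(noise, "noise_spec"))
    stop("invalid noise: expected a noise_spec", call. = FALSE)
  n <- length(curve$values)
  signal_curve(curve$scheme, curve$values + stats::rnorm(n, 0, noise$sigma))
}

#' Monte-Carlo simulation configuration
#'
#' Describes one simulation arm: a ground-truth tissue model, the acquisition
#' scheme, the SNR levels to sweep and the number of noisy replicates per
#' level. Defaults follow the study design: 1000 iterations per SNR level at
#' SNR 20, 30, 40, 50, 60, 70.
#'
#' @param model_params Ground-truth [ivim_params()].
#' @param scheme An [acquisition_scheme()]; defaults to [study_scheme()].
#' @param snr_levels Numeric vector of SNR levels, all > 0.
#' @param n_iterations Number of noisy replicates per SNR level, >= 1.
#' @param seed Master seed; one independent substream is derived per
#'   (model, SNR) pair so levels can be regenerated in isolation.
#' @param model_id Label used in output tables and for substream derivation.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(model_params,
                              scheme = study_scheme(),
                              snr_levels = c(20, 30, 40, 50, 60, 70),
                              n_iterations = 1000,
                              seed = 1L,
                              model_id = "model") {
  if (!inherits(model_params, "ivim_params"))
    stop("invalid config: model_params must be an ivim_params", call. = FALSE)
  if (!inherits(scheme, "acquisition_scheme"))
    stop("invalid config: scheme must be an acquisition_scheme", call. = FALSE)
  if (!is.numeric(snr_levels) || length(snr_levels) < 1L || any(snr_levels <= 0))
    stop("invalid config: snr_levels must all be > 0", call. = FALSE)
  if (!is.numeric(n_iterations) || n_iterations < 1)
    stop("invalid config: n_iterations must be >= 1", call. = FALSE)
  structure(list(model_params = model_params, scheme = scheme,
                 snr_levels = as.numeric(snr_levels),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), model_id = as.character(model_id)),
            class = "simulation_config")
}

# Deterministic substream seed for a (model, SNR) arm. Mixes the master seed,
# a cheap string hash of the model label and the SNR with distinct large
# multipliers; kept below 2^31 - 1 so it is a valid set.seed() argument.
substream_seed <- function(seed, model_id, snr) {
  h <- 0
  for (k in utf8ToInt(as.character(model_id))) h <- (h * 131 + k) %% 1000003
  as.integer((as.double(seed) * 48271 + h * 69621 + round(snr * 100) * 16807) %%
               2147483647)
}

#' Generate the Monte-Carlo signal ensemble
#'
#' For every SNR level in the configuration, draws `n_iterations` independent
#' noisy realizations of the model curve. Each (model, SNR) level uses its own
#' RNG substream derived from the master seed, so ensembles are bit-identical
#' under the same configuration and individual levels are independent and
#' regenerable in isolation.
#'
#' @param config A [simulation_config()].
#' @return A long data frame with columns `model`, `snr`, `iteration`, `b`,
#'   `signal` (one row per iteration x b-value).
#' @examples
#' cfg <- simulation_config(reference_params("gm"), snr_levels = 40,
#'                          n_iterations = 5, seed = 7, model_id = "gm")
#' head(generate_ensemble(cfg))
#' @export
generate_ensemble <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("invalid config: expected a simulation_config", call. = FALSE)
  clean <- ivim_signal(config$model_params, config$scheme)
  b <- config$scheme$b_values
  nb <- length(b)
  n <- config$n_iterations
  out <- vector("list", length(config$snr_levels))
  for (i in seq_along(config$snr_levels)) {
    snr <- config$snr_levels[i]
    sigma <- 1 / snr
    set.seed(substream_seed(config$seed, config$model_id, snr))
    noise <- matrix(stats::rnorm(nb * n, 0, sigma), nrow = nb, ncol = n)
    out[[i]] <- data.frame(
      model = config$model_id,
      snr = snr,
      iteration = rep(seq_len(n), each = nb),
      b = rep(b, times = n),
      signal = as.vector(clean$values + noise))
  }
  do.call(rbind, out)
}

#' Extract one iteration of an ensemble as a signal curve
#'
#' @param ensemble A data frame from [generate_ensemble()].
#' @param snr,iteration Which arm and replicate to extract.
#' @param model Model label; may be omitted when the ensemble holds one model.
#' @return A [signal_curve()].
#' @export
ensemble_curve <- function(ensemble, snr, iteration, model = NULL) {
  rows <- ensemble$snr == snr & ensemble$iteration == iteration
  if (!is.null(model)) rows <- rows & ensemble$model == model
  sub <- ensemble[rows, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no ensemble rows match the requested (model, snr, iteration)",
         call. = FALSE)
  sub <- sub[order(sub$b), , drop = FALSE]
  signal_curve(acquisition_scheme(sub$b), sub$signal)
}
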