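# Shared fixtures: the study scheme, the two tissue models, and small
# ensemble builders. Everything is generated in code; no stored data.

sch11 <- study_scheme()
gm_truth <- reference_params("gm")
tumor_truth <- reference_params("tumor")

make_ensemble <- function(model, snr, n, seed = 42) {
  generate_ensemble(simulation_config(
    reference_params(model), snr_levels = snr, n_iterations = n,
    seed = seed, model_id = model))
}

# Independent minimizer for cross-checking nonlinear fits: same objective,
# different algorithm (quasi-Newton box-constrained vs Levenberg-Marquardt).
nlminb_ivim <- function(curve, start, lower, upper) {
  b <- curve$scheme$b_values
  y <- curve$values
  obj <- function(p) sum((p[3] * exp(-b * p[2]) + (1 - p[3]) * exp(-b * p[1]) - y)^2)
  stats::nlminb(start, obj, lower = lower, upper = upper,
                control = list(abs.tol = 0, rel.tol = 1e-12))
}

# Closed-form ordinary least squares of log(signal) on b (the segment-fit
# oracle), written out rather than delegated to lm().
ols_log_segment <- function(b, s) {
  x <- b
  y <- log(s)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  list(D = -beta, S_int = exp(alpha))
}

# Small two-region phantom: region 1 in the left half, region 2 in the right.
two_region_labels <- function(nx = 6, ny = 5, nz = 3) {
  lab <- array(0L, c(nx, ny, nz))
  lab[1:(nx / 2), , ] <- 1L
  lab[(nx / 2 + 1):nx, , ] <- 2L
  lab
}
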