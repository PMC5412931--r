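#' IVIM parameter triplet
#'
#' Bundles the three parameters of the bi-exponential intravoxel incoherent
#' motion (IVIM) signal model: the tissue diffusion coefficient `D` (mm^2/s),
#' the pseudo-diffusion coefficient `D_star` (mm^2/s) describing incoherent
#' capillary flow, and the perfusion fraction `f` (dimensionless, in `[0, 1]`)
#' giving the share of voxel signal attributed to the vascular compartment.
#'
#' Construction enforces `D > 0`, `D_star > 0` and `0 <= f <= 1` but does not
#' require `D_star > D`; use [is_biexponential()] to test whether a triplet is
#' in the bi-exponential regime where the two compartments are ordered.
#'
#' @param D Tissue diffusion coefficient, mm^2/s. Must be positive.
#' @param D_star Pseudo-diffusion coefficient, mm^2/s. Must be positive.
#' @param f Perfusion fraction in `[0, 1]`.
#' @return An object of class `ivim_params`.
#' @seealso [reference_params()] for the gray-matter and tumor study models.
#' @examples
#' p <- ivim_params(D = 8.32e-4, D_star = 2.68e-2, f = 0.115)
#' is_biexponential(p)
#' @export
ivim_params <- function(D, D_star, f) {
  for (nm in c("D", "D_star", "f")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("invalid IVIM parameters: '", nm, "' must be a finite scalar",
           call. = FALSE)
  }
  if (D <= 0)
    stop("invalid IVIM parameters: D must be > 0 (got ", D, ")", call. = FALSE)
  if (D_star <= 0)
    stop("invalid IVIM parameters: D_star must be > 0 (got ", D_star, ")",
         call. = FALSE)
  if (f < 0 || f > 1)
    stop("invalid IVIM parameters: f must lie in [0, 1] (got ", f, ")",
         call. = FALSE)
  structure(list(D = D, D_star = D_star, f = f), class = "ivim_params")
}

#' @rdname ivim_params
#' @param params An `ivim_params` object.
#' @export
is_biexponential <- function(params) {
  stopifnot(inherits(params, "ivim_params"))
  params$D_star > params$D
}

#' @export
print.ivim_params <- function(x, ...) {
  cat(sprintf("IVIM parameters: D = %g mm^2/s, D* = %g mm^2/s, f = %g\n",
              x$D, x$D_star, x$f))
  invisible(x)
}

#' @export
as.numeric.ivim_params <- function(x, ...) {
  c(D = x$D, D_star = x$D_star, f = x$f)
}

#' Study tissue models
#'
#' Ground-truth IVIM parameters for the two simulated tissue types: healthy
#' gray matter (well-perfused, pronounced bi-exponential decay) and a
#' low-perfused pediatric brain tumor (subtle bi-exponential decay, with
#' `D_star` only ~4.4x `D`).
#'
#' @param model `"gm"` for gray matter or `"tumor"`.
#' @return An [ivim_params()] object.
#' @examples
#' reference_params("tumor")
#' @export
reference_params <- function(model = c("gm", "tumor")) {
  model <- match.arg(model)
  switch(model,
         gm    = ivim_params(D = 8.32e-4, D_star = 2.68e-2, f = 0.115),
         tumor = ivim_params(D = 1.63e-3, D_star = 7.23e-3, f = 0.0953))
}
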