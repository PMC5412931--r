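#' Diffusion-weighting acquisition scheme
#'
#' An ordered schedule of b-values (s/mm^2) at which the normalized diffusion
#' signal is sampled. The schedule must start at b = 0 (the normalization
#' reference), be strictly increasing and contain no duplicates.
#'
#' @param b_values Numeric vector of b-values in s/mm^2.
#' @return An object of class `acquisition_scheme` wrapping the b-values.
#' @examples
#' study_scheme()
#' @export
acquisition_scheme <- function(b_values) {
  if (!is.numeric(b_values) || length(b_values) < 2L || anyNA(b_values))
    stop("invalid scheme: b_values must be a numeric vector of length >= 2",
         call. = FALSE)
  if (any(b_values < 0))
    stop("invalid scheme: all b-values must be >= 0", call. = FALSE)
  if (b_values[1] != 0)
    stop("invalid scheme: first b-value must be 0", call. = FALSE)
  if (any(diff(b_values) <= 0))
    stop("invalid scheme: b-values must be strictly increasing with no duplicates",
         call. = FALSE)
  structure(list(b_values = as.numeric(b_values)), class = "acquisition_scheme")
}

#' @rdname acquisition_scheme
#' @details `study_scheme()` returns the 11-point schedule used throughout the
#'   simulation study: b = 0, 20, 40, 80, 110, 140, 170, 200, 300, 500,
#'   1000 s/mm^2 (eight points at or below the perfusion threshold of
#'   200 s/mm^2 plus three high-b points for the mono-exponential segment).
#' @export
study_scheme <- function() {
  acquisition_scheme(c(0, 20, 40, 80, 110, 140, 170, 200, 300, 500, 1000))
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat("Acquisition scheme:", length(x$b_values), "b-values (s/mm^2):",
      paste(x$b_values, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.acquisition_scheme <- function(x) length(x$b_values)
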