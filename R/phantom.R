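#' Digital multi-compartment phantom specification
#'
#' Describes a 3D label volume whose compartments (e.g. gray matter, tumor,
#' CSF) each decay with their own IVIM parameters, plus the acquisition
#' scheme and noise level used to synthesize the 4D multi-b-value signal.
#' Unlabeled (zero) voxels are background and emit no signal.
#'
#' @param labels 3D integer array; 0 = background, positive values index
#'   `regions`.
#' @param regions Named list of [ivim_params()], one per positive label value
#'   (name order matches label value 1, 2, ...).
#' @param scheme An [acquisition_scheme()].
#' @param noise A [noise_spec()] or `NULL` for a noiseless phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(labels, regions, scheme = study_scheme(),
                         noise = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("invalid phantom: labels must be a 3D array", call. = FALSE)
  if (any(dim(labels) < 1L))
    stop("invalid phantom: dimensions must be positive", call. = FALSE)
  lab_vals <- sort(unique(as.integer(labels[labels > 0])))
  if (length(lab_vals) && max(lab_vals) > length(regions))
    stop("invalid phantom: label ", max(lab_vals),
         " has no matching region parameters", call. = FALSE)
  if (!all(vapply(regions, inherits, TRUE, what = "ivim_params")))
    stop("invalid phantom: every region needs ivim_params", call. = FALSE)
  if (!is.null(noise) && !inherits(noise, "noise_spec"))
    stop("invalid phantom: noise must be a noise_spec or NULL", call. = FALSE)
  structure(list(labels = labels, regions = regions, scheme = scheme,
                 noise = noise), class = "phantom_spec")
}

#' Synthesize a 4D multi-b-value phantom volume
#'
#' Every labeled voxel receives its region's noiseless IVIM decay along the
#' fourth (b) dimension plus, when a noise spec is present, i.i.d. Gaussian
#' noise; background voxels are zero everywhere. Noise draws come from the
#' global RNG stream (seed with `set.seed()` for reproducibility).
#'
#' @param spec A [phantom_spec()].
#' @return A 4D array of dimension `c(dim(labels), length(scheme))`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- dim(spec$labels)
  nb <- length(spec$scheme$b_values)
  vol <- array(0, c(dims, nb))
  flat <- matrix(0, prod(dims), nb)
  lab <- as.integer(spec$labels)
  for (r in seq_along(spec$regions)) {
    idx <- which(lab == r)
    if (!length(idx)) next
    clean <- ivim_signal(spec$regions[[r]], spec$scheme)$values
    block <- matrix(rep(clean, each = length(idx)), nrow = length(idx))
    if (!is.null(spec$noise))
      block <- block + matrix(stats::rnorm(length(idx) * nb, 0,
                                           spec$noise$sigma),
                              nrow = length(idx))
    flat[idx, ] <- block
  }
  array(flat, c(dims, nb))
}

#' Write / read a phantom as NIfTI plus a b-value sidecar
#'
#' The 4D signal and 3D label volumes are written as NIfTI files and the
#' b-value schedule as a plain text sidecar (one value per line, ordered like
#' the 4th dimension).
#'
#' @param volume 4D signal array.
#' @param labels 3D label array.
#' @param scheme The [acquisition_scheme()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_phantom_nifti <- function(volume, labels, scheme, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dwi <- file.path(dir, "phantom_dwi.nii.gz")
  lab <- file.path(dir, "phantom_labels.nii.gz")
  bval <- file.path(dir, "phantom.bval")
  RNifti::writeNifti(RNifti::asNifti(volume), dwi)
  RNifti::writeNifti(RNifti::asNifti(labels), lab)
  writeLines(format(scheme$b_values, trim = TRUE), bval)
  invisible(c(dwi = dwi, labels = lab, bval = bval))
}

#' @rdname write_phantom_nifti
#' @param dwi,labels_file,bval Paths written by `write_phantom_nifti()`.
#' @export
read_phantom_nifti <- function(dwi, labels_file, bval) {
  vol <- array(as.numeric(RNifti::readNifti(dwi)), dim = dim(RNifti::readNifti(dwi)))
  lab <- array(as.integer(round(as.numeric(RNifti::readNifti(labels_file)))),
               dim = dim(RNifti::readNifti(labels_file)))
  b <- as.numeric(readLines(bval))
  list(volume = vol, labels = lab, scheme = acquisition_scheme(b))
}
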