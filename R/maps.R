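#' Voxel-wise IVIM parameter mapping
#'
#' Applies a fitting cascade voxel-by-voxel to a 4D multi-b-value volume.
#' Each in-mask voxel is first normalized by its own measured b = 0 sample,
#' then fitted; voxels whose fitted perfusion fraction exceeds `f_max`
#' (default 0.3) are masked out as non-physiological, the rule used to remove
#' CSF-dominated voxels; outlier fits are flagged and their values withheld
#' from the maps.
#'
#' The returned masks partition the volume: `background` (outside the brain
#' mask), `csf_mask` (fitted f above `f_max`) and `fitted` (everything else
#' in-mask). Inside `fitted`, voxels with `outlier` set carry `NA` in the
#' parameter maps.
#'
#' @param volume 4D array (x, y, z, b).
#' @param scheme An [acquisition_scheme()] matching the 4th dimension.
#' @param spec A [method_spec()].
#' @param brain_mask Optional 3D logical array of voxels to fit; defaults to
#'   voxels with positive b = 0 signal.
#' @param f_max CSF threshold on the fitted perfusion fraction (default 0.3).
#' @return An object of class `parameter_maps`: 3D arrays `D`, `D_star`,
#'   `f`, logical arrays `fitted`, `csf_mask`, `background`, `outlier`.
#' @export
fit_volume <- function(volume, scheme, spec = method_spec("one_parameter"),
                       brain_mask = NULL, f_max = 0.3) {
  if (!is.array(volume) || length(dim(volume)) != 4L)
    stop("invalid volume: expected a 4D (x, y, z, b) array", call. = FALSE)
  dims <- dim(volume)
  if (dims[4] != length(scheme$b_values))
    stop("invalid volume: 4th dimension (", dims[4],
         ") does not match the scheme length (", length(scheme$b_values), ")",
         call. = FALSE)
  flat <- matrix(volume, prod(dims[1:3]), dims[4])
  if (is.null(brain_mask)) {
    mask <- flat[, 1] > 0
  } else {
    if (!identical(dim(brain_mask), dims[1:3]))
      stop("invalid mask: dimensions do not match the volume", call. = FALSE)
    mask <- as.logical(brain_mask)
    if (any(mask & flat[, 1] <= 0))
      stop("invalid volume: non-positive b = 0 signal inside the brain mask",
           call. = FALSE)
  }
  nvox <- prod(dims[1:3])
  Dm <- Ds <- Fm <- rep(NA_real_, nvox)
  out_flag <- rep(FALSE, nvox)
  idx <- which(mask)
  for (v in idx) {
    values <- flat[v, ] / flat[v, 1]
    fit <- fit_ivim(signal_curve(scheme, values), spec)
    Dm[v] <- fit$estimate[["D"]]
    Ds[v] <- fit$estimate[["D_star"]]
    Fm[v] <- fit$estimate[["f"]]
    out_flag[v] <- fit$outlier
  }
  csf <- mask & !is.na(Fm) & Fm > f_max
  fitted <- mask & !csf
  withheld <- fitted & out_flag
  Dm[csf | withheld | !mask] <- NA_real_
  Ds[csf | withheld | !mask] <- NA_real_
  Fm[csf | withheld | !mask] <- NA_real_
  shape <- function(x) array(x, dims[1:3])
  structure(list(D = shape(Dm), D_star = shape(Ds), f = shape(Fm),
                 fitted = shape(fitted), csf_mask = shape(csf),
                 background = shape(!mask), outlier = shape(out_flag),
                 f_max = f_max, method_id = spec$method_id),
            class = "parameter_maps")
}

#' Write parameter maps as NIfTI files
#'
#' @param maps A `parameter_maps` object from [fit_volume()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_parameter_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in c("D", "D_star", "f")) {
    p <- file.path(dir, paste0("map_", nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]]), p)
    paths[nm] <- p
  }
  for (nm in c("fitted", "csf_mask")) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]] * 1), p)
    paths[nm] <- p
  }
  invisible(paths)
}
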