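#!/usr/bin/env Rscript

# Stage 5: voxel-wise parameter mapping on a synthetic digital phantom.
#
# Three compartments: gray matter, low-perfused tumor and a CSF-like region
# whose perfusion fraction (0.4) exceeds the physiological range. The maps
# are fitted voxel-by-voxel (each voxel normalized by its own b = 0 sample);
# voxels with fitted f > 0.3 are masked as non-physiological, which should
# capture the CSF region completely.

library(ivimsim)

dir.create("results/phantom", showWarnings = FALSE, recursive = TRUE)
gm <- reference_params("gm")
tumor <- reference_params("tumor")
csf <- ivim_params(D = 3.0e-3, D_star = 3.0e-2, f = 0.4)
sch <- study_scheme()

labels <- array(0L, c(12, 12, 3))
labels[2:6, 2:11, ] <- 1L     # gray matter slab
labels[7:11, 2:6, ] <- 2L     # tumor
labels[7:11, 7:11, ] <- 3L    # CSF-like

set.seed(1)
vol <- generate_phantom(phantom_spec(labels, list(gm = gm, tumor = tumor,
                                                  csf = csf),
                                     sch, noise = noise_spec(40)))
paths <- write_phantom_nifti(vol, labels, sch, "results/phantom")

# Simultaneous fitting: in CSF-like voxels the two decay rates are close
# (D* ~ 3 D) and the high-b segment of the constrained cascades is heavily
# perfusion-contaminated, underestimating f and letting part of the CSF slip
# under the 0.3 threshold.
maps <- fit_volume(vol, sch, method_spec("three_parameter"),
                   brain_mask = labels > 0)
write_parameter_maps(maps, "results/phantom")

for (r in 1:3) {
  nm <- c("gm", "tumor", "csf")[r]
  truth <- list(gm, tumor, csf)[[r]]
  vox <- labels == r
  cat(sprintf(
    "%-6s voxels %3d | csf-masked %5.1f%% | median D %.3e (true %.3e) | median f %.3f (true %.3f)\n",
    nm, sum(vox), 100 * mean(maps$csf_mask[vox]),
    median(maps$D[vox], na.rm = TRUE), truth$D,
    median(maps$f[vox], na.rm = TRUE), truth$f))
}
cat("fitted voxels:", sum(maps$fitted), "| thresholded:", sum(maps$csf_mask),
    "| background:", sum(maps$background), "\n")
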