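#' Calibrated CT volume
#'
#' Container for a knee CT volume in Hounsfield units. The voxel array is
#' stored with the in-plane dimensions first and the bone's long axis third
#' (the constructor permutes the array if `long_axis` differs), and
#' `distal_first` records whether slice 1 is the joint-facing reference end
#' from which skeletal regions are measured.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing_mm length-3 positive numeric, voxel spacing in mm in the
#'   order of the array dimensions as supplied.
#' @param long_axis which supplied dimension runs along the bone (default 3).
#' @param distal_first is slice 1 (after permutation) the reference end?
#' @return list of class `ct_volume` with `voxels`, `spacing_mm`
#'   (reordered: in-plane x, in-plane y, long axis), `distal_first`.
#' @export
ct_volume <- function(voxels, spacing_mm, long_axis = 3L, distal_first = TRUE) {
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3-D array", call. = FALSE)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 positive values", call. = FALSE)
  }
  perm <- c(setdiff(1:3, long_axis), long_axis)
  structure(list(voxels = aperm(voxels, perm),
                 spacing_mm = as.numeric(spacing_mm[perm]),
                 distal_first = isTRUE(distal_first)),
            class = "ct_volume")
}

#' Fit the HU-to-density calibration line
#'
#' Least-squares line mapping mean Hounsfield units of the calibration-rod
#' ROIs to their known bone-equivalent densities:
#' density (g/cm^3) = slope * HU + intercept. An in-field phantom with rods
#' of known density is scanned with each subject, so the mapping is fitted
#' per scan.
#'
#' @param rod_mean_hu numeric, mean HU of each rod ROI (>= 2 distinct).
#' @param rod_densities numeric, known densities in g/cm^3.
#' @return list of class `qct_calibration`: `slope`, `intercept`,
#'   `residuals`, `r_squared`.
#' @examples
#' fit_calibration(c(0, 1000), c(0, 1))  # slope 0.001, intercept 0
#' @export
fit_calibration <- function(rod_mean_hu, rod_densities) {
  if (length(rod_mean_hu) != length(rod_densities) || length(rod_mean_hu) < 2L) {
    stop("need >= 2 rods with matching densities", call. = FALSE)
  }
  if (max(rod_mean_hu) - min(rod_mean_hu) < sqrt(.Machine$double.eps)) {
    stop("degenerate rod HU spread: cannot calibrate", call. = FALSE)
  }
  fit <- stats::lm(rod_densities ~ rod_mean_hu)
  # rod fits are often exact (noiseless phantoms): silence the perfect-fit note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residuals = unname(stats::residuals(fit)),
                 r_squared = r2),
            class = "qct_calibration")
}

#' Convert HU to calibrated density
#' @param calibration a [fit_calibration()] model.
#' @param hu numeric HU values.
#' @return densities in g/cm^3.
#' @export
hu_to_density <- function(calibration, hu) {
  calibration$slope * hu + calibration$intercept
}

# ---- internal morphology -----------------------------------------------

# shift a logical 3-D array by (dx, dy, dz), padding with FALSE
shift3 <- function(mask, dx = 0L, dy = 0L, dz = 0L) {
  d <- dim(mask)
  out <- array(FALSE, d)
  sx <- max(1L, 1L + dx):min(d[1], d[1] + dx)
  sy <- max(1L, 1L + dy):min(d[2], d[2] + dy)
  sz <- max(1L, 1L + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- mask[sx - dx, sy - dy, sz - dz]
  out
}

# largest 26-connected component of a logical array (igraph components on
# the foreground voxels only, so the cost scales with the surface voxels)
largest_component26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) stop("empty mask: nothing to label", call. = FALSE)
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0 &
                       (offsets[, 1] > 0 | (offsets[, 1] == 0 & offsets[, 2] > 0) |
                          (offsets[, 1] == 0 & offsets[, 2] == 0 & offsets[, 3] > 0)), ,
                     drop = FALSE]
  edges <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    nx <- co[, 1] + offsets[k, 1]; ny <- co[, 2] + offsets[k, 2]
    nz <- co[, 3] + offsets[k, 3]
    ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    lin <- (nz[ok] - 1L) * d[1] * d[2] + (ny[ok] - 1L) * d[1] + nx[ok]
    nb <- pos[lin]
    keep <- nb > 0L
    edges[[k]] <- cbind(which(ok)[keep], nb[keep])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  out <- array(FALSE, d)
  out[idx[comp$membership == biggest]] <- TRUE
  out
}

# flood-fill reachable background from a seed set, constrained to `bg`;
# 4-connected in-plane when inplane_only, else 6-connected in 3-D
flood_background <- function(bg, seed, inplane_only = FALSE) {
  reach <- seed & bg
  repeat {
    grow <- shift3(reach, 1L) | shift3(reach, -1L) |
      shift3(reach, 0L, 1L) | shift3(reach, 0L, -1L)
    if (!inplane_only) grow <- grow | shift3(reach, 0L, 0L, 1L) | shift3(reach, 0L, 0L, -1L)
    new <- reach | (bg & grow)
    if (sum(new) == sum(reach)) break
    reach <- new
  }
  reach
}

# fill holes: per-slice 2-D fill (background not reachable from the
# in-plane border), then a 3-D pass for cavities the slice-wise fill misses
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  border2 <- array(FALSE, d)
  border2[1, , ] <- TRUE; border2[d[1], , ] <- TRUE
  border2[, 1, ] <- TRUE; border2[, d[2], ] <- TRUE
  reach <- flood_background(bg, border2, inplane_only = TRUE)
  mask <- mask | (bg & !reach)
  bg <- !mask
  border3 <- border2
  border3[, , 1] <- TRUE; border3[, , d[3]] <- TRUE
  reach <- flood_background(bg, border3, inplane_only = FALSE)
  mask | (bg & !reach)
}

# in-plane erosion by a Euclidean disc of radius r_px (applied per slice)
erode_disk <- function(mask, r_px) {
  if (r_px <= 0) return(mask)
  offs <- expand.grid(dx = -r_px:r_px, dy = -r_px:r_px)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r_px^2, ]
  out <- mask
  for (k in seq_len(nrow(offs))) {
    if (offs$dx[k] == 0 && offs$dy[k] == 0) next
    out <- out & shift3(mask, offs$dx[k], offs$dy[k])
  }
  out
}

# ---- segmentation -------------------------------------------------------

#' Segment the periosteal bone surface
#'
#' Converts the volume to calibrated density, thresholds at the fixed
#' periosteal density, keeps the largest 26-connected component (the bone;
#' calibration rods and table parts form smaller components), and fills
#' interior holes slice-wise and in 3-D. Hole filling automates the manual
#' correction of missing low-density surface voxels that interactive
#' protocols require.
#'
#' @param volume a [ct_volume()].
#' @param calibration a [fit_calibration()] model.
#' @param threshold periosteal density threshold in g/cm^3 (default 0.15).
#' @return logical array congruent with the volume (class `bone_mask`,
#'   attribute `kind = "periosteal"`).
#' @export
segment_periosteal <- function(volume, calibration, threshold = 0.15) {
  stopifnot(inherits(volume, "ct_volume"))
  dens <- hu_to_density(calibration, volume$voxels)
  fg <- dens >= threshold
  if (!any(fg)) stop("segmentation error: no voxel reaches the periosteal threshold",
                     call. = FALSE)
  mask <- largest_component26(fg)
  mask <- fill_holes(mask)
  attr(mask, "kind") <- "periosteal"
  class(mask) <- c("bone_mask", class(mask))
  mask
}

#' Split bone into cortical and trabecular compartments
#'
#' Erodes the periosteal mask in-plane by a disc whose radius in pixels is
#' `depth_mm` divided by the in-plane pixel size, rounded half away from
#' zero. The eroded mask is the trabecular compartment; the removed rim is
#' cortical. The divisor is the in-plane pixel size (not slice thickness),
#' so the erosion is applied slice by slice.
#'
#' @param periosteal periosteal mask from [segment_periosteal()].
#' @param spacing_mm voxel spacing (in-plane x, in-plane y, slice).
#' @param depth_mm cortical depth to remove in mm (default 3.5).
#' @param rounding function mapping the pixel count 3.5/pixel-size to an
#'   integer (default round-half-away-from-zero).
#' @return list with logical arrays `cortical` and `trabecular` and the
#'   `erosion_px` used. Warns (not errors) if erosion removes everything.
#' @export
split_cortical_trabecular <- function(periosteal, spacing_mm, depth_mm = 3.5,
                                      rounding = round_half_away) {
  px <- spacing_mm[1]
  if (abs(spacing_mm[1] - spacing_mm[2]) > 1e-9) {
    warning("anisotropic in-plane spacing; using the mean pixel size")
    px <- mean(spacing_mm[1:2])
  }
  r_px <- as.integer(rounding(depth_mm / px))
  trab <- erode_disk(unclass(periosteal), r_px)
  if (!any(trab)) warning("erosion removed the whole bone: trabecular mask is empty")
  cort <- unclass(periosteal) & !trab
  attr(trab, "kind") <- "trabecular"; attr(cort, "kind") <- "cortical"
  list(cortical = cort, trabecular = trab, erosion_px = r_px)
}

#' Partition bone length into skeletal regions
#'
#' Bone length is the slice extent of the segmented mask along the long
#' axis (not the scan extent, which depends on acquisition). Measuring from
#' the joint-facing reference end, the epiphysis, metaphysis and diaphysis
#' are the consecutive bands [0, 10%), [10%, 20%) and [20%, 30%) of bone
#' length, with band edges at `floor(fraction * n_slices)`.
#'
#' @param mask periosteal (or trabecular) mask.
#' @param volume the [ct_volume()] (for the `distal_first` orientation).
#' @param fractions cumulative band edges (default `c(0.1, 0.2, 0.3)`).
#' @return list of class `region_partition`: per-region integer vectors of
#'   absolute slice indices (`epiphysis`, `metaphysis`, `diaphysis`), plus
#'   `bone_slices` (full extent) and `n_slices`.
#' @export
partition_regions <- function(mask, volume, fractions = c(0.1, 0.2, 0.3)) {
  has <- which(apply(unclass(mask), 3, any))
  if (!length(has)) stop("empty mask: cannot partition", call. = FALSE)
  z0 <- min(has); z1 <- max(has)
  n <- z1 - z0 + 1L
  if (n < 10L) warning("bone spans fewer than 10 slices; regions are coarse")
  rel <- if (volume$distal_first) seq.int(z0, z1) else seq.int(z1, z0)
  edges <- floor(fractions * n)
  regions <- list(epiphysis = rel[seq_len(edges[1])],
                  metaphysis = rel[setdiff(seq_len(edges[2]), seq_len(edges[1]))],
                  diaphysis = rel[setdiff(seq_len(edges[3]), seq_len(edges[2]))])
  structure(c(regions, list(bone_slices = rel, n_slices = n)),
            class = "region_partition")
}

#' Quantify marrow adipose tissue volume per region
#'
#' Counts trabecular voxels whose attenuation lies in the marrow-fat HU
#' window (inclusive bounds) within each region's slices and converts the
#' count to cm^3 with the voxel volume.
#'
#' @param volume a [ct_volume()].
#' @param trabecular trabecular mask.
#' @param partition a [partition_regions()] result.
#' @param hu_window inclusive HU bounds for marrow fat
#'   (default `c(-205, -50)`).
#' @return data.frame (`mat_result`): region, voxel count, volume_cm3;
#'   attribute `hu_window`.
#' @export
quantify_mat <- function(volume, trabecular, partition, hu_window = c(-205, -50)) {
  vox_cm3 <- prod(volume$spacing_mm) / 1000
  fat <- unclass(trabecular) & volume$voxels >= hu_window[1] &
    volume$voxels <= hu_window[2]
  regions <- c("epiphysis", "metaphysis", "diaphysis")
  counts <- vapply(regions, function(r) {
    sl <- partition[[r]]
    if (!length(sl)) return(0L)
    sum(fat[, , sl, drop = FALSE])
  }, integer(1))
  out <- data.frame(region = regions, voxels = counts,
                    volume_cm3 = counts * vox_cm3, row.names = NULL)
  attr(out, "hu_window") <- hu_window
  class(out) <- c("mat_result", "data.frame")
  out
}

#' Trabecular bone mineral content per region
#'
#' Integrates calibrated density over trabecular voxels:
#' BMC (g) = sum of density (g/cm^3) x voxel volume (cm^3). Marrow voxels
#' may calibrate to negative bone-equivalent density, so negative regional
#' totals are legitimate and preserved.
#'
#' @param volume a [ct_volume()].
#' @param calibration a [fit_calibration()] model.
#' @param trabecular trabecular mask.
#' @param partition a [partition_regions()] result.
#' @return data.frame (`bmc_result`): region, bmc_g; a `total` row is
#'   appended covering the three regions.
#' @export
trabecular_bmc <- function(volume, calibration, trabecular, partition) {
  vox_cm3 <- prod(volume$spacing_mm) / 1000
  dens <- hu_to_density(calibration, volume$voxels)
  trab <- unclass(trabecular)
  regions <- c("epiphysis", "metaphysis", "diaphysis")
  bmc <- vapply(regions, function(r) {
    sl <- partition[[r]]
    if (!length(sl)) return(0)
    sum(dens[, , sl, drop = FALSE][trab[, , sl, drop = FALSE]]) * vox_cm3
  }, numeric(1))
  out <- data.frame(region = c(regions, "total"), bmc_g = c(bmc, sum(bmc)),
                    row.names = NULL)
  class(out) <- c("bmc_result", "data.frame")
  out
}

#' Run the full QCT marrow-adiposity pipeline
#'
#' Composes calibration, periosteal segmentation, cortical/trabecular
#' splitting, region partitioning, MAT quantification and trabecular BMC
#' into one deterministic pass. Rod ROIs in the phantom descriptor are index
#' boxes `list(c(xmin, xmax), c(ymin, ymax), c(zmin, zmax))` over the
#' canonical (in-plane, in-plane, long-axis) array.
#'
#' @param volume a [ct_volume()].
#' @param phantom list with `rod_rois` (list of index boxes) and
#'   `rod_densities` (g/cm^3).
#' @param config list of stage parameters; recognized entries
#'   `threshold` (0.15), `erosion_mm` (3.5), `hu_window` (c(-205, -50)),
#'   `fractions` (c(0.1, 0.2, 0.3)).
#' @return list: `calibration`, `masks` (periosteal/cortical/trabecular),
#'   `partition`, `mat` ([quantify_mat()] table), `bmc`
#'   ([trabecular_bmc()] table), `config`.
#' @export
run_qct <- function(volume, phantom, config = list()) {
  cfg <- utils::modifyList(list(threshold = 0.15, erosion_mm = 3.5,
                                hu_window = c(-205, -50),
                                fractions = c(0.1, 0.2, 0.3)), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  rod_hu <- vapply(phantom$rod_rois, function(b) {
    mean(volume$voxels[b[[1]][1]:b[[1]][2], b[[2]][1]:b[[2]][2],
                       b[[3]][1]:b[[3]][2]])
  }, numeric(1))
  cal <- stage("calibration", fit_calibration(rod_hu, phantom$rod_densities))
  perio <- stage("segmentation", segment_periosteal(volume, cal, cfg$threshold))
  split <- stage("cortical-split",
                 split_cortical_trabecular(perio, volume$spacing_mm, cfg$erosion_mm))
  part <- stage("partition", partition_regions(perio, volume, cfg$fractions))
  mat <- stage("mat", quantify_mat(volume, split$trabecular, part, cfg$hu_window))
  bmc <- stage("bmc", trabecular_bmc(volume, cal, split$trabecular, part))
  list(calibration = cal,
       masks = list(periosteal = perio, cortical = split$cortical,
                    trabecular = split$trabecular),
       partition = part, mat = mat, bmc = bmc, config = cfg)
}

#' Read a CT volume from NIfTI
#' @param path NIfTI file (.nii or .nii.gz).
#' @param long_axis,distal_first see [ct_volume()].
#' @return a [ct_volume()].
#' @export
read_ct_nifti <- function(path, long_axis = 3L, distal_first = TRUE) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim(img)), RNifti::pixdim(img),
            long_axis = long_axis, distal_first = distal_first)
}

#' Write a CT volume (or mask) to NIfTI
#' @param volume a [ct_volume()] or numeric/logical 3-D array.
#' @param path output path.
#' @param spacing_mm spacing, required when `volume` is a bare array.
#' @export
write_ct_nifti <- function(volume, path, spacing_mm = NULL) {
  if (inherits(volume, "ct_volume")) {
    arr <- volume$voxels; spacing_mm <- volume$spacing_mm
  } else {
    arr <- volume * 1
    if (is.null(spacing_mm)) stop("`spacing_mm` required for bare arrays", call. = FALSE)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
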