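#' Cohort simulation specification
#'
#' Describes a multi-group cohort by per-group sizes, per-variable normal
#' means/SDs for continuous covariates and Bernoulli rates for binary ones.
#' An `NA` mean or rate marks a variable that does not apply to a group
#' (e.g. injury duration in uninjured controls) and yields `NA` values.
#' Binary covariates are simulated independently of the continuous ones.
#'
#' @param group_sizes named positive integer vector.
#' @param means,sds named lists: variable -> named numeric vector over
#'   groups (means; non-negative sds).
#' @param binary named list: variable -> named rate vector in [0, 1].
#' @param seed integer RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes, means, sds, binary = list(), seed = 1L) {
  if (any(group_sizes <= 0)) stop("group sizes must be positive", call. = FALSE)
  if (!identical(sort(names(means)), sort(names(sds)))) {
    stop("`means` and `sds` must cover the same variables", call. = FALSE)
  }
  for (v in names(sds)) {
    if (any(sds[[v]] < 0, na.rm = TRUE)) stop("sds must be non-negative", call. = FALSE)
  }
  for (v in names(binary)) {
    r <- binary[[v]]
    if (any(r < 0 | r > 1, na.rm = TRUE)) stop("rates must be in [0, 1]", call. = FALSE)
  }
  structure(list(group_sizes = group_sizes, means = means, sds = sds,
                 binary = binary, seed = seed),
            class = "cohort_spec")
}

#' Default three-group SCI cohort specification
#'
#' The study conditions: controls without SCI (n = 23), acute SCI (n = 12)
#' and chronic SCI (n = 18), with covariate means and SDs set to the
#' published cohort characteristics (age, injury timing, miR-148a-3p/5p
#' normalized counts, BMI, diaphysis marrow adiposity, regional trabecular
#' BMC) and binary rates for sex and tetraplegia.
#'
#' @param seed integer RNG seed.
#' @return a [cohort_spec()].
#' @export
sci_cohort_spec <- function(seed = 1L) {
  g <- c("none", "acute", "chronic")
  v <- function(a, b, c_) stats::setNames(c(a, b, c_), g)
  cohort_spec(
    group_sizes = stats::setNames(c(23L, 12L, 18L), g),
    means = list(age = v(37.08, 36.88, 34.43),
                 years_post_injury = v(NA, 0.23, 10.08),
                 age_at_injury = v(NA, 36.67, 24.36),
                 mir148a_3p = v(9731.65, 13241.08, 9407.89),
                 mir148a_5p = v(88.30, 130.16, 92.11),
                 bmi = v(24.22, 23.51, 23.28),
                 mat_diaphysis_cm3 = v(NA, 3.45, 7.80),
                 bmc_diaphysis_g = v(NA, 1.19, -0.52),
                 bmc_epiphysis_g = v(NA, 10.79, 3.22),
                 bmc_metaphysis_g = v(NA, 3.24, -0.24),
                 bmc_total_g = v(NA, 15.22, 2.44)),
    sds = list(age = v(11.07, 9.45, 9.51),
               years_post_injury = v(NA, 0.05, 7.19),
               age_at_injury = v(NA, 9.46, 7.77),
               mir148a_3p = v(4406.23, 2927.81, 2463.35),
               mir148a_5p = v(48.13, 64.73, 27.17),
               bmi = v(3.21, 4.30, 4.66),
               mat_diaphysis_cm3 = v(NA, 1.77, 4.08),
               bmc_diaphysis_g = v(NA, 0.92, 0.63),
               bmc_epiphysis_g = v(NA, 3.48, 2.10),
               bmc_metaphysis_g = v(NA, 1.79, 1.26),
               bmc_total_g = v(NA, 5.95, 3.47)),
    binary = list(male = v(0.565, 0.833, 0.778),
                  tetraplegic = v(NA, 0.583, 0.111)),
    seed = seed)
}

#' Generate a synthetic cohort table
#'
#' One record per subject; continuous covariates drawn from per-group
#' normals, binary covariates from per-group Bernoullis, `NA` where a
#' variable does not apply. Deterministic under a fixed spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with `subject_id`, `group`, covariate columns.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    groups <- names(spec$group_sizes)
    rows <- lapply(groups, function(g) {
      n <- spec$group_sizes[[g]]
      df <- data.frame(subject_id = sprintf("%s_%02d", g, seq_len(n)),
                       group = g, stringsAsFactors = FALSE)
      for (v in names(spec$means)) {
        m <- spec$means[[v]][[g]]; s <- spec$sds[[v]][[g]]
        df[[v]] <- if (is.na(m)) NA_real_ else stats::rnorm(n, m, s)
      }
      for (v in names(spec$binary)) {
        r <- spec$binary[[v]][[g]]
        df[[v]] <- if (is.na(r)) NA_integer_ else stats::rbinom(n, 1L, r)
      }
      df
    })
    do.call(rbind, rows)
  })
}

#' Count matrix simulation specification
#'
#' Negative-binomial miRNA counts with sample-specific library size factors
#' and a spiked set of differential miRNAs. The NB is parameterized by mean
#' and dispersion with variance = mu + mu^2 * dispersion; dispersion 0 is
#' the Poisson limit. The mean of miRNA i in sample j is
#' `abundance_i * lib_factor_j * 2^(log2_effect * sign_i)` when i is
#' differential and j belongs to the affected group.
#'
#' @param n_mirnas number of miRNAs.
#' @param samples_per_group named integer vector of group sizes.
#' @param baseline_abundances per-miRNA positive means, or `NULL` to draw
#'   log-normal (meanlog 4, sdlog 1.5) at generation time.
#' @param library_size_factors per-sample positive factors, or `NULL` to
#'   draw log-normal (meanlog 0, sdlog 0.25).
#' @param de_fraction proportion of miRNAs that are differential.
#' @param log2_effect log2 fold change magnitude of the spiked set.
#' @param dispersion NB dispersion (>= 0; 0 = Poisson).
#' @param affected_group group receiving the effect (default the second).
#' @param seed integer RNG seed.
#' @return list of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_mirnas = 2000L,
                           samples_per_group = c(acute = 12L, chronic = 18L),
                           baseline_abundances = NULL,
                           library_size_factors = NULL,
                           de_fraction = 0.1, log2_effect = 1.5,
                           dispersion = 0.1,
                           affected_group = names(samples_per_group)[2],
                           seed = 1L) {
  if (!is.null(baseline_abundances) && any(baseline_abundances <= 0)) {
    stop("abundances must be positive", call. = FALSE)
  }
  if (!is.null(library_size_factors) && any(library_size_factors <= 0)) {
    stop("library size factors must be positive", call. = FALSE)
  }
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction in [0,1]", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  structure(list(n_mirnas = as.integer(n_mirnas),
                 samples_per_group = samples_per_group,
                 baseline_abundances = baseline_abundances,
                 library_size_factors = library_size_factors,
                 de_fraction = de_fraction, log2_effect = log2_effect,
                 dispersion = dispersion, affected_group = affected_group,
                 seed = seed),
            class = "count_sim_spec")
}

#' Generate a synthetic miRNA count matrix with truth labels
#'
#' @param spec a [count_sim_spec()].
#' @return list: `counts` (integer matrix, miRNA x sample), `groups`
#'   (per-sample labels), `truth` (data.frame mirna/de/sign),
#'   `lib_factors`, `abundances`.
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_mirnas
    groups <- rep(names(spec$samples_per_group), spec$samples_per_group)
    m <- length(groups)
    ab <- spec$baseline_abundances %||% stats::rlnorm(n, meanlog = 4, sdlog = 1.5)
    if (length(ab) == 1L) ab <- rep(ab, n)
    lf <- spec$library_size_factors %||% stats::rlnorm(m, meanlog = 0, sdlog = 0.25)
    if (length(lf) == 1L) lf <- rep(lf, m)
    n_de <- round(spec$de_fraction * n)
    de <- rep(FALSE, n); de[seq_len(n_de)] <- TRUE
    sign <- integer(n)
    sign[de] <- sample(c(-1L, 1L), n_de, replace = TRUE)
    affected <- groups == spec$affected_group
    mu <- outer(ab, lf)
    if (n_de > 0) {
      shift <- 2^(spec$log2_effect * sign)
      mu[, affected] <- mu[, affected] * shift
    }
    counts <- if (spec$dispersion == 0) {
      matrix(stats::rpois(n * m, mu), n, m)
    } else {
      matrix(stats::rnbinom(n * m, mu = mu, size = 1 / spec$dispersion), n, m)
    }
    rownames(counts) <- sprintf("mir_%04d", seq_len(n))
    colnames(counts) <- sprintf("%s_%02d", groups, stats::ave(seq_len(m), groups,
                                                              FUN = seq_along))
    list(counts = counts, groups = groups,
         truth = data.frame(mirna = rownames(counts), de = de, sign = sign),
         lib_factors = stats::setNames(lf, colnames(counts)),
         abundances = stats::setNames(ab, rownames(counts)))
  })
}

#' CT phantom specification
#'
#' A procedural distal-femur-like phantom: an axis-aligned cylinder with a
#' hemispherical distal cap, a cortical shell above the periosteal density
#' threshold, a marrow interior with a sprinkling of trabecular struts and
#' an exact number of marrow-fat voxels per skeletal region, plus in-field
#' calibration rods whose HU map to their known densities under the true
#' calibration line. Geometry and spacing defaults sit inside the scan
#' protocol's resolution range (in-plane 0.652-0.977 mm, slices
#' 0.625-1.250 mm).
#'
#' @param bone_length_mm,bone_radius_mm,cortical_thickness_mm geometry (mm).
#' @param cortical_density,trabecular_density g/cm^3 of the shell and of
#'   trabecular struts.
#' @param marrow_hu,fat_hu HU of non-fat marrow (outside the fat window)
#'   and of fat voxels (inside -205..-50).
#' @param trabecular_fraction fraction of non-fat interior voxels set to
#'   `trabecular_density` struts.
#' @param n_fat_voxels_per_region named integer vector
#'   (epiphysis/metaphysis/diaphysis).
#' @param voxel_spacing_mm length-3 spacing (in-plane, in-plane, slice).
#' @param calibration_slope,calibration_intercept the true HU -> g/cm^3 line.
#' @param rod_densities calibration rod densities (g/cm^3).
#' @param noise_sd_hu additive Gaussian HU noise (0 = noiseless).
#' @param seed integer RNG seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(bone_length_mm = 150, bone_radius_mm = 15,
                         cortical_thickness_mm = 2.5,
                         cortical_density = 1.2, trabecular_density = 0.3,
                         marrow_hu = 30, fat_hu = -120,
                         trabecular_fraction = 0.1,
                         n_fat_voxels_per_region = c(epiphysis = 400L,
                                                     metaphysis = 400L,
                                                     diaphysis = 500L),
                         voxel_spacing_mm = c(0.8, 0.8, 1.0),
                         calibration_slope = 0.001,
                         calibration_intercept = 0,
                         rod_densities = c(0, 0.1, 0.2, 0.4, 0.8),
                         noise_sd_hu = 0, seed = 1L) {
  if (any(voxel_spacing_mm <= 0)) stop("spacing must be positive", call. = FALSE)
  if (fat_hu < -205 || fat_hu > -50) {
    stop("fat_hu must lie inside the marrow-fat window [-205, -50]", call. = FALSE)
  }
  if (marrow_hu >= -205 && marrow_hu <= -50) {
    stop("marrow_hu must lie outside the marrow-fat window", call. = FALSE)
  }
  if (calibration_slope == 0) stop("calibration slope must be nonzero", call. = FALSE)
  structure(list(bone_length_mm = bone_length_mm, bone_radius_mm = bone_radius_mm,
                 cortical_thickness_mm = cortical_thickness_mm,
                 cortical_density = cortical_density,
                 trabecular_density = trabecular_density,
                 marrow_hu = marrow_hu, fat_hu = fat_hu,
                 trabecular_fraction = trabecular_fraction,
                 n_fat_voxels_per_region = n_fat_voxels_per_region,
                 voxel_spacing_mm = voxel_spacing_mm,
                 calibration_slope = calibration_slope,
                 calibration_intercept = calibration_intercept,
                 rod_densities = rod_densities, noise_sd_hu = noise_sd_hu,
                 seed = seed),
            class = "phantom_spec")
}

#' Generate a CT phantom with known ground truth
#'
#' Builds the HU volume described by a [phantom_spec()] and the exact
#' quantities the QCT pipeline should recover: the calibration line, the
#' per-region marrow-fat volume (fat voxel count x voxel volume), and the
#' per-region trabecular BMC integrated over the documented trabecular mask
#' (periosteal solid eroded in-plane by round(3.5 mm / pixel size) pixels).
#' Fat voxels are placed strictly inside that mask with a 2-pixel safety
#' margin so the erosion never touches them, and only within the first 30%
#' of bone length so every fat voxel is attributed to a region.
#'
#' @param spec a [phantom_spec()].
#' @param erosion_mm cortical erosion depth the analysis will use
#'   (default 3.5 mm; the ground-truth trabecular mask depends on it).
#' @return list: `volume` ([ct_volume()]), `descriptor` (rod ROIs +
#'   densities, JSON-serializable), `truth` (calibration, `mat` table,
#'   `bmc` table, `periosteal`/`trabecular` masks, partition).
#' @export
generate_ct_phantom <- function(spec, erosion_mm = 3.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    sx <- spec$voxel_spacing_mm[1]; sy <- spec$voxel_spacing_mm[2]
    sz <- spec$voxel_spacing_mm[3]
    R <- spec$bone_radius_mm; L <- spec$bone_length_mm
    tck <- spec$cortical_thickness_mm
    pad <- 3L
    nxb <- ceiling(2 * R / sx) + 2L * pad
    ny <- ceiling(2 * R / sy) + 2L * pad
    rod_w <- 4L; rod_gap <- 2L
    n_rods <- length(spec$rod_densities)
    nx <- nxb + rod_gap + rod_w + 2L
    if (ny < n_rods * (rod_w + rod_gap)) ny <- n_rods * (rod_w + rod_gap) + 2L * pad
    nz <- ceiling(L / sz) + 2L * pad
    cx <- (nxb + 1) / 2; cy <- (ny + 1) / 2
    z0 <- pad                                    # bone starts after z0 slices

    hu <- array(-1000, c(nx, ny, nz))
    d2hu <- function(d) (d - spec$calibration_intercept) / spec$calibration_slope

    # bone solid and shell, slice by slice (distal cap at low z)
    xs <- (seq_len(nx) - cx) * sx
    ys <- (seq_len(ny) - cy) * sy
    dist2 <- outer(xs^2, ys^2, "+")
    solid <- array(FALSE, c(nx, ny, nz))
    for (z in seq_len(nz)) {
      zmm <- (z - z0 - 0.5) * sz
      if (zmm < 0 || zmm > L) next
      r_out <- if (zmm >= R) R else sqrt(max(0, R^2 - (R - zmm)^2))
      r_in <- if (zmm >= R) R - tck else sqrt(max(0, (R - tck)^2 - (R - zmm)^2))
      if (r_out <= 0) next
      sl_solid <- dist2 <= r_out^2
      sl_inner <- dist2 <= r_in^2
      solid[, , z] <- sl_solid
      sl <- hu[, , z]
      sl[sl_solid] <- d2hu(spec$cortical_density)
      sl[sl_inner] <- spec$marrow_hu
      hu[, , z] <- sl
    }
    interior <- solid & hu == spec$marrow_hu

    # calibration rods: boxes alongside the bone, spanning most of z
    rod_rois <- vector("list", n_rods)
    for (k in seq_len(n_rods)) {
      x1 <- nxb + rod_gap + 1L; x2 <- x1 + rod_w - 1L
      y1 <- pad + (k - 1L) * (rod_w + rod_gap) + 1L; y2 <- y1 + rod_w - 1L
      hu[x1:x2, y1:y2, (z0 + 1L):(nz - pad)] <- d2hu(spec$rod_densities[k])
      rod_rois[[k]] <- list(c(x1, x2), c(y1, y2), c(z0 + 1L, nz - pad))
    }

    vol <- ct_volume(hu, spec$voxel_spacing_mm, long_axis = 3L, distal_first = TRUE)

    # ground-truth masks and partition (the documented mask definitions)
    r_px <- as.integer(round_half_away(erosion_mm / sx))
    trab <- erode_disk(solid, r_px)
    part <- partition_regions(solid, vol)
    eligible <- erode_disk(solid, r_px + 2L) & interior

    vox_cm3 <- sx * sy * sz / 1000
    fat_idx <- integer(0)
    regions <- c("epiphysis", "metaphysis", "diaphysis")
    for (r in regions) {
      want <- spec$n_fat_voxels_per_region[[r]]
      sl <- part[[r]]
      zidx <- slice.index(eligible, 3)
      cand <- which(as.vector(eligible) & (as.vector(zidx) %in% sl))
      if (want > length(cand)) {
        stop(sprintf("validation error: %d fat voxels requested in %s but only %d fit",
                     want, r, length(cand)), call. = FALSE)
      }
      fat_idx <- c(fat_idx, sample(cand, want))
    }
    hu[fat_idx] <- spec$fat_hu

    # trabecular struts among the remaining interior voxels
    strut_pool <- setdiff(which(interior), fat_idx)
    n_strut <- round(spec$trabecular_fraction * length(strut_pool))
    if (n_strut > 0) {
      strut_idx <- sample(strut_pool, n_strut)
      hu[strut_idx] <- d2hu(spec$trabecular_density)
    }

    # truth computed on the noiseless volume
    dens <- spec$calibration_slope * hu + spec$calibration_intercept
    bmc <- vapply(regions, function(r) {
      sl <- part[[r]]
      sum(dens[, , sl, drop = FALSE][trab[, , sl, drop = FALSE]]) * vox_cm3
    }, numeric(1))
    mat_tab <- data.frame(region = regions,
                          voxels = as.integer(spec$n_fat_voxels_per_region[regions]),
                          volume_cm3 = spec$n_fat_voxels_per_region[regions] * vox_cm3,
                          row.names = NULL)
    bmc_tab <- data.frame(region = c(regions, "total"), bmc_g = c(bmc, sum(bmc)),
                          row.names = NULL)

    if (spec$noise_sd_hu > 0) {
      hu <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sd_hu), dim(hu))
    }
    vol <- ct_volume(hu, spec$voxel_spacing_mm, long_axis = 3L, distal_first = TRUE)

    list(volume = vol,
         descriptor = list(rod_rois = rod_rois,
                           rod_densities = spec$rod_densities),
         truth = list(calibration = list(slope = spec$calibration_slope,
                                         intercept = spec$calibration_intercept),
                      mat = mat_tab, bmc = bmc_tab,
                      periosteal = solid, trabecular = trab,
                      partition = part, fat_indices = fat_idx,
                      erosion_px = r_px))
  })
}

#' Write a phantom to NIfTI plus JSON sidecar
#'
#' @param phantom a [generate_ct_phantom()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nii <- file.path(dir, "phantom.nii.gz")
  js <- file.path(dir, "phantom.json")
  write_ct_nifti(phantom$volume, nii)
  side <- list(spacing_mm = phantom$volume$spacing_mm,
               rod_rois = phantom$descriptor$rod_rois,
               rod_densities = phantom$descriptor$rod_densities,
               truth = list(calibration = phantom$truth$calibration,
                            mat = phantom$truth$mat, bmc = phantom$truth$bmc))
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA)
  invisible(c(nii, js))
}

# ---- hairpin candidate generator ---------------------------------------

# assemble a dot-bracket hairpin from stem segments and internal loops:
# pair_runs[i] consecutive pairs, separated by unpaired runs of gap5[i] /
# gap3[i] nucleotides on the 5' / 3' strand
make_hairpin_structure <- function(pair_runs, gap5 = integer(0), gap3 = integer(0),
                                   loop_len = 10L, dangle5 = 0L, dangle3 = 0L) {
  k <- length(pair_runs)
  stopifnot(length(gap5) == k - 1 || k == 1, length(gap3) == length(gap5))
  left <- strrep(".", dangle5)
  for (i in seq_len(k)) {
    left <- paste0(left, strrep("(", pair_runs[i]),
                   if (i < k) strrep(".", gap5[i]) else "")
  }
  right <- ""
  for (i in rev(seq_len(k))) {
    right <- paste0(right, strrep(")", pair_runs[i]),
                    if (i > 1) strrep(".", gap3[i - 1]) else "")
  }
  paste0(left, strrep(".", loop_len), right, strrep(".", dangle3))
}

# random sequence consistent with a structure: paired partners complementary
sequence_for_structure <- function(structure) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  n <- nchar(structure)
  pair <- parse_hairpin(structure)$pair
  seq <- sample(names(comp), n, replace = TRUE)
  opens <- which(strsplit(structure, "")[[1]] == "(")
  seq[pair[opens]] <- comp[seq[opens]]
  paste(seq, collapse = "")
}

#' Hairpin candidate simulation specification
#'
#' @param n_candidates number of candidates to generate (> 0).
#' @param valid_fraction proportion passing all eleven structural criteria;
#'   the remainder each violate exactly one criterion, cycling through the
#'   eleven violation constructions.
#' @param seed integer RNG seed.
#' @return list of class `hairpin_sim_spec`.
#' @export
hairpin_sim_spec <- function(n_candidates = 100L, valid_fraction = 0.5, seed = 1L) {
  if (n_candidates <= 0) stop("n_candidates must be positive", call. = FALSE)
  if (valid_fraction < 0 || valid_fraction > 1) {
    stop("valid_fraction in [0, 1]", call. = FALSE)
  }
  structure(list(n_candidates = as.integer(n_candidates),
                 valid_fraction = valid_fraction, seed = seed),
            class = "hairpin_sim_spec")
}

# each builder returns list(structure, mature_start, mature_end, energy)
# violating exactly the named criterion at the default thresholds
hairpin_violation_builders <- list(
  stem_bulge_nt = function() list(
    structure = make_hairpin_structure(c(25L, 5L), gap5 = 13L, gap3 = 13L),
    mature = c(1L, 22L), energy = -30),
  stem_base_pairs = function() list(
    structure = make_hairpin_structure(15L, loop_len = 20L),
    mature = c(1L, 18L), energy = -30),
  free_energy = function() list(
    structure = make_hairpin_structure(30L),
    mature = c(1L, 22L), energy = -14),
  hairpin_length = function() list(
    structure = make_hairpin_structure(16L),
    mature = c(1L, 18L), energy = -30),
  loop_length = function() list(
    structure = make_hairpin_structure(30L, loop_len = 21L),
    mature = c(1L, 22L), energy = -30),
  mature_bulge_nt = function() list(
    structure = make_hairpin_structure(c(14L, 13L), gap5 = 9L, gap3 = 5L),
    mature = c(19L, 36L), energy = -30),
  mature_biased_errors = function() list(
    structure = make_hairpin_structure(c(10L, 14L), gap5 = 6L, gap3 = 1L),
    mature = c(5L, 28L), energy = -30),
  mature_biased_bulges = function() list(
    structure = make_hairpin_structure(c(6L, 6L, 6L, 10L),
                                       gap5 = c(2L, 2L, 2L), gap3 = c(1L, 1L, 1L)),
    mature = c(1L, 26L), energy = -30),
  mature_errors = function() list(
    structure = make_hairpin_structure(c(8L, 8L, 10L),
                                       gap5 = c(4L, 4L), gap3 = c(4L, 4L)),
    mature = c(1L, 26L), energy = -30),
  mature_base_pairs = function() list(
    structure = make_hairpin_structure(c(6L, 12L), gap5 = 7L, gap3 = 7L),
    mature = c(1L, 18L), energy = -30),
  percent_mature_in_stem = function() list(
    structure = make_hairpin_structure(30L, dangle5 = 5L),
    mature = c(1L, 22L), energy = -30)
)

#' Generate hairpin candidates with known pass/fail labels
#'
#' Valid candidates are perfect or near-perfect stems (randomized stem
#' length 20-35 bp, loop 4-15 nt, free energy -35 to -18 kcal/mol, a 22-nt
#' fully paired mature arm) that satisfy all eleven criteria by
#' construction. Invalid candidates cycle through eleven constructions,
#' each engineered to violate exactly one named criterion.
#'
#' @param spec a [hairpin_sim_spec()].
#' @return list: `candidates` (list of [hairpin_candidate()]), `truth`
#'   (data.frame id/valid/violates).
#' @export
generate_hairpins <- function(spec) {
  stopifnot(inherits(spec, "hairpin_sim_spec"))
  with_seed(spec$seed, {
    n_valid <- round(spec$valid_fraction * spec$n_candidates)
    cands <- vector("list", spec$n_candidates)
    truth <- data.frame(id = character(spec$n_candidates),
                        valid = logical(spec$n_candidates),
                        violates = NA_character_, stringsAsFactors = FALSE)
    viol_names <- names(hairpin_violation_builders)
    for (i in seq_len(spec$n_candidates)) {
      id <- sprintf("cand_%04d", i)
      if (i <= n_valid) {
        # stem >= 23 bp: the 22-nt mature arm stays fully paired and the
        # hairpin length 2p + loop clears the 50-nt minimum for any loop
        p <- sample(23:35, 1); loop <- sample(4:15, 1)
        db <- make_hairpin_structure(p, loop_len = loop)
        en <- stats::runif(1, -35, -18)
        cands[[i]] <- hairpin_candidate(id, sequence_for_structure(db), db,
                                        en, 1L, 22L)
        truth$valid[i] <- TRUE
      } else {
        v <- viol_names[((i - n_valid - 1L) %% length(viol_names)) + 1L]
        b <- hairpin_violation_builders[[v]]()
        cands[[i]] <- hairpin_candidate(id, sequence_for_structure(b$structure),
                                        b$structure, b$energy,
                                        b$mature[1], b$mature[2])
        truth$violates[i] <- v
      }
      truth$id[i] <- id
    }
    list(candidates = cands, truth = truth)
  })
}

#' Write a cohort table to CSV
#' @param cohort data.frame from [generate_cohort()].
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
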