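#' Simulation configuration for synthetic Halo-FISH acquisitions
#'
#' Describes the virtual microscope and camera used by [render_stack()]. The
#' acquisition geometry follows the assay's imaging protocol: 40 z-planes at
#' 0.2 um spacing, 12-bit grayscale widefield images, one deproteinized
#' nucleus centered per field. The xy pixel pitch and the Gaussian PSF widths
#' are package defaults (a 40x widefield setup); both are configurable.
#'
#' @param field_size_voxels integer (z, y, x) voxel counts of the field.
#' @param voxel_size_um numeric (z, y, x) voxel spacing in micrometres.
#' @param bit_depth camera bit depth; one of 8, 12, 16.
#' @param psf_sigma_um Gaussian PSF sigma (z, y, x) in micrometres.
#' @param photons_per_bp expected photons contributed per base pair of
#'   hybridized probe target (sets the intensity-to-length scale).
#' @param background_level mean background photons per voxel per channel.
#' @param read_noise_sd Gaussian camera read noise SD, ADU.
#' @param camera_offset camera offset (bias) added to every voxel, ADU.
#' @param dapi_core_level expected DAPI photons per voxel inside the nuclear
#'   core (the core is rendered as a bright solid body).
#' @param dapi_halo_level faint DAPI level in the Halo, photons per voxel.
#' @param cen_target_bp effective hybridization target per centromere focus,
#'   in base pairs, controlling centromere focus brightness.
#' @param saturation_warn_frac warn when this fraction of voxels saturates.
#' @param rng_seed optional seed used by rendering when set.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(field_size_voxels = c(z = 40L, y = 160L, x = 160L),
                       voxel_size_um = c(z = 0.2, y = 0.16, x = 0.16),
                       bit_depth = 12L,
                       psf_sigma_um = c(z = 0.35, y = 0.12, x = 0.12),
                       photons_per_bp = 1.0,
                       background_level = 10,
                       read_noise_sd = 2,
                       camera_offset = 100,
                       dapi_core_level = 2000,
                       dapi_halo_level = 3,
                       cen_target_bp = 5000,
                       saturation_warn_frac = 0.01,
                       rng_seed = NULL) {
  field_size_voxels <- as.integer(field_size_voxels)
  if (length(field_size_voxels) != 3L || any(field_size_voxels <= 0L))
    stop("field_size_voxels must be three positive counts (z, y, x)")
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("voxel_size_um must be three positive spacings (z, y, x)")
  if (!bit_depth %in% c(8L, 12L, 16L))
    stop("bit_depth must be one of 8, 12, 16")
  if (length(psf_sigma_um) != 3L || any(psf_sigma_um <= 0))
    stop("psf_sigma_um must be three positive sigmas (z, y, x)")
  stopifnot_scalar(photons_per_bp, "photons_per_bp")
  stopifnot_scalar(background_level, "background_level", positive = FALSE)
  stopifnot_scalar(read_noise_sd, "read_noise_sd", positive = FALSE)
  if (background_level < 0 || read_noise_sd < 0)
    stop("noise levels must be >= 0")
  cfg <- list(
    field_size_voxels = setNames(field_size_voxels, c("z", "y", "x")),
    voxel_size_um = setNames(as.numeric(voxel_size_um), c("z", "y", "x")),
    bit_depth = as.integer(bit_depth),
    psf_sigma_um = setNames(as.numeric(psf_sigma_um), c("z", "y", "x")),
    photons_per_bp = photons_per_bp,
    background_level = background_level,
    read_noise_sd = read_noise_sd,
    camera_offset = camera_offset,
    dapi_core_level = dapi_core_level,
    dapi_halo_level = dapi_halo_level,
    cen_target_bp = cen_target_bp,
    saturation_warn_frac = saturation_warn_frac,
    rng_seed = rng_seed
  )
  structure(cfg, class = "sim_config")
}

#' Field extent of a simulation configuration, in micrometres
#' @param config a [sim_config()].
#' @return Named numeric (z, y, x) extent in um.
#' @export
field_extent_um <- function(config) {
  config$field_size_voxels * config$voxel_size_um
}

#' Cell-line presets for the ECTR DNA generator
#'
#' Each preset parameterizes the per-nucleus ECTR molecule population of one
#' cell line: over-dispersed (negative binomial) per-strand molecule counts,
#' log-normal molecule lengths, the expected G-over-C number bias, and the
#' chromosomal context (diploid karyotype, telomere length distribution).
#' Count means for the ALT lines follow the reported per-nucleus averages
#' (GM847 126/95, VA13 59/44, U2OS 21/14 G/C-strand molecules); the log-normal
#' sigma reproduces the strong positive length skew (mean 2-2.5x the median),
#' and U2OS molecules are on average longer. `WI38` is a primary-fibroblast
#' control with fewer than 5 molecules per nucleus.
#'
#' @param name preset name; one of the packaged names, see [alt_presets()].
#' @param ectr_count_mean_G,ectr_count_mean_C mean ECTR molecules per nucleus.
#' @param ectr_count_dispersion negative-binomial size (smaller = more
#'   over-dispersed).
#' @param length_logmean,length_logsd log-normal parameters of molecule
#'   length in bp.
#' @param g_strand_number_bias expected fraction of nuclei with more G- than
#'   C-strand molecules (descriptive; emergent from the count model).
#' @param chromosome_count diploid chromosome number (2N), even.
#' @param telomere_length_mean_bp,telomere_length_sd_bp normal parameters of
#'   chromosomal telomere length (truncated at 500 bp).
#' @param g2_count_fold fold increase of the ECTR count rate in G2 relative
#'   to G1 (S phase uses the midpoint).
#' @param g2_length_fold fold increase of the median ECTR length in G2.
#' @return An object of class `cell_line_preset`.
#' @export
cell_line_preset <- function(name,
                             ectr_count_mean_G,
                             ectr_count_mean_C,
                             ectr_count_dispersion = 2,
                             length_logmean = log(12000),
                             length_logsd = 1.25,
                             g_strand_number_bias = 0.5,
                             chromosome_count = 46L,
                             telomere_length_mean_bp = 15000,
                             telomere_length_sd_bp = 6000,
                             g2_count_fold = 3.5,
                             g2_length_fold = 1.226) {
  vals <- c(ectr_count_mean_G, ectr_count_mean_C, ectr_count_dispersion,
            length_logmean, length_logsd, g_strand_number_bias,
            chromosome_count, telomere_length_mean_bp, telomere_length_sd_bp,
            g2_count_fold, g2_length_fold)
  if (any(!is.finite(vals)))
    stop("preset parameters must all be finite")
  if (ectr_count_mean_G < 0 || ectr_count_mean_C < 0)
    stop("count means must be >= 0")
  if (ectr_count_dispersion <= 0) stop("ectr_count_dispersion must be > 0")
  if (g_strand_number_bias < 0 || g_strand_number_bias > 1)
    stop("g_strand_number_bias must be in [0, 1]")
  chromosome_count <- as.integer(chromosome_count)
  if (chromosome_count < 2L || chromosome_count %% 2L != 0L)
    stop("chromosome_count must be even and >= 2")
  structure(list(
    name = name,
    ectr_count_mean_G = ectr_count_mean_G,
    ectr_count_mean_C = ectr_count_mean_C,
    ectr_count_dispersion = ectr_count_dispersion,
    length_logmean = length_logmean,
    length_logsd = length_logsd,
    g_strand_number_bias = g_strand_number_bias,
    chromosome_count = chromosome_count,
    telomere_length_mean_bp = telomere_length_mean_bp,
    telomere_length_sd_bp = telomere_length_sd_bp,
    g2_count_fold = g2_count_fold,
    g2_length_fold = g2_length_fold
  ), class = "cell_line_preset")
}

#' Packaged ALT cell-line presets
#' @return Named list of `cell_line_preset` objects (GM847, VA13, U2OS).
#' @export
alt_presets <- function() {
  list(
    GM847 = cell_line_preset("GM847", 126, 95,
                             length_logmean = log(12000),
                             g_strand_number_bias = 0.90),
    VA13 = cell_line_preset("VA13", 59, 44,
                            length_logmean = log(12000),
                            g_strand_number_bias = 0.617),
    U2OS = cell_line_preset("U2OS", 21, 14,
                            length_logmean = log(43000),
                            g_strand_number_bias = 0.823)
  )
}

#' Look up a packaged preset by name
#' @param name one of "GM847", "VA13", "U2OS", "WI38".
#' @return A `cell_line_preset`.
#' @export
get_preset <- function(name) {
  presets <- c(alt_presets(), list(
    WI38 = cell_line_preset("WI38", 2, 1.5,
                            ectr_count_dispersion = 1,
                            length_logmean = log(8000),
                            length_logsd = 1.0)
  ))
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s'; packaged presets: %s", name,
                 paste(names(presets), collapse = ", ")))
  presets[[name]]
}

#' Sample per-nucleus ECTR molecule populations
#'
#' Per nucleus, the total molecule count is drawn negative-binomially with
#' mean `ectr_count_mean_G + ectr_count_mean_C` (scaled by the cell-cycle
#' fold for S/G2 nuclei) and each molecule is independently assigned the
#' G strand with probability `mean_G / (mean_G + mean_C)`. Molecule lengths
#' are log-normal.
#'
#' @param preset a [cell_line_preset()].
#' @param n_nuclei number of nuclei to sample (>= 1).
#' @param seed optional RNG seed.
#' @param phase cell-cycle phase(s), "G1", "S" or "G2"; recycled to
#'   `n_nuclei`. Affects the count rate and length scale via the preset's
#'   `g2_*_fold` parameters.
#' @return A list of length `n_nuclei`; each element a data.frame with
#'   columns `strand` ("G"/"C") and `repeat_length_bp`.
#' @export
sample_ectr_population <- function(preset, n_nuclei, seed = NULL,
                                   phase = "G1") {
  stopifnot(inherits(preset, "cell_line_preset"))
  if (!is.numeric(n_nuclei) || n_nuclei < 1)
    stop("n_nuclei must be >= 1")
  n_nuclei <- as.integer(n_nuclei)
  phase <- match.arg(phase, c("G1", "S", "G2"), several.ok = TRUE)
  phase <- rep(phase, length.out = n_nuclei)
  with_seed(seed, {
    lapply(seq_len(n_nuclei), function(i) {
      cf <- switch(phase[i], G1 = 1,
                   S = (1 + preset$g2_count_fold) / 2,
                   G2 = preset$g2_count_fold)
      lf <- switch(phase[i], G1 = 1,
                   S = (1 + preset$g2_length_fold) / 2,
                   G2 = preset$g2_length_fold)
      mu <- (preset$ectr_count_mean_G + preset$ectr_count_mean_C) * cf
      if (mu <= 0) {
        return(data.frame(strand = character(0),
                          repeat_length_bp = numeric(0)))
      }
      n <- rnbinom(1, size = preset$ectr_count_dispersion, mu = mu)
      p_g <- preset$ectr_count_mean_G /
        (preset$ectr_count_mean_G + preset$ectr_count_mean_C)
      strand <- ifelse(runif(n) < p_g, "G", "C")
      len <- rlnorm(n, meanlog = preset$length_logmean + log(lf),
                    sdlog = preset$length_logsd)
      data.frame(strand = strand, repeat_length_bp = len)
    })
  })
}

#' Build the ground truth of one simulated deproteinized nucleus
#'
#' The nuclear core is modeled as an oblate spheroid centered in the field:
#' lysis and deproteinization swell the nucleoid laterally (the default is
#' 14 um across) while the thin agarose layer keeps it flat axially.
#' Chromosomal telomeres (2 per chromosome, duplex, so they appear in both
#' telomere channels) and centromeres (1 per chromosome) are placed uniformly
#' inside the core; G2 doubles and S multiplies both by 1.5. ECTR molecules
#' are placed in the Halo: the xy distance from the core edge is a fixed
#' standoff plus a half-normal draw, and z is uniform about the core plane.
#'
#' @param preset a [cell_line_preset()].
#' @param ectr_molecules data.frame with `strand`, `repeat_length_bp` (one
#'   element of [sample_ectr_population()]).
#' @param cell_cycle_phase "G1", "S" or "G2".
#' @param config a [sim_config()] (the field the geometry must fit).
#' @param seed optional RNG seed.
#' @param nucleus_id identifier stored in the truth record.
#' @param core_radius_um core xy semi-axis, um.
#' @param core_z_semiaxis_um core z semi-axis, um.
#' @param halo_standoff_um minimum xy distance of Halo molecules from the
#'   core edge (diffusion clears a gap between core and Halo foci).
#' @param halo_scale_um half-normal scale of the Halo radial profile, um.
#' @param halo_z_um Halo molecules are placed within +/- this z range of the
#'   core plane, um.
#' @param border_margin_um minimum distance from the field border, um.
#' @param max_retries placement retries per molecule before erroring.
#' @return An object of class `ground_truth`.
#' @export
build_nucleus_truth <- function(preset, ectr_molecules,
                                cell_cycle_phase = c("G1", "S", "G2"),
                                config = sim_config(), seed = NULL,
                                nucleus_id = 1L,
                                core_radius_um = 7,
                                core_z_semiaxis_um = 2.0,
                                halo_standoff_um = 0.8,
                                halo_scale_um = 2.0,
                                halo_z_um = 2.0,
                                border_margin_um = 0.5,
                                max_retries = 200L) {
  stopifnot(inherits(preset, "cell_line_preset"))
  cell_cycle_phase <- match.arg(cell_cycle_phase)
  ext <- field_extent_um(config)
  center <- ext / 2
  if (core_radius_um > 0 &&
      (2 * core_radius_um >= min(ext["y"], ext["x"]) ||
       2 * core_z_semiaxis_um > ext["z"]))
    stop("core geometry does not fit the field of view")

  phase_factor <- switch(cell_cycle_phase, G1 = 1, S = 1.5, G2 = 2)

  with_seed(seed, {
    n_cen <- as.integer(round(preset$chromosome_count * phase_factor))
    n_tel <- as.integer(round(2 * preset$chromosome_count * phase_factor))

    cen_pos <- sample_in_spheroid(n_cen, center, core_radius_um,
                                  core_z_semiaxis_um)
    tel_pos <- sample_in_spheroid(n_tel, center, core_radius_um,
                                  core_z_semiaxis_um)
    tel_len <- pmax(rnorm(n_tel, preset$telomere_length_mean_bp,
                          preset$telomere_length_sd_bp), 500)
    core_mol <- data.frame(
      strand = rep("duplex", n_tel),
      repeat_length_bp = tel_len,
      z_um = tel_pos[, 1], y_um = tel_pos[, 2], x_um = tel_pos[, 3],
      compartment_truth = rep("core", n_tel)
    )

    n_ectr <- nrow(ectr_molecules)
    halo_mol <- NULL
    if (n_ectr > 0) {
      pos <- matrix(NA_real_, n_ectr, 3)
      for (i in seq_len(n_ectr)) {
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          theta <- runif(1, 0, 2 * pi)
          r <- core_radius_um + halo_standoff_um +
            abs(rnorm(1, 0, halo_scale_um))
          y <- center["y"] + r * sin(theta)
          x <- center["x"] + r * cos(theta)
          z <- center["z"] + runif(1, -halo_z_um, halo_z_um)
          if (y > border_margin_um && y < ext["y"] - border_margin_um &&
              x > border_margin_um && x < ext["x"] - border_margin_um &&
              z > border_margin_um && z < ext["z"] - border_margin_um) {
            pos[i, ] <- c(z, y, x)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place Halo molecule inside the field of view")
      }
      halo_mol <- data.frame(
        strand = ectr_molecules$strand,
        repeat_length_bp = ectr_molecules$repeat_length_bp,
        z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
        compartment_truth = rep("halo", n_ectr)
      )
    }

    molecules <- rbind(core_mol, halo_mol)
    rownames(molecules) <- NULL

    structure(list(
      nucleus_id = nucleus_id,
      preset_name = preset$name,
      core_center_um = setNames(as.numeric(center), c("z", "y", "x")),
      core_radius_um = core_radius_um,
      core_z_semiaxis_um = core_z_semiaxis_um,
      molecules = molecules,
      centromere_positions_um = data.frame(
        z_um = cen_pos[, 1], y_um = cen_pos[, 2], x_um = cen_pos[, 3]),
      cell_cycle_truth = cell_cycle_phase
    ), class = "ground_truth")
  })
}

# uniform sample inside an axis-aligned spheroid with z semi-axis rz and
# xy semi-axis rxy; returns matrix (z, y, x) in um
sample_in_spheroid <- function(n, center, rxy, rz) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  u <- runif(n)^(1 / 3)
  pts <- v * u
  cbind(center["z"] + pts[, 1] * rz,
        center["y"] + pts[, 2] * rxy,
        center["x"] + pts[, 3] * rxy)
}

#' Render a ground-truth nucleus into a 4-channel image stack
#'
#' Each molecule contributes an expected photon count of
#' `photons_per_bp * repeat_length_bp`, spread by the separable Gaussian PSF
#' (voxel masses are exact Gaussian integrals, so total expected flux is
#' conserved to well under 0.1% for molecules away from the border). Duplex
#' molecules emit in both telomere channels at full flux. The DAPI channel
#' renders the core as a bright solid spheroid plus a faint Halo level.
#' With `noise = TRUE`, Poisson shot noise, Gaussian read noise, the camera
#' offset, rounding and clipping to the camera bit depth are applied; with
#' `noise = FALSE` the expected image plus offset is returned unquantized.
#'
#' @param truth a [build_nucleus_truth()] or calibration-slide truth.
#' @param config a [sim_config()].
#' @param noise logical; apply the full camera noise model.
#' @param seed optional RNG seed (defaults to `config$rng_seed`).
#' @return An object of class `halo_stack`: a list with `voxels` (z, y, x,
#'   channel array in ADU), `voxel_size_um`, `bit_depth`, `channel_names`,
#'   `camera_offset`.
#' @export
render_stack <- function(truth, config = sim_config(), noise = TRUE,
                         seed = config$rng_seed) {
  stopifnot(inherits(truth, "ground_truth"))
  nzyx <- config$field_size_voxels
  vox <- config$voxel_size_um
  ext <- field_extent_um(config)
  mol <- truth$molecules
  if (nrow(mol) > 0) {
    inside <- mol$z_um >= 0 & mol$z_um <= ext["z"] &
      mol$y_um >= 0 & mol$y_um <= ext["y"] &
      mol$x_um >= 0 & mol$x_um <= ext["x"]
    if (!all(inside)) stop("truth positions outside the field of view")
  }

  dims <- unname(nzyx)
  expected <- array(0, dim = c(dims, 4L),
                    dimnames = list(NULL, NULL, NULL, HALO_CHANNELS))

  # DAPI: solid core spheroid + faint halo, blurred by the PSF
  dapi <- array(config$dapi_halo_level, dim = dims)
  if (truth$core_radius_um > 0) {
    cz <- truth$core_center_um["z"]
    cy <- truth$core_center_um["y"]
    cx <- truth$core_center_um["x"]
    zc <- (seq_len(dims[1]) - 0.5) * vox["z"]
    yc <- (seq_len(dims[2]) - 0.5) * vox["y"]
    xc <- (seq_len(dims[3]) - 0.5) * vox["x"]
    dz2 <- ((zc - cz) / truth$core_z_semiaxis_um)^2
    dy2 <- ((yc - cy) / truth$core_radius_um)^2
    dx2 <- ((xc - cx) / truth$core_radius_um)^2
    inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
    dapi[inside] <- config$dapi_core_level
    dapi <- gaussian_smooth(dapi, config$psf_sigma_um / vox)
  }
  expected[, , , "DAPI"] <- dapi

  sigma_px <- config$psf_sigma_um / vox

  add_molecules <- function(channel, pos_um, photons) {
    arr <- expected[, , , channel]
    for (i in seq_along(photons)) {
      arr <- add_gaussian_blob(arr, pos_um[i, ] / vox, sigma_px, photons[i])
    }
    expected[, , , channel] <<- arr
  }

  cen <- truth$centromere_positions_um
  if (nrow(cen) > 0) {
    add_molecules("CEN", as.matrix(cen[, c("z_um", "y_um", "x_um")]),
                  rep(config$photons_per_bp * config$cen_target_bp,
                      nrow(cen)))
  }
  if (nrow(mol) > 0) {
    pos <- as.matrix(mol[, c("z_um", "y_um", "x_um")])
    ph <- config$photons_per_bp * mol$repeat_length_bp
    for (ch in c("TelC", "TelG")) {
      sel <- mol$strand == "duplex" | mol$strand == (if (ch == "TelG") "G" else "C")
      if (any(sel)) add_molecules(ch, pos[sel, , drop = FALSE], ph[sel])
    }
  }

  expected <- expected + config$background_level
  maxval <- 2^config$bit_depth - 1

  if (noise) {
    voxels <- with_seed(seed, {
      counts <- rpois(length(expected), lambda = expected)
      counts <- counts + rnorm(length(counts), 0, config$read_noise_sd)
      round(counts) + config$camera_offset
    })
    voxels <- pmin(pmax(voxels, 0), maxval)
  } else {
    voxels <- pmin(expected + config$camera_offset, maxval)
  }
  dim(voxels) <- c(dims, 4L)
  dimnames(voxels) <- list(NULL, NULL, NULL, HALO_CHANNELS)

  sat <- mean(voxels >= maxval)
  if (sat > config$saturation_warn_frac)
    warning(sprintf("%.1f%% of voxels saturated at %d ADU", 100 * sat,
                    maxval))

  structure(list(
    voxels = voxels,
    voxel_size_um = vox,
    bit_depth = config$bit_depth,
    channel_names = HALO_CHANNELS,
    camera_offset = config$camera_offset
  ), class = "halo_stack")
}

# add an anisotropic Gaussian point source at voxel-unit position `pos_px`
# (z, y, x; continuous, voxel centers at i - 0.5) with total flux `photons`.
# Voxel masses are Gaussian integrals over voxel extents (pnorm differences),
# computed on a +/- 5 sigma window, so flux is conserved to < 1e-5.
add_gaussian_blob <- function(arr, pos_px, sigma_px, photons) {
  d <- dim(arr)
  axes <- vector("list", 3)
  for (a in 1:3) {
    half <- max(1L, ceiling(5 * sigma_px[a]))
    ctr <- pos_px[a] + 0.5  # voxel i covers [i-1, i]
    lo <- max(1L, floor(ctr - half))
    hi <- min(d[a], ceiling(ctr + half))
    if (lo > hi) return(arr)
    edges <- (lo - 1):hi
    mass <- diff(pnorm(edges, mean = pos_px[a], sd = sigma_px[a]))
    axes[[a]] <- list(idx = lo:hi, mass = mass)
  }
  blob <- photons * outer(outer(axes[[1]]$mass, axes[[2]]$mass), axes[[3]]$mass)
  arr[axes[[1]]$idx, axes[[2]]$idx, axes[[3]]$idx] <-
    arr[axes[[1]]$idx, axes[[2]]$idx, axes[[3]]$idx] + blob
  arr
}

#' Simulate a plasmid calibration slide
#'
#' Isolated duplex plasmid foci of known telomere-repeat insert length are
#' scattered on an empty field (no DAPI core). Each insert repeat is a
#' hexamer, so `repeat_length_bp = 6 * insert_repeats` (135 repeats = 810 bp,
#' 270 repeats = 1620 bp). Being double-stranded, plasmid foci emit in both
#' telomere channels with equal expected flux.
#'
#' @param insert_repeats number of hexameric telomere repeats in the insert.
#' @param n_foci number of foci to place (0 gives a pure-background stack).
#' @param config a [sim_config()].
#' @param seed optional RNG seed.
#' @param min_separation_um minimum pairwise focus distance.
#' @param border_margin_um placement margin from the xy border.
#' @param noise logical; apply the camera noise model.
#' @return list with elements `stack` (a `halo_stack`) and `truth`
#'   (a `ground_truth` with `core_radius_um = 0`).
#' @export
simulate_calibration_slide <- function(insert_repeats, n_foci,
                                       config = sim_config(), seed = NULL,
                                       min_separation_um = 1.5,
                                       border_margin_um = 1.0,
                                       noise = TRUE) {
  if (!is.numeric(insert_repeats) || insert_repeats <= 0)
    stop("insert_repeats must be > 0")
  if (n_foci < 0) stop("n_foci must be >= 0")
  ext <- field_extent_um(config)
  bp <- 6 * insert_repeats

  truth <- with_seed(seed, {
    pos <- matrix(numeric(0), 0, 3)
    consecutive_misses <- 0L
    while (nrow(pos) < n_foci) {
      if (consecutive_misses >= 2000L)
        stop("could not place calibration foci without overlap; ",
             "reduce n_foci or min_separation_um")
      zlo <- max(border_margin_um, ext["z"] / 2 - 2.5)
      zhi <- min(ext["z"] - border_margin_um, ext["z"] / 2 + 2.5)
      cand <- c(
        runif(1, zlo, zhi),
        runif(1, border_margin_um, ext["y"] - border_margin_um),
        runif(1, border_margin_um, ext["x"] - border_margin_um)
      )
      if (nrow(pos) > 0) {
        dd <- sqrt(colSums((t(pos) - cand)^2))
        if (min(dd) < min_separation_um) {
          consecutive_misses <- consecutive_misses + 1L
          next
        }
      }
      consecutive_misses <- 0L
      pos <- rbind(pos, cand)
    }
    molecules <- data.frame(
      strand = rep("duplex", n_foci),
      repeat_length_bp = rep(bp, n_foci),
      z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
      compartment_truth = rep("halo", n_foci)
    )
    structure(list(
      nucleus_id = sprintf("calib_%d", insert_repeats),
      preset_name = sprintf("plasmid_%drep", insert_repeats),
      core_center_um = setNames(as.numeric(ext / 2), c("z", "y", "x")),
      core_radius_um = 0,
      core_z_semiaxis_um = 0,
      molecules = molecules,
      centromere_positions_um = data.frame(z_um = numeric(0),
                                           y_um = numeric(0),
                                           x_um = numeric(0)),
      cell_cycle_truth = NA_character_
    ), class = "ground_truth")
  })

  stack <- render_stack(truth, config, noise = noise,
                        seed = if (is.null(seed)) NULL else seed + 1L)
  list(stack = stack, truth = truth)
}

#' Extract one channel of a stack as a 3D array
#' @param stack a `halo_stack`.
#' @param channel channel name.
#' @return 3D numeric array (z, y, x) in ADU.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "halo_stack"))
  if (!channel %in% stack$channel_names)
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(stack$channel_names, collapse = ", ")))
  arr <- stack$voxels[, , , channel]
  dim(arr) <- dim(stack$voxels)[1:3]
  arr
}

#' @export
print.halo_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Halo-FISH stack: %d z x %d y x %d x voxels, channels: %s\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  voxel size (um): z=%.3g y=%.3g x=%.3g, %d-bit\n",
              x$voxel_size_um["z"], x$voxel_size_um["y"],
              x$voxel_size_um["x"], x$bit_depth))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth '%s' (%s): %d molecules (%d core / %d halo), %d centromeres, phase %s\n",
              x$nucleus_id, x$preset_name, nrow(x$molecules),
              sum(x$molecules$compartment_truth == "core"),
              sum(x$molecules$compartment_truth == "halo"),
              nrow(x$centromere_positions_um),
              x$cell_cycle_truth))
  invisible(x)
}
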