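#' Fit a quantitative-FISH intensity-to-base-pair calibration
#'
#' Converts background-corrected integrated probe intensity into DNA
#' base-pair length using plasmid standards of known telomere-repeat insert
#' length: 135 repeats (810 bp) and optionally 270 repeats (1620 bp). With
#' only the 810-bp standard the slope is `mean(I_810) / 810`; with both
#' standards a zero-intercept least-squares line through the two standard
#' means is used, and the 1620-bp residual is reported as a linearity
#' diagnostic. The mean intensity of the 810-bp standard also defines the
#' minimum detection threshold applied to ECTR calling on slides processed
#' in parallel.
#'
#' @param foci_810 data.frame of detected foci of the 135-repeat standard
#'   (one channel), or a numeric vector of integrated intensities.
#' @param foci_1620 optional; same for the 270-repeat standard.
#' @param channel channel the calibration applies to ("TelG" or "TelC").
#' @param noise_sigma optional focus-scale background noise SD (see
#'   [estimate_noise_sigma()]); enables [detection_limit_bp()].
#' @param bp_810,bp_1620 standard lengths in bp.
#' @param min_foci minimum number of standard foci required.
#' @return An object of class `halo_calibration` with a `channels` list
#'   holding per-channel `slope_intensity_per_bp`, `min_threshold_intensity`,
#'   `standard_stats` and `noise_sigma`. Models for different channels can
#'   be merged with [merge_calibrations()].
#' @export
fit_calibration <- function(foci_810, foci_1620 = NULL, channel = "TelG",
                            noise_sigma = NULL, bp_810 = 810,
                            bp_1620 = 1620, min_foci = 10L) {
  i810 <- intensities_of(foci_810)
  if (length(i810) < min_foci)
    stop(sprintf("need >= %d foci for the 810-bp standard, got %d",
                 min_foci, length(i810)))
  m810 <- mean(i810)
  stats <- data.frame(
    standard_bp = bp_810, n_foci = length(i810), mean_intensity = m810,
    sd_intensity = sd(i810))
  linearity_residual_bp <- NA_real_
  if (is.null(foci_1620)) {
    slope <- m810 / bp_810
  } else {
    i1620 <- intensities_of(foci_1620)
    if (length(i1620) < min_foci)
      stop(sprintf("need >= %d foci for the 1620-bp standard, got %d",
                   min_foci, length(i1620)))
    m1620 <- mean(i1620)
    stats <- rbind(stats, data.frame(
      standard_bp = bp_1620, n_foci = length(i1620),
      mean_intensity = m1620, sd_intensity = sd(i1620)))
    # least squares through the origin on (bp, mean intensity)
    slope <- (bp_810 * m810 + bp_1620 * m1620) / (bp_810^2 + bp_1620^2)
    linearity_residual_bp <- m1620 / slope - bp_1620
  }
  if (!is.finite(slope) || slope <= 0)
    stop("fitted calibration slope is not positive")
  ch <- list(slope_intensity_per_bp = slope,
             min_threshold_intensity = m810,
             standard_stats = stats,
             linearity_residual_bp = linearity_residual_bp,
             noise_sigma = noise_sigma)
  structure(list(channels = setNames(list(ch), channel)),
            class = "halo_calibration")
}

intensities_of <- function(x) {
  if (is.data.frame(x)) {
    if (!is.null(x$border_flag)) x <- x[!x$border_flag, , drop = FALSE]
    return(x$integrated_intensity)
  }
  as.numeric(x)
}

#' Merge per-channel calibration models
#' @param ... `halo_calibration` objects for different channels.
#' @return A single `halo_calibration` covering all channels.
#' @export
merge_calibrations <- function(...) {
  models <- list(...)
  chans <- list()
  for (m in models) {
    stopifnot(inherits(m, "halo_calibration"))
    chans <- c(chans, m$channels)
  }
  if (anyDuplicated(names(chans)))
    stop("duplicate channel in calibration merge")
  structure(list(channels = chans), class = "halo_calibration")
}

#' Convert integrated intensity to base pairs
#' @param intensity numeric vector of background-corrected integrated
#'   intensities, ADU.
#' @param model a `halo_calibration`.
#' @param channel channel whose slope to use.
#' @return Estimated length in bp (non-negative).
#' @export
intensity_to_bp <- function(intensity, model, channel) {
  ch <- calibration_channel(model, channel)
  pmax(intensity / ch$slope_intensity_per_bp, 0)
}

#' Detection limit in base pairs at a given signal-to-noise ratio
#'
#' The shortest molecule whose expected integrated intensity equals
#' `snr * noise_sigma`, where `noise_sigma` is the SD of integrated
#' intensity over focus-sized null apertures in the Halo. This is
#' informational: the operating cut remains the 810-bp plasmid threshold.
#'
#' @param model a `halo_calibration` with `noise_sigma` set.
#' @param snr accepted signal-to-noise ratio (> 0), e.g. 2.
#' @param channel channel whose slope and noise to use.
#' @return Detection limit in bp.
#' @export
detection_limit_bp <- function(model, snr, channel) {
  if (snr <= 0) stop("snr must be > 0")
  ch <- calibration_channel(model, channel)
  if (is.null(ch$noise_sigma))
    stop("noise_sigma has not been estimated for this channel")
  snr * ch$noise_sigma / ch$slope_intensity_per_bp
}

calibration_channel <- function(model, channel) {
  if (!inherits(model, "halo_calibration"))
    stop("model is not a fitted calibration")
  if (!channel %in% names(model$channels))
    stop(sprintf("no calibration for channel '%s'", channel))
  model$channels[[channel]]
}

#' Estimate focus-scale background noise in the Halo
#'
#' Integrates background-corrected intensity over randomly placed
#' focus-sized (ellipsoidal, PSF-scaled) null apertures in the Halo (or the
#' whole field when no compartments are given), avoiding detected foci, and
#' returns the SD of those sums. This is the noise term of the
#' signal-to-noise detection-limit computation.
#'
#' @param stack a `halo_stack`.
#' @param channel channel name.
#' @param compartments optional `compartment_map`; apertures are drawn in
#'   the Halo mask.
#' @param foci optional detected foci to avoid (within 2 um).
#' @param n_apertures number of null apertures.
#' @param params,psf detection parameters (aperture size) and PSF model.
#' @param seed optional RNG seed.
#' @return SD of the null-aperture integrated intensities, ADU.
#' @export
estimate_noise_sigma <- function(stack, channel, compartments = NULL,
                                 foci = NULL, n_apertures = 200L,
                                 params = detect_params(),
                                 psf = psf_model(), seed = NULL) {
  arr <- get_channel(stack, channel)
  d <- dim(arr)
  vox <- stack$voxel_size_um
  bg <- estimate_background(arr)
  x <- as.numeric(arr) - as.numeric(background_field(bg))
  dim(x) <- d
  sigma_px <- psf$sigma_um / vox
  r_px <- pmax(params$aperture_sigma * sigma_px, 1)
  rc <- ceiling(r_px)

  # precompute the ellipsoid offsets once
  zi <- -rc[1]:rc[1]; yi <- -rc[2]:rc[2]; xi <- -rc[3]:rc[3]
  ell <- outer(outer((zi / r_px[1])^2, (yi / r_px[2])^2, `+`),
               (xi / r_px[3])^2, `+`) <= 1

  with_seed(seed, {
    sums <- numeric(0)
    tries <- 0L
    while (length(sums) < n_apertures && tries < 50L * n_apertures) {
      tries <- tries + 1L
      ctr <- c(sample(seq(rc[1] + 1, d[1] - rc[1]), 1),
               sample(seq(rc[2] + 1, d[2] - rc[2]), 1),
               sample(seq(rc[3] + 1, d[3] - rc[3]), 1))
      if (!is.null(compartments) &&
          !compartments$halo_mask[ctr[1], ctr[2], ctr[3]]) next
      if (!is.null(foci) && nrow(foci) > 0) {
        pos <- (ctr - 0.5) * vox
        dd <- sqrt((foci$z_um - pos[1])^2 + (foci$y_um - pos[2])^2 +
                   (foci$x_um - pos[3])^2)
        if (min(dd) < 2) next
      }
      block <- x[(ctr[1] - rc[1]):(ctr[1] + rc[1]),
                 (ctr[2] - rc[2]):(ctr[2] + rc[2]),
                 (ctr[3] - rc[3]):(ctr[3] + rc[3])]
      sums <- c(sums, sum(block[ell]))
    }
    if (length(sums) < 10)
      stop("could not place enough null apertures")
    sd(sums)
  })
}

#' @export
print.halo_calibration <- function(x, ...) {
  for (ch in names(x$channels)) {
    m <- x$channels[[ch]]
    cat(sprintf("%s: slope %.4g ADU/bp, threshold %.4g ADU (mean of 810-bp standard, n = %d)\n",
                ch, m$slope_intensity_per_bp, m$min_threshold_intensity,
                m$standard_stats$n_foci[1]))
    if (!is.null(m$noise_sigma))
      cat(sprintf("  noise sigma %.4g ADU; 2:1 SNR detection limit %.0f bp\n",
                  m$noise_sigma, 2 * m$noise_sigma / m$slope_intensity_per_bp))
  }
  invisible(x)
}

#' Serialize a calibration model to JSON
#' @param model a `halo_calibration`.
#' @param path output file.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "halo_calibration"))
  jsonlite::write_json(model$channels, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a calibration model from JSON
#' @param path JSON file written by [write_calibration()].
#' @return A `halo_calibration`.
#' @export
read_calibration <- function(path) {
  chans <- jsonlite::read_json(path, simplifyVector = TRUE)
  chans <- lapply(chans, function(ch) {
    ch$standard_stats <- as.data.frame(ch$standard_stats)
    ch
  })
  structure(list(channels = chans), class = "halo_calibration")
}
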