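#' Spot-detection parameters
#'
#' @param peak_snr peaks must exceed `peak_snr` robust SDs of the
#'   band-pass (difference-of-Gaussians) response.
#' @param min_peak_response absolute floor on the peak response, ADU; keeps
#'   detection defined on noise-free images where the robust SD is zero.
#' @param aperture_sigma integration aperture radius in units of the PSF
#'   sigma per axis (an ellipsoid; 4.5 sigma captures > 99.9% of a Gaussian
#'   spot's flux).
#' @param dog_ratio sigma ratio of the two Gaussians of the band-pass.
#' @param detect_sigma_scale band-pass scale as a fraction of the PSF sigma;
#'   values below 1 trade a little peak SNR for better splitting of nearby
#'   spots in the crowded nuclear core (the aperture stays PSF-sized).
#' @param nms_sigma non-maximum-suppression radius in PSF sigmas: of two
#'   candidate peaks closer than this the weaker is dropped. Set below the
#'   optical merge distance (~2.4 sigma) it cannot suppress resolvable
#'   pairs, but it removes duplicate maxima on the noise-dithered plateaus
#'   of camera-saturated foci.
#' @param max_foci safety cap on the number of detected foci per channel.
#' @return list of class `detect_params`.
#' @export
detect_params <- function(peak_snr = 7, min_peak_response = 2,
                          aperture_sigma = 4.5, dog_ratio = 1.6,
                          detect_sigma_scale = 0.5, nms_sigma = 2,
                          max_foci = 5000L) {
  stopifnot_scalar(peak_snr, "peak_snr")
  stopifnot_scalar(aperture_sigma, "aperture_sigma")
  stopifnot_scalar(detect_sigma_scale, "detect_sigma_scale")
  structure(list(peak_snr = peak_snr,
                 min_peak_response = min_peak_response,
                 aperture_sigma = aperture_sigma,
                 dog_ratio = dog_ratio,
                 detect_sigma_scale = detect_sigma_scale,
                 nms_sigma = nms_sigma,
                 max_foci = as.integer(max_foci)),
            class = "detect_params")
}

#' Detect 3D foci in one channel
#'
#' Candidate spots are local maxima of a PSF-matched band-pass
#' (difference-of-Gaussians, a Laplacian-of-Gaussian approximation) response
#' exceeding a noise-adaptive cut (robust MAD of the response). Voxels within
#' the union of per-peak ellipsoidal apertures are partitioned among peaks by
#' marker-based watershed on the smoothed intensity, so overlapping spots
#' split their flux while isolated spots keep their full aperture.
#' Integrated intensity is the background-corrected sum over the assigned
#' region (per-plane median background).
#'
#' @param stack a `halo_stack` or 3D array.
#' @param channel channel name ("CEN", "TelC" or "TelG" for stacks).
#' @param compartments optional [segment_nuclear_core()] result; assigns each
#'   focus to "core" or "halo" by its centroid (guard-zone centroids are
#'   scored as core, since they are PSF bleed from core chromatin).
#' @param params a [detect_params()].
#' @param psf a [psf_model()]; sets the band-pass scale and aperture.
#' @param voxel_size_um voxel spacing; taken from the stack when available.
#' @return data.frame with one row per focus: `focus_id`, `channel`,
#'   `z_um`, `y_um`, `x_um`, `voxel_count`, `integrated_intensity`,
#'   `peak_response`, `compartment`, `border_flag`, `estimated_bp`,
#'   `passes_threshold`.
#' @export
detect_foci <- function(stack, channel = NULL, compartments = NULL,
                        params = detect_params(), psf = psf_model(),
                        voxel_size_um = NULL) {
  if (inherits(stack, "halo_stack")) {
    if (is.null(channel)) stop("channel must be given for a stack")
    arr <- get_channel(stack, channel)
    vox <- stack$voxel_size_um
  } else {
    arr <- stack
    vox <- voxel_size_um %||% c(z = 1, y = 1, x = 1)
    channel <- channel %||% "image"
  }
  d <- dim(arr)
  sigma_px <- psf$sigma_um / vox

  bg <- estimate_background(arr)
  bgf <- background_field(bg)
  x <- as.numeric(arr) - as.numeric(bgf)
  dim(x) <- d

  det_px <- sigma_px * params$detect_sigma_scale
  s1 <- gaussian_smooth(x, det_px)
  s2 <- gaussian_smooth(x, det_px * params$dog_ratio)
  resp <- s1 - s2

  noise_sd <- mad(resp, center = 0)
  cut <- max(params$min_peak_response, params$peak_snr * noise_sd)

  mx <- max_filter3_cpp(resp, as.integer(d))
  peak_mask <- (resp == mx) & (resp >= cut)
  if (!any(peak_mask)) return(empty_foci_frame(channel))

  # collapse plateau maxima (adjacent equal-response voxels) to one peak
  plab <- label3d_cpp(peak_mask, as.integer(d), connectivity = 26L)
  npk <- max(plab)
  peak_idx <- integer(npk)
  for (l in seq_len(npk)) {
    vs <- which(plab == l)
    peak_idx[l] <- vs[which.max(resp[vs])]
  }
  # non-maximum suppression: drop the weaker of two peaks closer than
  # nms_sigma PSF widths (duplicate maxima on saturated plateaus)
  if (length(peak_idx) > 1) {
    pkm <- arrayInd(peak_idx, d)
    r_nms <- pmax(params$nms_sigma * sigma_px, 1)
    ord <- order(resp[peak_idx], decreasing = TRUE)
    sel <- integer(0)
    for (i in ord) {
      if (length(sel) > 0) {
        dd <- ((pkm[sel, 1] - pkm[i, 1]) / r_nms[1])^2 +
          ((pkm[sel, 2] - pkm[i, 2]) / r_nms[2])^2 +
          ((pkm[sel, 3] - pkm[i, 3]) / r_nms[3])^2
        if (any(dd < 1)) next
      }
      sel <- c(sel, i)
    }
    peak_idx <- sort(peak_idx[sel])
  }
  # camera-saturated foci: all peaks standing on (or next to) the same
  # connected saturated blob are duplicate maxima of one clipped focus
  if (inherits(stack, "halo_stack") && length(peak_idx) > 1) {
    maxval <- 2^stack$bit_depth - 1
    sat <- arr >= maxval - 0.5
    if (any(sat)) {
      sat_lab <- label3d_cpp(dilate_mask(sat, 2L), as.integer(d),
                             connectivity = 26L)
      grp <- sat_lab[peak_idx]
      keep <- rep(TRUE, length(peak_idx))
      for (g in unique(grp[grp > 0])) {
        members <- which(grp == g)
        if (length(members) > 1) {
          best <- members[which.max(resp[peak_idx[members]])]
          keep[setdiff(members, best)] <- FALSE
        }
      }
      peak_idx <- peak_idx[keep]
    }
  }
  npk <- length(peak_idx)
  if (npk > params$max_foci)
    stop(sprintf("more than %d candidate foci; raise the detection cut",
                 params$max_foci))

  pk <- arrayInd(peak_idx, d)
  r_px <- pmax(params$aperture_sigma * sigma_px, 1)

  mask <- array(FALSE, dim = d)
  markers <- array(0L, dim = d)
  border_flag <- logical(npk)
  for (i in seq_len(npk)) {
    lo <- pmax(pk[i, ] - ceiling(r_px), 1)
    hi <- pmin(pk[i, ] + ceiling(r_px), d)
    border_flag[i] <- any(pk[i, 2:3] - r_px[2:3] < 1) ||
      any(pk[i, 2:3] + r_px[2:3] > d[2:3])
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    ell <- outer(outer(((zi - pk[i, 1]) / r_px[1])^2,
                       ((yi - pk[i, 2]) / r_px[2])^2, `+`),
                 ((xi - pk[i, 3]) / r_px[3])^2, `+`) <= 1
    mask[zi, yi, xi] <- mask[zi, yi, xi] | ell
    markers[pk[i, 1], pk[i, 2], pk[i, 3]] <- i
  }

  labels <- watershed_markers_cpp(as.numeric(s1), as.integer(markers),
                                  as.logical(mask), as.integer(d))

  # refine the background from voxels outside every aperture: the plain
  # per-plane median is biased upward by focus signal in crowded planes
  bg2 <- vapply(seq_len(d[1]), function(zi) {
    plane <- arr[zi, , ]
    free <- !mask[zi, , ]
    if (any(free)) median(plane[free]) else bg$per_plane[zi]
  }, numeric(1))
  x <- as.numeric(arr) - rep(bg2, times = prod(d[2:3]))
  dim(x) <- d

  assigned <- which(labels > 0)
  lab <- labels[assigned]
  xv <- x[assigned]
  voxel_count <- tabulate(lab, npk)
  integrated <- vapply(split(xv, factor(lab, levels = seq_len(npk))),
                       sum, numeric(1))
  integrated <- pmax(unname(integrated), 0)

  # intensity-weighted centroids (positive part of the corrected signal)
  ai <- arrayInd(assigned, d)
  w <- pmax(xv, 0)
  wsum <- vapply(split(w, factor(lab, levels = seq_len(npk))), sum,
                 numeric(1))
  centroid_px <- sapply(1:3, function(a) {
    s <- vapply(split(w * ai[, a], factor(lab, levels = seq_len(npk))),
                sum, numeric(1))
    ifelse(wsum > 0, s / wsum, pk[, a])
  })
  if (npk == 1L) centroid_px <- matrix(centroid_px, nrow = 1L)
  centroid_um <- sweep(centroid_px - 0.5, 2, vox, `*`)

  compartment <- rep(NA_character_, npk)
  if (!is.null(compartments)) {
    cc <- compartment_at(compartments, centroid_um)
    compartment <- ifelse(cc == "guard", "core", cc)
  }

  data.frame(
    focus_id = seq_len(npk),
    channel = channel,
    z_um = centroid_um[, 1],
    y_um = centroid_um[, 2],
    x_um = centroid_um[, 3],
    voxel_count = voxel_count,
    integrated_intensity = integrated,
    peak_response = resp[peak_idx],
    compartment = compartment,
    border_flag = border_flag,
    estimated_bp = NA_real_,
    passes_threshold = NA,
    stringsAsFactors = FALSE
  )
}

empty_foci_frame <- function(channel) {
  data.frame(focus_id = integer(0), channel = character(0),
             z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
             voxel_count = integer(0), integrated_intensity = numeric(0),
             peak_response = numeric(0), compartment = character(0),
             border_flag = logical(0), estimated_bp = numeric(0),
             passes_threshold = logical(0), stringsAsFactors = FALSE)
}

#' Apply the plasmid-standard minimum detection threshold
#'
#' A focus passes when its background-corrected integrated intensity is at
#' least the calibration model's `min_threshold_intensity` (the mean
#' intensity of the 135-repeat / 810-bp plasmid standard); the boundary case
#' passes. Centromere foci carry no telomere calibration and always pass.
#'
#' @param foci data.frame from [detect_foci()] (any mix of channels).
#' @param calibration a [fit_calibration()] model (possibly multi-channel).
#' @return `foci` with `passes_threshold` (and `estimated_bp` for calibrated
#'   channels) filled in.
#' @export
apply_detection_threshold <- function(foci, calibration) {
  if (missing(calibration) || is.null(calibration))
    stop("calibration model is required")
  stopifnot(inherits(calibration, "halo_calibration"))
  foci$passes_threshold <- rep(TRUE, nrow(foci))
  for (ch in unique(foci$channel)) {
    sel <- foci$channel == ch
    if (ch %in% names(calibration$channels)) {
      m <- calibration$channels[[ch]]
      foci$passes_threshold[sel] <-
        foci$integrated_intensity[sel] >= m$min_threshold_intensity
      foci$estimated_bp[sel] <-
        intensity_to_bp(foci$integrated_intensity[sel], calibration, ch)
    }
  }
  foci
}

#' Pair colocalized G- and C-strand foci
#'
#' Mutual-nearest-neighbor (greedy closest-pair) matching under a maximum
#' 3D centroid distance; each focus joins at most one pair; ties go to the
#' smaller distance. The colocalization fraction is the number of pairs
#' divided by the mean of the two channel counts.
#'
#' @param g_foci,c_foci data.frames from [detect_foci()] for the two strands
#'   (pre-filtered to one compartment if desired).
#' @param max_distance_um maximum centroid distance for a pair, um.
#' @return list with `pairs` (data.frame `g_id`, `c_id`,
#'   `centroid_distance_um`) and `fraction`.
#' @export
pair_colocalized <- function(g_foci, c_foci, max_distance_um = 0.3) {
  if (max_distance_um < 0) stop("max_distance_um must be >= 0")
  ng <- nrow(g_foci); nc <- nrow(c_foci)
  pairs <- data.frame(g_id = integer(0), c_id = integer(0),
                      centroid_distance_um = numeric(0))
  if (ng == 0 || nc == 0) {
    fraction <- if (ng == 0 && nc == 0) 0 else 0
    return(list(pairs = pairs, fraction = fraction))
  }
  gm <- as.matrix(g_foci[, c("z_um", "y_um", "x_um")])
  cm <- as.matrix(c_foci[, c("z_um", "y_um", "x_um")])
  dmat <- sqrt(outer(rowSums(gm^2), rep(1, nc)) +
               outer(rep(1, ng), rowSums(cm^2)) - 2 * gm %*% t(cm))
  dmat[dmat > max_distance_um] <- Inf
  repeat {
    m <- which.min(dmat)
    if (length(m) == 0 || !is.finite(dmat[m])) break
    gi <- (m - 1) %% ng + 1
    ci <- (m - 1) %/% ng + 1
    pairs <- rbind(pairs, data.frame(
      g_id = g_foci$focus_id[gi], c_id = c_foci$focus_id[ci],
      centroid_distance_um = dmat[m]))
    dmat[gi, ] <- Inf
    dmat[, ci] <- Inf
  }
  list(pairs = pairs, fraction = nrow(pairs) / mean(c(ng, nc)))
}

#' Probability that a chance multi-molecule aggregate mixes both strands
#'
#' If a Halo focus were formed by `k` molecules co-deposited independently,
#' each G-strand with probability `p_g`, the probability that the focus
#' contains both strand types is `1 - p_g^k - (1 - p_g)^k`. For `p_g = 0.5`
#' this is minimized over `k >= 2` at `k = 2`, giving 0.5: at least half of
#' all chance aggregates would be strand-mixed and score as colocalization
#' events, which is the basis for rejecting the aggregate interpretation of
#' Halo foci given the low observed G/C colocalization.
#'
#' @param k_molecules number of molecules in the aggregate (>= 1).
#' @param p_g probability a molecule is G-strand.
#' @return Probability of a mixed (G+C) aggregate; vectorized over
#'   `k_molecules`.
#' @export
chance_mixed_focus_probability <- function(k_molecules, p_g = 0.5) {
  if (any(k_molecules < 1) || any(k_molecules != round(k_molecules)))
    stop("k_molecules must be integer >= 1")
  if (p_g < 0 || p_g > 1) stop("p_g must be in [0, 1]")
  1 - p_g^k_molecules - (1 - p_g)^k_molecules
}
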