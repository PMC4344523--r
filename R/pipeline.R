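#' Analyze a single nucleus stack
#'
#' The per-nucleus computational chain: optional Richardson-Lucy
#' deconvolution, DAPI core/Halo segmentation, 3D spot detection in the
#' CEN, TelC and TelG channels, plasmid-threshold and length calibration,
#' and the per-nucleus metric summary.
#'
#' @param stack a `halo_stack`.
#' @param calibration a `halo_calibration` for the telomere channels.
#' @param deconvolve_iterations Richardson-Lucy iterations (0 skips
#'   deconvolution; detection counts are invariant to this at packaged
#'   settings, so batch simulations may skip it).
#' @param params a [detect_params()].
#' @param psf a [psf_model()].
#' @param segmentation list of [segment_nuclear_core()] arguments.
#' @param coloc_distance_um colocalization pairing distance.
#' @param nucleus_id identifier for the output rows.
#' @return list with `compartments`, `foci` (all channels) and `metrics`
#'   (one row).
#' @export
analyze_stack <- function(stack, calibration,
                          deconvolve_iterations = 0,
                          params = detect_params(), psf = psf_model(),
                          segmentation = list(),
                          coloc_distance_um = 0.3,
                          nucleus_id = NA) {
  require_channels(stack)
  if (deconvolve_iterations > 0)
    stack <- deconvolve(stack, psf, deconvolve_iterations)
  compartments <- do.call(segment_nuclear_core,
                          c(list(stack), segmentation))
  foci <- do.call(rbind, lapply(c("CEN", "TelC", "TelG"), function(ch) {
    detect_foci(stack, ch, compartments, params = params, psf = psf)
  }))
  foci <- apply_detection_threshold(foci, calibration)
  metrics <- summarize_nucleus(compartments, foci,
                               nucleus_id = nucleus_id,
                               coloc_distance_um = coloc_distance_um)
  list(compartments = compartments, foci = foci, metrics = metrics)
}

#' Simulate calibration slides and fit the intensity-to-bp model
#'
#' Renders the 135-repeat (810 bp) and optionally the 270-repeat (1620 bp)
#' plasmid slides, detects their foci per telomere channel, fits the
#' calibration, and estimates the Halo noise sigma from null apertures on
#' the 810-bp slide.
#'
#' @param config a [sim_config()].
#' @param n_foci foci per slide.
#' @param seed RNG seed.
#' @param channels telomere channels to calibrate.
#' @param use_1620 include the 1620-bp standard in the fit.
#' @param noise render the slides with camera noise.
#' @param params,psf detection settings.
#' @return list with `calibration` (a merged `halo_calibration`),
#'   `slide_810`, `slide_1620` (each with `stack`, `truth`, per-channel
#'   `foci`).
#' @export
simulate_and_fit_calibration <- function(config = sim_config(), n_foci = 60,
                                         seed = NULL,
                                         channels = c("TelG", "TelC"),
                                         use_1620 = FALSE, noise = TRUE,
                                         params = detect_params(),
                                         psf = psf_model()) {
  s810 <- simulate_calibration_slide(135, n_foci, config, seed = seed,
                                     noise = noise)
  s1620 <- simulate_calibration_slide(270, n_foci, config,
                                      seed = if (is.null(seed)) NULL else seed + 1000L,
                                      noise = noise)
  detect_ch <- function(slide, ch)
    detect_foci(slide$stack, ch, params = params, psf = psf)
  models <- lapply(channels, function(ch) {
    f810 <- detect_ch(s810, ch)
    ns <- estimate_noise_sigma(s810$stack, ch, foci = f810,
                               params = params, psf = psf,
                               seed = if (is.null(seed)) NULL else seed + 2000L)
    fit_calibration(f810,
                    foci_1620 = if (use_1620) detect_ch(s1620, ch) else NULL,
                    channel = ch, noise_sigma = ns)
  })
  calibration <- do.call(merge_calibrations, models)
  s810$foci <- lapply(setNames(channels, channels),
                      function(ch) detect_ch(s810, ch))
  s1620$foci <- lapply(setNames(channels, channels),
                       function(ch) detect_ch(s1620, ch))
  list(calibration = calibration, slide_810 = s810, slide_1620 = s1620)
}

#' Simulate and analyze a population of nuclei end-to-end
#'
#' Draws per-nucleus ECTR populations from a cell-line preset, builds and
#' renders each nucleus, runs the analysis chain, and collects per-nucleus
#' metrics together with the generator's truth counts for parameter-recovery
#' checks. Stacks are rendered and analyzed one at a time.
#'
#' @param preset a [cell_line_preset()] (or packaged preset name).
#' @param n_nuclei number of nuclei.
#' @param config a [sim_config()].
#' @param calibration a `halo_calibration`; fitted from a simulated 810-bp
#'   slide when `NULL`.
#' @param phase fixed phase ("G1", "S", "G2") or `NULL` to draw phases with
#'   `phase_probs`.
#' @param phase_probs sampling probabilities for (G1, S, G2) in an
#'   asynchronous population.
#' @param seed RNG seed for the whole experiment.
#' @param deconvolve_iterations passed to [analyze_stack()].
#' @param noise render with camera noise.
#' @param params,psf detection settings.
#' @param truth_args extra arguments for [build_nucleus_truth()].
#' @param keep_foci keep the per-focus table of every nucleus.
#' @return list with `metrics` (per-nucleus rows plus truth columns
#'   `truth_halo_count_G/C`, `truth_phase`), `foci` (if kept) and
#'   `calibration`.
#' @export
run_simulated_experiment <- function(preset, n_nuclei,
                                     config = sim_config(),
                                     calibration = NULL,
                                     phase = "G1",
                                     phase_probs = c(G1 = 0.5, S = 0.3,
                                                     G2 = 0.2),
                                     seed = NULL,
                                     deconvolve_iterations = 0,
                                     noise = TRUE,
                                     params = detect_params(),
                                     psf = psf_model(),
                                     truth_args = list(),
                                     keep_foci = FALSE) {
  if (is.character(preset)) preset <- get_preset(preset)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(calibration)) {
    calibration <- simulate_and_fit_calibration(config, seed = NULL,
                                                params = params,
                                                psf = psf)$calibration
  }
  phases <- if (is.null(phase)) {
    sample(names(phase_probs), n_nuclei, replace = TRUE, prob = phase_probs)
  } else rep(phase, length.out = n_nuclei)

  pops <- sample_ectr_population(preset, n_nuclei, phase = phases)
  metrics <- vector("list", n_nuclei)
  foci <- if (keep_foci) vector("list", n_nuclei) else NULL
  for (i in seq_len(n_nuclei)) {
    truth <- do.call(build_nucleus_truth,
                     c(list(preset, pops[[i]], cell_cycle_phase = phases[i],
                            config = config, nucleus_id = i), truth_args))
    stack <- render_stack(truth, config, noise = noise, seed = NULL)
    out <- analyze_stack(stack, calibration,
                         deconvolve_iterations = deconvolve_iterations,
                         params = params, psf = psf, nucleus_id = i)
    m <- out$metrics
    m$truth_halo_count_G <- sum(pops[[i]]$strand == "G")
    m$truth_halo_count_C <- sum(pops[[i]]$strand == "C")
    # molecules at or above the 810-bp operating threshold: the population
    # the detector actually claims to count
    det <- pops[[i]]$repeat_length_bp >= 810
    m$truth_detectable_G <- sum(pops[[i]]$strand == "G" & det)
    m$truth_detectable_C <- sum(pops[[i]]$strand == "C" & det)
    m$truth_phase <- phases[i]
    metrics[[i]] <- m
    if (keep_foci) foci[[i]] <- cbind(nucleus_id = i, out$foci)
  }
  metrics <- do.call(rbind, metrics)
  list(metrics = metrics,
       foci = if (keep_foci) do.call(rbind, foci) else NULL,
       calibration = calibration)
}
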