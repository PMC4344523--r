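# Shared fixtures: a reduced field keeps unit-test renders fast while using
# the same voxel size, PSF and camera model as the full-size default.

small_config <- function(...) {
  sim_config(field_size_voxels = c(z = 24L, y = 72L, x = 72L), ...)
}

# geometry that fits the reduced field
small_truth_args <- function() {
  list(core_radius_um = 3, core_z_semiaxis_um = 1.2,
       halo_standoff_um = 0.5, halo_scale_um = 0.7, halo_z_um = 0.7)
}

# build a bare ground-truth record for hand-placed molecules
make_truth <- function(molecules, config,
                       centromeres = data.frame(z_um = numeric(0),
                                                y_um = numeric(0),
                                                x_um = numeric(0)),
                       core_radius_um = 0, core_z_semiaxis_um = 0,
                       phase = "G1", id = "manual") {
  ext <- field_extent_um(config)
  structure(list(
    nucleus_id = id, preset_name = "manual",
    core_center_um = setNames(as.numeric(ext / 2), c("z", "y", "x")),
    core_radius_um = core_radius_um,
    core_z_semiaxis_um = core_z_semiaxis_um,
    molecules = molecules,
    centromere_positions_um = centromeres,
    cell_cycle_truth = phase
  ), class = "ground_truth")
}

molecule_frame <- function(strand, bp, z, y, x, compartment = "halo") {
  data.frame(strand = strand, repeat_length_bp = bp,
             z_um = z, y_um = y, x_um = x,
             compartment_truth = rep(compartment, length.out = length(z)))
}

# random well-separated positions inside the field (rejection sampling)
separated_positions <- function(n, config, min_dist = 2.0, margin = 1.2) {
  ext <- field_extent_um(config)
  pos <- matrix(numeric(0), 0, 3)
  while (nrow(pos) < n) {
    cand <- c(runif(1, margin, ext["z"] - margin),
              runif(1, margin, ext["y"] - margin),
              runif(1, margin, ext["x"] - margin))
    if (nrow(pos) == 0 || min(sqrt(colSums((t(pos) - cand)^2))) >= min_dist)
      pos <- rbind(pos, cand)
  }
  colnames(pos) <- c("z", "y", "x")
  pos
}

# calibration model built directly from known intensities (no imaging)
toy_calibration <- function(mean_810 = 810, n = 20, channels = c("TelG", "TelC"),
                            noise_sigma = 40) {
  models <- lapply(channels, function(ch) {
    fit_calibration(rep(mean_810, n), channel = ch,
                    noise_sigma = noise_sigma)
  })
  do.call(merge_calibrations, models)
}

# minimal foci row(s) for quantify-level tests
toy_focus <- function(channel, compartment, intensity = 50000,
                      z = 4, y = 12, x = 12, border = FALSE) {
  data.frame(focus_id = seq_along(intensity), channel = channel,
             z_um = z, y_um = y, x_um = x,
             voxel_count = 100L, integrated_intensity = intensity,
             peak_response = intensity / 100,
             compartment = compartment, border_flag = border,
             estimated_bp = NA_real_, passes_threshold = NA,
             stringsAsFactors = FALSE)
}
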