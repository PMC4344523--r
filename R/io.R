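#' Write a multi-channel stack as TIFF with an OME-style XML sidecar
#'
#' Planes are written channel-major (all z of DAPI, then CEN, TelC, TelG) as
#' 16-bit grayscale TIFF; voxel size, channel names, bit depth and camera
#' offset go into a `<basename>.ome.xml` companion file (the installed TIFF
#' writer does not persist description tags). Intensities are rounded to
#' integer ADU on write.
#'
#' @param stack a `halo_stack`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "halo_stack"))
  d <- dim(stack$voxels)
  pages <- vector("list", d[1] * d[4])
  k <- 1L
  for (ci in seq_len(d[4])) {
    for (zi in seq_len(d[1])) {
      m <- stack$voxels[zi, , , ci]
      dim(m) <- d[2:3]
      pages[[k]] <- pmin(pmax(round(m), 0), 65535) / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- xml2::xml_new_root("OME")
  img <- xml2::xml_add_child(meta, "Image")
  px <- xml2::xml_add_child(
    img, "Pixels",
    DimensionOrder = "XYZCT", Type = "uint16",
    SizeX = d[3], SizeY = d[2], SizeZ = d[1], SizeC = d[4], SizeT = 1,
    PhysicalSizeX = unname(stack$voxel_size_um["x"]),
    PhysicalSizeY = unname(stack$voxel_size_um["y"]),
    PhysicalSizeZ = unname(stack$voxel_size_um["z"]),
    BitDepth = unname(stack$bit_depth),
    CameraOffset = unname(stack$camera_offset))
  for (ch in stack$channel_names)
    xml2::xml_add_child(px, "Channel", Name = ch)
  xml2::write_xml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tiff?$", "", path, ignore.case = TRUE) |>
  paste0(".ome.xml")

#' Read a multi-channel stack written by [write_stack()]
#'
#' Voxel size and channel names come from the OME-style sidecar; when the
#' sidecar is missing, defaults (0.2 x 0.16 x 0.16 um, standard channel
#' order) are assumed with a warning.
#'
#' @param path `.tif` path.
#' @param channel_names override channel names.
#' @param voxel_size_um override voxel size (z, y, x), um.
#' @return A `halo_stack`.
#' @export
read_stack <- function(path, channel_names = NULL, voxel_size_um = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read stack '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- list(voxel_size_um = c(z = 0.2, y = 0.16, x = 0.16),
               channel_names = HALO_CHANNELS, bit_depth = 12L,
               camera_offset = 100)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    x <- xml2::read_xml(sp)
    px <- xml2::xml_find_first(x, ".//Pixels")
    att <- function(a) as.numeric(xml2::xml_attr(px, a))
    meta$voxel_size_um <- c(z = att("PhysicalSizeZ"), y = att("PhysicalSizeY"),
                            x = att("PhysicalSizeX"))
    meta$bit_depth <- as.integer(att("BitDepth"))
    meta$camera_offset <- att("CameraOffset")
    meta$channel_names <-
      xml2::xml_attr(xml2::xml_find_all(px, ".//Channel"), "Name")
  } else {
    warning(sprintf("no metadata sidecar for '%s'; assuming default voxel size and channel order",
                    path))
  }
  if (!is.null(channel_names)) meta$channel_names <- channel_names
  if (!is.null(voxel_size_um))
    meta$voxel_size_um <- setNames(voxel_size_um, c("z", "y", "x"))
  nch <- length(meta$channel_names)
  if (length(pages) %% nch != 0)
    stop(sprintf("page count %d is not a multiple of %d channels",
                 length(pages), nch))
  nz <- length(pages) %/% nch
  d2 <- dim(pages[[1]])
  voxels <- array(0, dim = c(nz, d2[1], d2[2], nch),
                  dimnames = list(NULL, NULL, NULL, meta$channel_names))
  k <- 1L
  for (ci in seq_len(nch)) {
    for (zi in seq_len(nz)) {
      voxels[zi, , , ci] <- pages[[k]] * 65535
      k <- k + 1L
    }
  }
  structure(list(voxels = voxels, voxel_size_um = meta$voxel_size_um,
                 bit_depth = meta$bit_depth,
                 channel_names = meta$channel_names,
                 camera_offset = meta$camera_offset),
            class = "halo_stack")
}

#' Check that a stack carries the channels the pipeline needs
#' @param stack a `halo_stack`.
#' @param channels required channel names.
#' @return `stack`, invisibly; errors naming any missing channel.
#' @export
require_channels <- function(stack, channels = HALO_CHANNELS) {
  missing <- setdiff(channels, stack$channel_names)
  if (length(missing) > 0)
    stop(sprintf("stack is missing channel(s): %s",
                 paste(missing, collapse = ", ")))
  invisible(stack)
}

#' Write ground truth as JSON (one record per nucleus) and molecule CSV
#' @param truths a `ground_truth` or list of them.
#' @param json_path,csv_path output files (either may be `NULL`).
#' @export
write_ground_truth <- function(truths, json_path = NULL, csv_path = NULL) {
  if (inherits(truths, "ground_truth")) truths <- list(truths)
  if (!is.null(json_path)) {
    recs <- lapply(truths, function(tr) unclass(tr))
    jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    rows <- lapply(truths, function(tr) {
      if (nrow(tr$molecules) == 0) return(NULL)
      cbind(nucleus_id = tr$nucleus_id, tr$molecules)
    })
    write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  }
  invisible(truths)
}

#' Default run configuration
#'
#' Nested parameter list for [run_pipeline()]; any subset can be overridden
#' from a YAML file. Unknown keys are rejected.
#' @return Named nested list.
#' @export
default_run_config <- function() {
  list(
    input = list(stack_dir = NULL, pattern = "\\.tiff?$"),
    output = list(dir = "halofish_out"),
    calibration = list(file = NULL),
    psf = list(sigma_um = c(0.35, 0.12, 0.12), truncate = 4),
    deconvolution = list(iterations = 10),
    segmentation = list(smooth_sigma_um = 0.15, guard_voxels = 2),
    detection = list(peak_snr = 7, min_peak_response = 2,
                     aperture_sigma = 4.5, dog_ratio = 1.6,
                     detect_sigma_scale = 0.5, nms_sigma = 2),
    quantify = list(coloc_distance_um = 0.3, g1_max = 1.25, g2_min = 1.75),
    seed = 1,
    log_level = "info"
  )
}

#' Read and validate a YAML run configuration
#' @param path YAML file; keys must exist in [default_run_config()].
#' @return Merged configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_run_config()
  check_keys <- function(u, d, prefix = "") {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown) > 0)
      stop(sprintf("unknown config key(s): %s",
                   paste0(prefix, unknown, collapse = ", ")))
    for (k in names(u)) {
      if (is.list(d[[k]]) && !is.null(names(d[[k]])))
        check_keys(u[[k]] %||% list(), d[[k]], paste0(prefix, k, "."))
    }
  }
  check_keys(user, defaults)
  modifyList(defaults, user)
}

config_hash <- function(config) {
  fnv1a_hash(paste(deparse(config), collapse = ""))
}

#' Run the full analysis pipeline over a directory of stacks
#'
#' For each stack: deconvolve, segment the nuclear core, detect foci in the
#' CEN/TelC/TelG channels, apply the plasmid calibration threshold and
#' length conversion, and summarize the nucleus. Per-stack failures are
#' recorded and the remaining stacks still run. Writes `foci.csv`,
#' `nuclei.csv`, `group_summary.csv` and `report.json` (run parameters,
#' parameter hash, package version, per-stack status) into the output
#' directory.
#'
#' @param config configuration list (see [default_run_config()] /
#'   [read_run_config()]).
#' @return Invisibly, a list with `metrics`, `foci`, `report`. The report's
#'   `n_failed` equals the number of stacks that errored; the pipeline
#'   itself errors only when every stack fails.
#' @export
run_pipeline <- function(config) {
  config <- modifyList(default_run_config(), config)
  dir_in <- config$input$stack_dir
  if (is.null(dir_in) || !dir.exists(dir_in))
    stop("input$stack_dir does not exist")
  files <- sort(list.files(dir_in, pattern = config$input$pattern,
                           full.names = TRUE))
  if (length(files) == 0) stop(sprintf("no stacks found in '%s'", dir_in))
  if (is.null(config$calibration$file))
    stop("calibration$file is required")
  calibration <- read_calibration(config$calibration$file)
  psf <- psf_model(config$psf$sigma_um, config$psf$truncate)
  params <- detect_params(peak_snr = config$detection$peak_snr,
                          min_peak_response = config$detection$min_peak_response,
                          aperture_sigma = config$detection$aperture_sigma,
                          dog_ratio = config$detection$dog_ratio,
                          detect_sigma_scale = config$detection$detect_sigma_scale,
                          nms_sigma = config$detection$nms_sigma)
  set.seed(as.integer(config$seed))

  out_dir <- config$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # provenance hash covers the analysis parameters, not the i/o paths
  hash <- config_hash(config[setdiff(names(config), c("input", "output"))])

  all_foci <- list(); all_metrics <- list(); status <- list()
  for (f in files) {
    id <- sub("\\.tiff?$", "", basename(f), ignore.case = TRUE)
    res <- tryCatch({
      stack <- read_stack(f)
      require_channels(stack)
      out <- analyze_stack(stack, calibration,
                           deconvolve_iterations = config$deconvolution$iterations,
                           params = params, psf = psf,
                           segmentation = config$segmentation,
                           coloc_distance_um = config$quantify$coloc_distance_um,
                           nucleus_id = id)
      all_foci[[id]] <- cbind(nucleus_id = id, out$foci, run_hash = hash)
      all_metrics[[id]] <- out$metrics
      "ok"
    }, error = function(e) paste("error:", conditionMessage(e)))
    status[[id]] <- res
  }
  n_failed <- sum(vapply(status, function(s) s != "ok", logical(1)))
  if (n_failed == length(files))
    stop("all stacks failed; see report for per-stack errors")

  metrics <- do.call(rbind, all_metrics)
  metrics <- assign_cell_cycle_bins(metrics,
                                    g1_max = config$quantify$g1_max,
                                    g2_min = config$quantify$g2_min)
  metrics$run_hash <- hash
  foci <- do.call(rbind, all_foci)
  write.csv(foci, file.path(out_dir, "foci.csv"), row.names = FALSE)
  write.csv(metrics, file.path(out_dir, "nuclei.csv"), row.names = FALSE)
  write.csv(group_summary(metrics, label = basename(dir_in)),
            file.path(out_dir, "group_summary.csv"), row.names = FALSE)
  report <- list(
    package_version = as.character(utils::packageVersion("halofish")),
    r_version = R.version.string,
    parameter_hash = hash,
    seed = config$seed,
    n_stacks = length(files),
    n_failed = n_failed,
    status = status,
    config = config
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(list(metrics = metrics, foci = foci, report = report))
}
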