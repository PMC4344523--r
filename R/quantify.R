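#' Per-nucleus ECTR metrics
#'
#' Computes the full per-nucleus report from thresholded, length-estimated
#' foci: Halo and core focus counts per telomere strand, core centromere
#' count, kb content per strand and compartment, the percentage of each
#' strand's telomere-repeat DNA that is extrachromosomal, the core
#' telomere:centromere focus ratio, G/C colocalization fractions per
#' compartment, symmetric percent strand biases in Halo number and content,
#' and Halo length-distribution summaries. Biases use the symmetric
#' denominator `mean(G, C)`, so swapping the strands negates them exactly.
#'
#' @param compartments a `compartment_map` (may be `NULL` for fields
#'   without a nucleus; compartment columns must then be present in `foci`).
#' @param foci data.frame of detected foci across channels, with
#'   `passes_threshold` and `estimated_bp` filled in
#'   (see [apply_detection_threshold()]).
#' @param calibration optional `halo_calibration`; when given it is applied
#'   to `foci` first.
#' @param nucleus_id identifier copied into the output row.
#' @param coloc_distance_um colocalization distance for [pair_colocalized()].
#' @return One-row data.frame of class `nucleus_metrics`.
#' @export
summarize_nucleus <- function(compartments, foci, calibration = NULL,
                              nucleus_id = NA, coloc_distance_um = 0.3) {
  if (!is.null(calibration))
    foci <- apply_detection_threshold(foci, calibration)
  if (any(is.na(foci$passes_threshold)))
    stop("foci must be thresholded before summarizing ",
         "(apply_detection_threshold or pass a calibration)")

  sub <- function(channel, compartment = NULL, passing = TRUE) {
    s <- foci$channel == channel
    if (!is.null(compartment)) s <- s & foci$compartment %in% compartment
    if (passing) s <- s & foci$passes_threshold
    foci[s, , drop = FALSE]
  }
  content_kb <- function(f) {
    f <- f[!f$border_flag & !is.na(f$estimated_bp), , drop = FALSE]
    sum(f$estimated_bp) / 1000
  }

  halo_G <- sub("TelG", "halo"); halo_C <- sub("TelC", "halo")
  core_G <- sub("TelG", "core"); core_C <- sub("TelC", "core")
  cen_core <- sub("CEN", "core"); cen_halo <- sub("CEN", "halo")

  halo_count_G <- nrow(halo_G); halo_count_C <- nrow(halo_C)
  core_count_G <- nrow(core_G); core_count_C <- nrow(core_C)
  n_cen <- nrow(cen_core)

  halo_content_G <- content_kb(halo_G); halo_content_C <- content_kb(halo_C)
  core_content_G <- content_kb(core_G); core_content_C <- content_kb(core_C)

  frac <- function(halo, core) {
    tot <- halo + core
    if (tot <= 0) NA_real_ else 100 * halo / tot
  }
  bias <- function(g, c) {
    m <- mean(c(g, c))
    if (m <= 0) NA_real_ else 100 * (g - c) / m
  }

  coloc <- function(compartment) {
    g <- sub("TelG", compartment); c <- sub("TelC", compartment)
    if (nrow(g) == 0 && nrow(c) == 0) return(NA_real_)
    pair_colocalized(g, c, coloc_distance_um)$fraction
  }

  lstats <- function(f) {
    f <- f[!f$border_flag & !is.na(f$estimated_bp), , drop = FALSE]
    length_distribution_stats(f$estimated_bp / 1000)
  }
  ls_G <- lstats(halo_G); ls_C <- lstats(halo_C)
  pooled <- c(halo_G$estimated_bp[!halo_G$border_flag],
              halo_C$estimated_bp[!halo_C$border_flag]) / 1000
  pooled <- pooled[!is.na(pooled)]

  out <- data.frame(
    nucleus_id = nucleus_id,
    halo_count_G = halo_count_G, halo_count_C = halo_count_C,
    core_count_G = core_count_G, core_count_C = core_count_C,
    centromere_count_core = n_cen,
    centromere_count_halo = nrow(cen_halo),
    halo_content_kb_G = halo_content_G, halo_content_kb_C = halo_content_C,
    core_content_kb_G = core_content_G, core_content_kb_C = core_content_C,
    ectr_fraction_G = frac(halo_content_G, core_content_G),
    ectr_fraction_C = frac(halo_content_C, core_content_C),
    tel_cen_ratio_G = if (n_cen > 0) core_count_G / n_cen else NA_real_,
    tel_cen_ratio_C = if (n_cen > 0) core_count_C / n_cen else NA_real_,
    coloc_fraction_halo = coloc("halo"),
    coloc_fraction_core = coloc("core"),
    number_bias_pct = bias(halo_count_G, halo_count_C),
    content_bias_pct = bias(halo_content_G, halo_content_C),
    cell_cycle_bin = NA_character_,
    length_mean_kb_G = ls_G$mean_kb, length_median_kb_G = ls_G$median_kb,
    length_pct_below_50_G = ls_G$pct_below_50,
    length_pct_above_200_G = ls_G$pct_above_200,
    length_mean_kb_C = ls_C$mean_kb, length_median_kb_C = ls_C$median_kb,
    length_pct_below_50_C = ls_C$pct_below_50,
    length_pct_above_200_C = ls_C$pct_above_200,
    length_median_kb_all = if (length(pooled)) median(pooled) else NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("nucleus_metrics", class(out))
  out
}

#' Summary statistics of an ECTR length distribution
#'
#' Lengths are binned as in the standard reporting: below 50 kb, 50-200 kb,
#' above 200 kb. ECTR length distributions are strongly right-skewed, with
#' means typically 2-2.5x the median.
#'
#' @param lengths_kb numeric vector of molecule lengths in kb.
#' @return list with `mean_kb`, `median_kb`, `pct_below_50`,
#'   `pct_above_200`, `mean_median_ratio` (all `NA` for empty input).
#' @export
length_distribution_stats <- function(lengths_kb) {
  lengths_kb <- lengths_kb[!is.na(lengths_kb)]
  if (length(lengths_kb) == 0) {
    return(list(mean_kb = NA_real_, median_kb = NA_real_,
                pct_below_50 = NA_real_, pct_above_200 = NA_real_,
                mean_median_ratio = NA_real_))
  }
  m <- mean(lengths_kb)
  md <- median(lengths_kb)
  list(mean_kb = m, median_kb = md,
       pct_below_50 = 100 * mean(lengths_kb < 50),
       pct_above_200 = 100 * mean(lengths_kb > 200),
       mean_median_ratio = if (md > 0) m / md else NA_real_)
}

#' Assign a cell-cycle bin from the core centromere focus count
#'
#' Chromosome replication doubles the number of centromeres per nucleus, so
#' core-localized centromere focus counts sort nuclei into G1-, S- and
#' G2-enriched fractions: counts up to `g1_max` times the modal 2N count are
#' G1, counts at or above `g2_min` times the modal count are G2, the rest S.
#'
#' @param centromere_count per-nucleus core centromere focus count (> 0).
#' @param modal_2n_count modal (2N) centromere count of the population.
#' @param g1_max,g2_min bin cut-offs as multiples of the modal count.
#' @return Character vector of bins ("G1", "S", "G2").
#' @export
assign_cell_cycle_bin <- function(centromere_count, modal_2n_count,
                                  g1_max = 1.25, g2_min = 1.75) {
  if (modal_2n_count <= 0) stop("modal_2n_count must be > 0")
  if (any(centromere_count <= 0))
    stop("centromere counts must be > 0")
  ifelse(centromere_count <= g1_max * modal_2n_count, "G1",
         ifelse(centromere_count >= g2_min * modal_2n_count, "G2", "S"))
}

#' Modal centromere count of a population
#' @param counts integer vector of per-nucleus centromere counts.
#' @return The most frequent count (smallest on ties).
#' @export
modal_centromere_count <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("no positive centromere counts")
  tab <- table(counts)
  as.numeric(names(tab)[which.max(tab)])
}

#' Fill cell-cycle bins into a metrics table
#' @param metrics data.frame of [summarize_nucleus()] rows.
#' @param modal_2n_count modal 2N centromere count; estimated from the data
#'   when `NULL`.
#' @param ... passed to [assign_cell_cycle_bin()].
#' @return `metrics` with `cell_cycle_bin` filled.
#' @export
assign_cell_cycle_bins <- function(metrics, modal_2n_count = NULL, ...) {
  modal_2n_count <- modal_2n_count %||%
    modal_centromere_count(metrics$centromere_count_core)
  ok <- metrics$centromere_count_core > 0
  metrics$cell_cycle_bin[ok] <-
    assign_cell_cycle_bin(metrics$centromere_count_core[ok],
                          modal_2n_count, ...)
  metrics
}

#' Welch two-sample comparison of a per-nucleus metric
#'
#' @param group_a,group_b numeric vectors (each n >= 2), or metrics
#'   data.frames together with `metric`.
#' @param metric column name when data.frames are given.
#' @return list with `t_statistic`, `df`, `p_value`, and per-group `n`,
#'   `median` and interquartile range.
#' @export
compare_groups <- function(group_a, group_b, metric = NULL) {
  if (is.data.frame(group_a)) {
    if (is.null(metric)) stop("metric must name a column")
    group_a <- group_a[[metric]]
    group_b <- group_b[[metric]]
  }
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs n >= 2")
  if (sd(group_a) == 0 && sd(group_b) == 0)
    stop("both groups have zero variance; t-test is degenerate")
  tt <- t.test(group_a, group_b)  # Welch by default
  summ <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    list(n = length(x), median = q[2], iqr_low = q[1], iqr_high = q[3])
  }
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, group_a = summ(group_a),
       group_b = summ(group_b))
}

#' Regress total ECTR content on core centromere count
#'
#' Ordinary least squares of per-nucleus total (G + C strand) Halo content
#' in kb on the number of core-localized centromere foci, with a 95%
#' confidence interval on the slope. A positive slope indicates ECTR DNA
#' accumulation with cell-cycle progression.
#'
#' @param metrics data.frame of [summarize_nucleus()] rows (n >= 3).
#' @param conf_level confidence level for the slope interval.
#' @return list with `slope`, `intercept`, `ci_low`, `ci_high`, `n`.
#' @export
regress_content_vs_centromeres <- function(metrics, conf_level = 0.95) {
  if (nrow(metrics) < 3) stop("need at least 3 nuclei")
  x <- metrics$centromere_count_core
  y <- metrics$halo_content_kb_G + metrics$halo_content_kb_C
  if (sd(x) == 0) stop("centromere counts are constant; slope undefined")
  fit <- lm(y ~ x)
  ci <- suppressWarnings(confint(fit, "x", level = conf_level))
  ci[!is.finite(ci)] <- coef(fit)[["x"]]  # zero-residual exact fit
  list(slope = unname(coef(fit)[["x"]]),
       intercept = unname(coef(fit)[["(Intercept)"]]),
       ci_low = unname(ci[1]), ci_high = unname(ci[2]),
       n = nrow(metrics))
}

#' Cell-cycle fold changes of ECTR number and length
#'
#' Fold change (G2-enriched over G1-enriched nuclei) of the mean per-nucleus
#' Halo molecule count (G + C strands) and of the mean per-nucleus median
#' molecule length.
#'
#' @param metrics data.frame with `cell_cycle_bin` filled (see
#'   [assign_cell_cycle_bins()]).
#' @return list with per-bin summaries (`bins`), `count_fold_g2_g1` and
#'   `median_length_fold_g2_g1` (`NA` with a warning when a bin is empty).
#' @export
cell_cycle_fold_changes <- function(metrics) {
  bins <- c("G1", "S", "G2")
  per_bin <- lapply(bins, function(b) {
    m <- metrics[metrics$cell_cycle_bin %in% b, , drop = FALSE]
    if (nrow(m) == 0)
      return(list(n = 0L, mean_count = NA_real_,
                  mean_median_length_kb = NA_real_))
    list(n = nrow(m),
         mean_count = mean(m$halo_count_G + m$halo_count_C),
         mean_median_length_kb = mean(m$length_median_kb_all, na.rm = TRUE))
  })
  names(per_bin) <- bins
  g1 <- per_bin$G1; g2 <- per_bin$G2
  if (g1$n == 0 || g2$n == 0) {
    warning("empty G1 or G2 bin; fold changes undefined")
    return(list(bins = per_bin, count_fold_g2_g1 = NA_real_,
                median_length_fold_g2_g1 = NA_real_))
  }
  list(bins = per_bin,
       count_fold_g2_g1 = g2$mean_count / g1$mean_count,
       median_length_fold_g2_g1 =
         g2$mean_median_length_kb / g1$mean_median_length_kb)
}

#' Group summary (median and interquartile range) of per-nucleus metrics
#' @param metrics data.frame of [summarize_nucleus()] rows.
#' @param label group label stored in the output.
#' @param columns metric columns to summarize (default: all numeric).
#' @return data.frame with one row per metric: median, IQR bounds, n.
#' @export
group_summary <- function(metrics, label = "group", columns = NULL) {
  if (nrow(metrics) == 0) stop("no nuclei to summarize")
  if (is.null(columns))
    columns <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  columns <- setdiff(columns, "nucleus_id")
  rows <- lapply(columns, function(cn) {
    v <- metrics[[cn]]
    v <- v[!is.na(v)]
    if (length(v) == 0)
      return(data.frame(group = label, metric = cn, n = 0L,
                        median = NA_real_, iqr_low = NA_real_,
                        iqr_high = NA_real_))
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = label, metric = cn, n = length(v),
               median = q[2], iqr_low = q[1], iqr_high = q[3])
  })
  do.call(rbind, rows)
}
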