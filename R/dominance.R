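# Dominant-rhythm classification: per-band maximum peaks, standardised peak
# heights, winner-takes-all band assignment, and tabulation by region, lobe,
# hemisphere and electrode type.

#' Canonical frequency-band schemes
#'
#' `"standard"` uses half-open, non-overlapping bands theta `[4,8)`, alpha
#' `[8,13)`, beta `[13,30)`, gamma `[30,100)` — the headline classification
#' convention, with the 12-13 Hz gap folded into alpha. `"wide_beta"` keeps
#' the alternative printed convention beta `[13,35)` with gamma `[30,100)`;
#' those two bands overlap on `[30,35)` and a peak there is eligible for
#' both.
#'
#' @param scheme `"standard"` or `"wide_beta"`.
#' @return Data frame with columns `band`, `low`, `high` (Hz; low inclusive,
#'   high exclusive), in ascending frequency order.
#' @export
band_scheme <- function(scheme = c("standard", "wide_beta")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         standard = data.frame(band = c("theta", "alpha", "beta", "gamma"),
                               low = c(4, 8, 13, 30),
                               high = c(8, 13, 30, 100)),
         wide_beta = data.frame(band = c("theta", "alpha", "beta", "gamma"),
                                low = c(4, 8, 13, 30),
                                high = c(8, 13, 35, 100)))
}

#' Highest peak of a spectral model within one frequency band
#'
#' Among fitted peaks with center in `[low, high)`, returns the one with
#' maximal height; ties break toward the lower center frequency.
#'
#' @param fit a [spectral_fit()] (or a bare peak data frame with columns
#'   center/height/width).
#' @param low,high band edges in Hz (low inclusive, high exclusive).
#' @return One-row data frame (center, height, width), or `NULL` if the band
#'   holds no peak.
#' @export
band_max_peak <- function(fit, low, high) {
  peaks <- if (inherits(fit, "spectral_fit")) fit$peaks else fit
  inb <- peaks$center >= low & peaks$center < high
  if (!any(inb)) return(NULL)
  pk <- peaks[inb, , drop = FALSE]
  pk <- pk[order(-pk$height, pk$center), , drop = FALSE]
  pk[1, , drop = FALSE]
}

#' Long table of per-band maximum peaks for a cohort of fitted models
#'
#' @param fits named list of [spectral_fit()] objects (names = channel ids).
#' @param channels data frame with at least `channel_id`, `subject_id`,
#'   `electrode_id` (rows aligned with `fits` by channel_id).
#' @param bands a [band_scheme()] data frame.
#' @return Data frame (channel_id, subject_id, electrode_id, band, center,
#'   height) with one row per channel x band that holds a peak.
#' @export
cohort_band_peaks <- function(fits, channels, bands = band_scheme()) {
  rows <- list()
  for (ch in channels$channel_id) {
    fit <- fits[[ch]]
    if (is.null(fit)) next
    meta <- channels[channels$channel_id == ch, , drop = FALSE][1, ]
    for (b in seq_len(nrow(bands))) {
      pk <- band_max_peak(fit, bands$low[b], bands$high[b])
      if (is.null(pk)) next
      rows[[length(rows) + 1L]] <-
        data.frame(channel_id = ch, subject_id = meta$subject_id,
                   electrode_id = meta$electrode_id, band = bands$band[b],
                   center = pk$center, height = pk$height,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(channel_id = character(), subject_id = character(),
                      electrode_id = character(), band = character(),
                      center = numeric(), height = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# one z-scoring pass within groups; degenerate groups (n = 1 or zero spread)
# are centred only. Population SD (divide by n) so a {1,3} pair maps to
# {-1,+1}.
zscore_within <- function(x, group) {
  out <- x
  for (g in unique(group)) {
    i <- group == g
    mu <- mean(x[i])
    sdv <- sqrt(mean((x[i] - mu)^2))
    out[i] <- if (sdv > 0) (x[i] - mu) / sdv else x[i] - mu
  }
  out
}

#' Standardise peak heights within electrodes, subjects, and the dataset
#'
#' Sequential z-scoring of the `height` column: first within electrodes,
#' then within subjects, then across the whole dataset, each stage
#' subtracting the group mean and dividing by the group (population) SD.
#' Degenerate groups (single peak, or zero spread) are centred only.
#' Winner-takes-all dominance within a channel is invariant to this
#' standardisation, which maps all of a channel's peaks through one
#' increasing affine transform per stage.
#'
#' @param peak_table output of [cohort_band_peaks()].
#' @param levels which grouping stages to apply, in order.
#' @return `peak_table` with an added `height_z` column.
#' @export
zscore_peak_heights <- function(peak_table,
                                levels = c("electrode", "subject", "dataset")) {
  if (!nrow(peak_table)) stop("empty peak table")
  z <- peak_table$height
  for (lv in levels) {
    grp <- switch(lv,
                  electrode = peak_table$electrode_id,
                  subject = peak_table$subject_id,
                  dataset = rep("all", nrow(peak_table)),
                  stop("unknown level: ", lv))
    z <- zscore_within(z, grp)
  }
  peak_table$height_z <- z
  peak_table
}

#' Winner-takes-all dominant band per channel
#'
#' For each channel, the band whose (standardised) maximum peak height is
#' largest. Ties break toward the lower-frequency band. Channels absent from
#' the peak table (no fitted peak in any band) get `NA`.
#'
#' @param peak_table output of [zscore_peak_heights()] (or
#'   [cohort_band_peaks()]; set `use_z = FALSE` to rank raw heights).
#' @param channel_ids channels to classify (default: those in the table).
#' @param bands band scheme, for the frequency order used in tie-breaks.
#' @param use_z rank standardised (`height_z`) or raw heights.
#' @return Data frame (channel_id, dominant_band).
#' @export
dominant_band <- function(peak_table, channel_ids = NULL,
                          bands = band_scheme(), use_z = TRUE) {
  if (is.null(channel_ids)) channel_ids <- unique(peak_table$channel_id)
  hcol <- if (use_z && "height_z" %in% names(peak_table)) "height_z" else "height"
  band_rank <- stats::setNames(seq_len(nrow(bands)), bands$band)
  dom <- vapply(channel_ids, function(ch) {
    rows <- peak_table[peak_table$channel_id == ch, , drop = FALSE]
    if (!nrow(rows)) return(NA_character_)
    rows <- rows[order(-rows[[hcol]], band_rank[rows$band], rows$center), ,
                 drop = FALSE]
    rows$band[1]
  }, character(1))
  data.frame(channel_id = channel_ids, dominant_band = unname(dom),
             stringsAsFactors = FALSE)
}

#' Map an MNI coordinate to a parcellation label
#'
#' Returns the label of the voxel containing the coordinate; if that voxel is
#' unlabelled, the nearest labelled voxel center within `max_dist_mm`; else
#' `"unlabelled"`. Coordinates outside the image bounding box return
#' `"unlabelled"` with a warning.
#'
#' @param mni_xyz length-3 mm coordinate (or n-by-3 matrix).
#' @param parcellation a [parcellation()] object.
#' @param max_dist_mm search radius for the nearest labelled voxel.
#' @return Character vector of region names (and attribute `"lobe"` when the
#'   lookup has a `lobe` column).
#' @export
assign_region <- function(mni_xyz, parcellation, max_dist_mm = 5) {
  stopifnot(inherits(parcellation, "parcellation"))
  xyz <- matrix(as.numeric(mni_xyz), ncol = 3)
  img <- parcellation$image
  lab <- round(img$values)
  d <- dim(lab)
  lut <- parcellation$lookup
  labelled_idx <- which(lab > 0)
  lab_mm <- NULL
  name_of <- function(l) {
    i <- match(l, lut$label)
    if (is.na(i)) "unlabelled" else lut$name[i]
  }
  out <- character(nrow(xyz))
  for (r in seq_len(nrow(xyz))) {
    v <- round(mm_to_vox(xyz[r, , drop = FALSE], img$affine))
    if (any(v < 0) || any(v > d - 1L)) {
      warning(sprintf("coordinate (%g, %g, %g) outside image bounding box",
                      xyz[r, 1], xyz[r, 2], xyz[r, 3]))
      out[r] <- "unlabelled"
      next
    }
    l <- lab[v[1] + 1L, v[2] + 1L, v[3] + 1L]
    if (l > 0) { out[r] <- name_of(l); next }
    if (!length(labelled_idx)) { out[r] <- "unlabelled"; next }
    if (is.null(lab_mm))
      lab_mm <- vox_to_mm(arrayInd(labelled_idx, d) - 1L, img$affine)
    dist2 <- (lab_mm[, 1] - xyz[r, 1])^2 + (lab_mm[, 2] - xyz[r, 2])^2 +
      (lab_mm[, 3] - xyz[r, 3])^2
    j <- which.min(dist2)
    out[r] <- if (dist2[j] <= max_dist_mm^2) name_of(lab[labelled_idx[j]])
    else "unlabelled"
  }
  lobe <- if ("lobe" %in% names(lut))
    ifelse(out == "unlabelled", "unlabelled",
           lut$lobe[match(out, lut$name)])
  else NULL
  if (!is.null(lobe)) attr(out, "lobe") <- lobe
  out
}

#' Hemisphere from the sign of the MNI x coordinate
#' @param x_mm numeric vector of x coordinates; `|x| <= midline_mm` is
#'   midline.
#' @param midline_mm half-width of the midline strip.
#' @return Character vector `"L"`, `"R"`, or `"midline"`.
#' @export
hemisphere_of <- function(x_mm, midline_mm = 2) {
  ifelse(abs(x_mm) <= midline_mm, "midline", ifelse(x_mm < 0, "L", "R"))
}

#' Tabulate dominant rhythms by group
#'
#' Counts and within-group percentages of each dominant band, one row per
#' group. Channels with no dominant band (no fitted peak) are counted in the
#' group total but in no band column, so percentages sum to <= 100%.
#'
#' @param cohort data frame with `dominant_band` and the grouping column.
#' @param group_by name of the grouping column (e.g. `"lobe"`, `"region"`,
#'   `"electrode_type"`, `"hemisphere"`).
#' @param bands band scheme (column order of the output).
#' @return Data frame: group, n_channels, then `<band>_n` and `<band>_pct`
#'   per band. Empty groups are omitted.
#' @export
tabulate_dominance <- function(cohort, group_by = "lobe",
                               bands = band_scheme()) {
  if (!group_by %in% names(cohort))
    stop("no column `", group_by, "` in cohort")
  grp <- cohort[[group_by]]
  out <- NULL
  for (g in sort(unique(grp))) {
    sub <- cohort[grp == g, , drop = FALSE]
    if (!nrow(sub)) next
    row <- data.frame(group = g, n_channels = nrow(sub),
                      stringsAsFactors = FALSE)
    for (b in bands$band) {
      nb <- sum(sub$dominant_band == b, na.rm = TRUE)
      row[[paste0(b, "_n")]] <- nb
      row[[paste0(b, "_pct")]] <- round(100 * nb / nrow(sub), 2)
    }
    out <- rbind(out, row)
  }
  names(out)[1] <- group_by
  rownames(out) <- NULL
  out
}

#' Two-proportion chi-square test of hemispheric asymmetry for one band
#'
#' Compares the fraction of channels dominant in `band` between left and
#' right hemispheres (midline channels excluded) with a 2x2 chi-square test
#' without continuity correction.
#'
#' @param cohort data frame with `dominant_band` and `hemisphere` columns
#'   (`"L"`/`"R"`/`"midline"`).
#' @param band band name to test.
#' @return List: `statistic` (chi-square), `df`, `p_value`, and the 2x2
#'   `table` (hemisphere x band-dominant yes/no).
#' @export
hemisphere_test <- function(cohort, band = "beta") {
  sub <- cohort[cohort$hemisphere %in% c("L", "R"), , drop = FALSE]
  nL <- sum(sub$hemisphere == "L"); nR <- sum(sub$hemisphere == "R")
  if (nL == 0 || nR == 0) stop("both hemispheres must be represented")
  tab <- table(factor(sub$hemisphere, c("L", "R")),
               factor(sub$dominant_band == band, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0)) stop("both hemispheres must be represented")
  # identical proportions give chi-square 0, p = 1; chisq.test warns when
  # expected counts are small, which is informative, not an error
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat <- unname(ht$statistic)
  if (is.nan(stat)) stat <- 0
  list(statistic = stat, df = unname(ht$parameter),
       p_value = if (is.nan(ht$p.value)) 1 else ht$p.value, table = tab)
}

#' Classify a whole cohort end to end
#'
#' Convenience wrapper: per-band maximum peaks, sequential height
#' standardisation, winner-takes-all dominance, hemisphere labels.
#'
#' @param fits named list of [spectral_fit()] objects.
#' @param channels cohort channel table (channel_id, subject_id,
#'   electrode_id, x_mm, ...).
#' @param bands a [band_scheme()].
#' @param zscore_levels standardisation stages, in order.
#' @return `channels` with added `dominant_band` and `hemisphere` columns.
#' @export
classify_dominance <- function(fits, channels, bands = band_scheme(),
                               zscore_levels = c("electrode", "subject",
                                                 "dataset")) {
  pt <- cohort_band_peaks(fits, channels, bands)
  if (nrow(pt)) pt <- zscore_peak_heights(pt, zscore_levels)
  dom <- dominant_band(pt, channel_ids = channels$channel_id, bands = bands)
  channels$dominant_band <- dom$dominant_band[match(channels$channel_id,
                                                    dom$channel_id)]
  channels$hemisphere <- hemisphere_of(channels$x_mm)
  channels
}
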