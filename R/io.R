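# File formats: TSV channel tables, JSON-lines streamlines, JSON model and
# provenance sidecars, TSV spectra. NIfTI I/O lives in volume.R.

#' Write a channel table as TSV
#' @param channels data frame with at least channel_id, subject_id, x_mm,
#'   y_mm, z_mm, electrode_type, fs_hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel_table <- function(channels, path) {
  utils::write.table(channels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a channel table from TSV
#'
#' Rows with missing or non-numeric coordinates are rejected with a warning
#' naming the offending line.
#'
#' @param path TSV path with a header row.
#' @return Data frame of valid rows.
#' @export
read_channel_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("channel_id", "subject_id", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("channel table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  bad <- !is.finite(suppressWarnings(as.numeric(df$x_mm))) |
    !is.finite(suppressWarnings(as.numeric(df$y_mm))) |
    !is.finite(suppressWarnings(as.numeric(df$z_mm)))
  if (any(bad)) {
    for (i in which(bad))
      warning(sprintf("%s line %d: missing coordinate; row rejected",
                      path, i + 1L))                 # +1 for the header
    df <- df[!bad, , drop = FALSE]
  }
  df$x_mm <- as.numeric(df$x_mm); df$y_mm <- as.numeric(df$y_mm)
  df$z_mm <- as.numeric(df$z_mm)
  rownames(df) <- NULL
  df
}

#' Write streamlines as JSON lines
#'
#' One JSON object per line: `{"points": [[x,y,z], ...]}` with coordinates
#' in MNI mm. A plain-text, easily diffable polyline format.
#'
#' @param streamlines a [streamline_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(streamlines, path) {
  stopifnot(inherits(streamlines, "streamline_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (sl in streamlines) {
    writeLines(jsonlite::toJSON(list(points = unname(as.matrix(sl))),
                                digits = NA), con)
  }
  invisible(path)
}

#' Read streamlines from JSON lines
#' @param path path written by [write_streamlines()].
#' @return A [streamline_set()].
#' @export
read_streamlines <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sl <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop(sprintf("%s line %d: malformed JSON (%s)",
                                   path, i, conditionMessage(e))))
    if (is.null(obj$points))
      stop(sprintf("%s line %d: missing 'points' field", path, i))
    matrix(as.numeric(obj$points), ncol = 3)
  })
  streamline_set(sl)
}

#' Write a power spectrum as two-column TSV (freq_hz, power)
#' @param spectrum a [power_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(data.frame(freq_hz = spectrum$freqs,
                                power = spectrum$power),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a power spectrum from TSV
#' @param path path written by [write_spectrum()].
#' @return A [power_spectrum()].
#' @export
read_spectrum <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("freq_hz", "power") %in% names(df)))
    stop("spectrum file ", path, " needs columns freq_hz, power")
  power_spectrum(df$freq_hz, df$power)
}

#' Serialise a fitted spectral model (with its settings) to JSON
#' @param fit a [spectral_fit()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectral_fit <- function(fit, path) {
  stopifnot(inherits(fit, "spectral_fit"))
  obj <- list(aperiodic = fit$aperiodic,
              peaks = fit$peaks,
              fit_error = fit$fit_error,
              settings = unclass(fit$settings),
              freq_range = range(fit$freqs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a serialised spectral model
#' @param path path written by [write_spectral_fit()].
#' @return List with aperiodic, peaks, fit_error, settings, freq_range.
#' @export
read_spectral_fit <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$aperiodic))
    stop("model file ", path, " lacks an 'aperiodic' field")
  obj$peaks <- as.data.frame(obj$peaks)
  if (!nrow(obj$peaks))
    obj$peaks <- data.frame(center = numeric(), height = numeric(),
                            width = numeric())
  obj$settings$max_n_peaks <- if (is.null(obj$settings$max_n_peaks))
    Inf else as.numeric(obj$settings$max_n_peaks)
  obj
}

#' Write a provenance sidecar for a pipeline artefact
#' @param path JSON output path.
#' @param config the pipeline configuration used.
#' @param extra named list of extra fields (seeds, stage, versions).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, extra = list()) {
  obj <- c(list(package = "oscillonet",
                version = as.character(utils::packageVersion("oscillonet")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                config = unclass(config)),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
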