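# Plain-text spectrum files: '#'-prefixed key = value metadata lines, then
# two whitespace-separated columns (0-based channel index, integer counts).

#' Write a lifetime spectrum to a plain-text file
#'
#' @param spectrum A `pals_spectrum` (or data frame with `channel` and
#'   `counts` plus settings passed explicitly).
#' @param path Output file path.
#' @param settings Acquisition settings; defaults to the attached metadata.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, settings = NULL) {
  settings <- settings %||% attr(spectrum, "settings")
  if (is.null(settings)) abort("No acquisition settings to write.")
  seed <- attr(spectrum, "seed") %||% NA_integer_
  meta <- c(
    sprintf("# channel_width_ps = %.10g", settings$channel_width),
    sprintf("# n_channels = %d", settings$n_channels),
    sprintf("# t0_channel = %.10g", settings$t0_channel),
    sprintf("# irf_fwhm_ps = %.10g", settings$irf_fwhm),
    sprintf("# total_counts = %.10g", settings$total_counts),
    sprintf("# background_fraction = %.10g", settings$background_fraction),
    sprintf("# seed = %s", format(seed)),
    "# columns: channel counts (channel centers at t = (channel - t0_channel) * channel_width)"
  )
  body <- sprintf("%d %d", spectrum$channel, spectrum$counts)
  writeLines(c(meta, body), path)
  invisible(path)
}

#' Read a plain-text lifetime spectrum
#'
#' @param path File written by [write_spectrum()] (or any two-column
#'   channel/counts file with `# key = value` metadata lines).
#' @return A `pals_spectrum` with reconstructed acquisition settings.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines,
                   regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(\\S+)", meta_lines))
  kv <- kv[lengths(kv) == 3L]
  meta <- stats::setNames(
    vapply(kv, `[`, "", 3L),
    vapply(kv, `[`, "", 2L)
  )
  num <- function(key, default) {
    if (key %in% names(meta)) as.numeric(meta[[key]]) else default
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  cols <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  channel <- as.integer(cols[, 1])
  counts <- as.integer(cols[, 2])
  settings <- acquisition(
    channel_width = num("channel_width_ps", 6.5),
    n_channels = num("n_channels", length(counts)),
    total_counts = num("total_counts", max(sum(counts), 1)),
    t0_channel = num("t0_channel", which.max(counts) - 1L),
    irf_fwhm = num("irf_fwhm_ps", 250),
    background_fraction = num("background_fraction", 0)
  )
  if (length(counts) != settings$n_channels) {
    abort("Channel count in file body disagrees with n_channels metadata.")
  }
  seed <- suppressWarnings(as.integer(meta["seed"]))
  w_ns <- settings$channel_width / 1000
  out <- tibble::tibble(
    channel = channel,
    time_ns = (channel - settings$t0_channel) * w_ns,
    counts = counts
  )
  new_pals_spectrum(out, settings, if (length(seed)) seed else NA_integer_)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; list-valued keys
#' (`lifetimes`, `intensities`) are comma-separated.
#'
#' @param path Config file path.
#' @return A named list with numeric scalars/vectors where values parse as
#'   numbers, character otherwise.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L) abort(sprintf("Malformed config line: '%s'", ln))
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    numv <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(numv)) numv else vals
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param config Named list of scalars or numeric vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 15, trim = TRUE),
                                collapse = ", "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# CSV with '#'-prefixed provenance header lines, then a standard CSV body.
write_csv_report <- function(data, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline CSV report
#'
#' Reads the fit, free-volume or summary CSVs written by [run_pipeline()],
#' skipping their provenance header lines.
#'
#' @param path Path to a report CSV.
#' @return A tibble.
#' @export
read_report <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
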