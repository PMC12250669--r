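# Delimited-text readers and writers. All readers sniff the delimiter
# (comma, tab or semicolon) from the first non-comment line, validate the
# schema, and report violations with row numbers. Units are fixed: degrees
# C, nm, minutes -- no auto-conversion.

sniff_delimiter <- function(path) {
  lines <- readLines(path, n = 50, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) mf_stop(sprintf("'%s' has no data lines", path))
  header <- lines[1]
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
              ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))))
  if (all(counts == 0)) mf_stop(sprintf("cannot sniff a delimiter in '%s'", path))
  names(counts)[which.max(counts)]
}

read_header_metadata <- function(path) {
  lines <- readLines(path, n = 50, warn = FALSE)
  meta_lines <- grep("^#\\s*[A-Za-z_.]+\\s*=", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (is.na(num)) val else num
  }
  meta
}

read_delimited <- function(path, required, numeric_cols = required,
                           non_negative = character()) {
  if (!file.exists(path)) mf_stop(sprintf("input file '%s' does not exist", path))
  sep <- sniff_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    mf_stop(sprintf("'%s' is missing column(s): %s", path,
                    paste(missing, collapse = ", ")))
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      mf_stop(sprintf("'%s' row %d: column '%s' is not numeric", path, bad[1], col))
    }
    if (anyNA(v)) {
      mf_stop(sprintf("'%s' row %d: column '%s' is missing", path,
                      which(is.na(v))[1], col))
    }
    df[[col]] <- v
  }
  for (col in intersect(non_negative, names(df))) {
    bad <- which(df[[col]] < 0)
    if (length(bad) > 0) {
      mf_stop(sprintf("'%s' row %d: negative intensity in column '%s'",
                      path, bad[1], col))
    }
  }
  df
}

#' Read a polarized-intensity table
#'
#' Delimited text with columns `temperature_C`, `i_vv`, `i_vh`, `i_hv`,
#' `i_hh` and optional `replicate`. Negative intensities are rejected with
#' the offending row number.
#'
#' @param path File path (CSV/TSV, delimiter sniffed).
#' @return Data frame of polarized readings.
#' @export
read_polarized_table <- function(path) {
  df <- read_delimited(path,
                       required = c("temperature_C", "i_vv", "i_vh", "i_hv", "i_hh"),
                       non_negative = c("i_vv", "i_vh", "i_hv", "i_hh"))
  if (is.null(df$replicate)) df$replicate <- 1L
  df
}

#' Read an anisotropy curve
#'
#' Columns `temperature_C`, `r`, optional `sd` and `n`; temperatures must
#' be strictly increasing.
#'
#' @param path File path.
#' @return An [anisotropy_curve()].
#' @export
read_anisotropy_curve <- function(path) {
  df <- read_delimited(path, required = c("temperature_C", "r"))
  anisotropy_curve(df$temperature_C, df$r,
                   if (is.null(df$sd)) NA_real_ else df$sd,
                   if (is.null(df$n)) 1L else df$n)
}

#' Read an emission spectrum
#'
#' Columns `wavelength_nm`, `intensity`; header metadata lines in comment
#' syntax (`# excitation_nm=355`, `# temperature_C=37`) are parsed into
#' attributes.
#'
#' @param path File path.
#' @return An [emission_spectrum()].
#' @export
read_spectrum <- function(path) {
  df <- read_delimited(path, required = c("wavelength_nm", "intensity"),
                       non_negative = "intensity")
  meta <- read_header_metadata(path)
  emission_spectrum(df$wavelength_nm, df$intensity,
                    excitation_nm = meta$excitation_nm %||% NA_real_,
                    temperature = meta$temperature_C %||% NA_real_)
}

#' Read oxidation time series
#'
#' Accepts long format (`time_min`, `fluorescence`, `label`) or wide format
#' (`time_min` plus one fluorescence column per sample).
#'
#' @param path File path.
#' @return Named list of [oxidation_series()] objects.
#' @export
read_oxidation_table <- function(path) {
  df <- read_delimited(path, required = "time_min", numeric_cols = "time_min")
  if (all(c("fluorescence", "label") %in% names(df))) {
    df$fluorescence <- as.numeric(df$fluorescence)
    out <- lapply(split(df, df$label), function(d) {
      d <- d[order(d$time_min), ]
      oxidation_series(d$time_min, d$fluorescence, label = d$label[1])
    })
    return(out)
  }
  value_cols <- setdiff(names(df), "time_min")
  if (length(value_cols) == 0) mf_stop(sprintf("'%s' has no fluorescence columns", path))
  df <- df[order(df$time_min), ]
  out <- lapply(value_cols, function(col) {
    oxidation_series(df$time_min, as.numeric(df[[col]]), label = col)
  })
  stats::setNames(out, value_cols)
}

#' Read a tidy replicate table for group comparisons
#'
#' Long format with columns `group` and `value` (optional `sample`,
#' `replicate`).
#'
#' @param path File path.
#' @return Data frame with `group` and `value`.
#' @export
read_group_table <- function(path) {
  df <- read_delimited(path, required = c("group", "value"),
                       numeric_cols = "value")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a, for a short config fingerprint in output headers (no external
# digest dependency; not cryptographic).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(x)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a result table with a commented provenance header
#'
#' Delimited text (CSV) preceded by comment lines recording the package
#' version, seed and config fingerprint, so any output can be traced to the
#' run that produced it. Timestamps are deliberately excluded: re-running
#' with the same config and seed yields byte-identical files.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param config Config object fingerprinted in the header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# membrafluor_version=%s",
            as.character(utils::packageVersion("membrafluor"))),
    sprintf("# seed=%s", seed),
    sprintf("# config_hash=%s", if (is.null(config)) "none" else fnv1a_hash(config))
  ), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an emission spectrum with metadata header
#' @param spectrum An [emission_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ex <- attr(spectrum, "excitation_nm")
  if (!is.null(ex) && !is.na(ex)) writeLines(sprintf("# excitation_nm=%g", ex), con)
  tc <- attr(spectrum, "temperature")
  if (!is.null(tc) && !is.na(tc)) writeLines(sprintf("# temperature_C=%g", tc), con)
  utils::write.table(as.data.frame(spectrum), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a truth manifest as JSON
#' @param truth Named list of ground-truth parameters.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
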