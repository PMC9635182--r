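# On-disk formats. All files are comma-delimited text with ISO-8601 UTC
# timestamps, wet coded 0/1 and "NA" as the missing token. Readers validate
# the data model; gaps in the 10-s cadence are tolerated and reported, never
# interpolated.

.record_cols <- c("bird_id", "timestamp_utc", "depth_m", "temp_c", "wet", "light_raw")
.position_cols <- c("bird_id", "date", "lat", "lon", "source")
.covariate_cols <- c("date", "year", "doy", "moon", "nao")
.summary_cols <- c(
  "bird_id", "date", "sst_c", "t_fly_h", "t_dive_h", "t_rest_h", "t_swim_h",
  "dive_day_h", "dive_civil_h", "dive_naut_h", "dive_night_h", "n_dives",
  "dee_kj", "dee5_kj", "td5_h", "aei_kj_per_h", "doy", "moon", "nao",
  "year", "state"
)

.check_header <- function(got, want, path) {
  if (!identical(got, want)) {
    stop(sprintf("'%s': expected header %s, found %s", path,
                 paste(want, collapse = ","), paste(got, collapse = ",")),
         call. = FALSE)
  }
}

# validate the header before fread sees the file, so schema errors are
# reported as such rather than as parse failures
.pre_check_header <- function(path, want) {
  first <- readLines(path, n = 1L)
  .check_header(strsplit(first, ",", fixed = TRUE)[[1]], want, path)
}

.parse_utc <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  out
}

#' Read raw logger records
#'
#' Reads a `records.csv` file (columns `bird_id, timestamp_utc, depth_m,
#' temp_c, wet, light_raw`), validates it against the logger data model and
#' returns one `data.frame` sorted by bird and timestamp. Within each bird,
#' timestamps must be strictly increasing; depth must be non-negative; wet
#' must be coded 0/1. Gaps relative to the nominal cadence are allowed and
#' summarised in the `gap_report` attribute.
#'
#' @param path Path to the file.
#' @param cadence_s Nominal sampling interval in seconds (default 10).
#' @return A `data.frame` with columns `bird_id` (character), `timestamp`
#'   (POSIXct UTC), `depth` (m), `temp` (deg C), `wet` (logical),
#'   `light_raw`; attribute `gap_report` is a per-bird data.frame with
#'   `n_gaps` and `max_gap_s`.
#' @export
read_logger_records <- function(path, cadence_s = 10) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  .pre_check_header(path, .record_cols)
  dt <- data.table::fread(path, colClasses = list(character = c("bird_id", "timestamp_utc")),
                          na.strings = "NA", showProgress = FALSE)
  .check_header(names(dt), .record_cols, path)
  ts <- .parse_utc(dt$timestamp_utc)
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop(sprintf("'%s' line %d: malformed timestamp '%s'", path,
                 bad[1] + 1L, dt$timestamp_utc[bad[1]]), call. = FALSE)
  }
  if (!is.numeric(dt$depth_m)) stop(sprintf("'%s': non-numeric depth_m", path), call. = FALSE)
  bad <- which(dt$depth_m < 0)
  if (length(bad)) {
    stop(sprintf("'%s' line %d: negative depth %.3f", path, bad[1] + 1L,
                 dt$depth_m[bad[1]]), call. = FALSE)
  }
  bad <- which(!(dt$wet %in% c(0L, 1L)))
  if (length(bad)) {
    stop(sprintf("'%s' line %d: wet must be coded 0/1, found '%s'", path,
                 bad[1] + 1L, as.character(dt$wet[bad[1]])), call. = FALSE)
  }
  rec <- data.frame(
    bird_id = dt$bird_id, timestamp = ts, depth = dt$depth_m,
    temp = dt$temp_c, wet = dt$wet == 1L, light_raw = dt$light_raw,
    stringsAsFactors = FALSE
  )
  rec <- rec[order(rec$bird_id, rec$timestamp), , drop = FALSE]
  rownames(rec) <- NULL
  gaps <- lapply(split(rec$timestamp, rec$bird_id), function(t) {
    d <- diff(as.numeric(t))
    if (any(d <= 0)) stop(sprintf("duplicate or non-increasing timestamps within a bird in '%s'", path), call. = FALSE)
    data.frame(n_gaps = sum(d > cadence_s), max_gap_s = if (length(d)) max(d) else NA_real_)
  })
  gr <- do.call(rbind, gaps)
  gr <- data.frame(bird_id = rownames(gr), gr, row.names = NULL)
  attr(rec, "gap_report") <- gr
  rec
}

#' Write raw logger records
#'
#' Inverse of [read_logger_records()]; `write` then `read` reproduces the
#' numeric values bit-exactly (numbers are written with full precision).
#'
#' @param records Data frame as returned by [read_logger_records()] or the
#'   simulator.
#' @param path Output path.
#' @export
write_logger_records <- function(records, path) {
  out <- data.table::data.table(
    bird_id = records$bird_id,
    timestamp_utc = format(records$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    depth_m = records$depth,
    temp_c = records$temp,
    wet = as.integer(records$wet),
    light_raw = if ("light_raw" %in% names(records)) records$light_raw else NA_real_
  )
  data.table::fwrite(out, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read daily positions
#'
#' @param path Path to a `positions.csv` file with columns
#'   `bird_id, date, lat, lon, source`.
#' @return Data frame with one row per bird-date; coordinates validated.
#' @export
read_positions <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c("bird_id", "date", "source")),
                          na.strings = "NA", showProgress = FALSE)
  .check_header(names(dt), .position_cols, path)
  pos <- as.data.frame(dt)
  pos$date <- as.Date(pos$date)
  if (anyNA(pos$date)) stop(sprintf("'%s': malformed date", path), call. = FALSE)
  ok <- is.na(pos$lat) | (pos$lat >= -90 & pos$lat <= 90 & pos$lon >= -180 & pos$lon <= 180)
  if (!all(ok)) stop(sprintf("'%s' line %d: coordinates out of range", path, which(!ok)[1] + 1L), call. = FALSE)
  if (anyDuplicated(pos[c("bird_id", "date")])) {
    stop(sprintf("'%s': duplicate bird-date rows", path), call. = FALSE)
  }
  pos
}

#' Write daily positions
#' @param positions Data frame with columns `bird_id, date, lat, lon, source`.
#' @param path Output path.
#' @export
write_positions <- function(positions, path) {
  out <- data.table::as.data.table(positions[, c("bird_id", "date", "lat", "lon", "source")])
  out$date <- format(as.Date(out$date))
  data.table::fwrite(out, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read daily covariates
#'
#' @param path Path to a `covariates.csv` file with columns
#'   `date, year, doy, moon, nao`. `year` is a two-level factor coded by
#'   calendar year; `moon` must lie in \[0, 1\].
#' @return Data frame with one row per date.
#' @export
read_covariates <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "date"),
                          na.strings = "NA", showProgress = FALSE)
  .check_header(names(dt), .covariate_cols, path)
  cov <- as.data.frame(dt)
  cov$date <- as.Date(cov$date)
  if (anyNA(cov$date)) stop(sprintf("'%s': malformed date", path), call. = FALSE)
  if (anyDuplicated(cov$date)) stop(sprintf("'%s': duplicate dates", path), call. = FALSE)
  if (any(cov$moon < 0 | cov$moon > 1, na.rm = TRUE)) {
    stop(sprintf("'%s': moon fraction outside [0, 1]", path), call. = FALSE)
  }
  cov[order(cov$date), , drop = FALSE]
}

#' Write daily covariates
#' @param covariates Data frame with columns `date, year, doy, moon, nao`.
#' @param path Output path.
#' @export
write_covariates <- function(covariates, path) {
  out <- data.table::as.data.table(covariates[, .covariate_cols])
  out$date <- format(as.Date(out$date))
  data.table::fwrite(out, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Write daily summaries
#'
#' Writes the model-ready bird-day table (one row per bird-date). Missing
#' SST, DEE or AEI are written as the missing token `NA`, never as zero.
#'
#' @param summaries Data frame with the `daily_summary.csv` column set (see
#'   Details); extra columns are dropped, missing optional columns are
#'   filled with `NA`.
#' @param path Output path.
#' @details Columns: `bird_id, date, sst_c, t_fly_h, t_dive_h, t_rest_h,
#'   t_swim_h, dive_day_h, dive_civil_h, dive_naut_h, dive_night_h, n_dives,
#'   dee_kj, dee5_kj, td5_h, aei_kj_per_h, doy, moon, nao, year, state`.
#' @export
write_daily_summaries <- function(summaries, path) {
  if (nrow(summaries) && anyDuplicated(summaries[c("bird_id", "date")])) {
    stop("duplicate bird-date rows in daily summaries", call. = FALSE)
  }
  out <- data.table::as.data.table(summaries)
  for (cc in setdiff(.summary_cols, names(out))) out[[cc]] <- NA
  out <- out[, .summary_cols, with = FALSE]
  out$date <- format(as.Date(out$date))
  data.table::fwrite(out, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read daily summaries
#' @param path Path to a `daily_summary.csv` file.
#' @return Data frame with one row per bird-date.
#' @export
read_daily_summaries <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c("bird_id", "date")),
                          na.strings = "NA", showProgress = FALSE)
  .check_header(names(dt), .summary_cols, path)
  out <- as.data.frame(dt)
  out$date <- as.Date(out$date)
  out
}
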