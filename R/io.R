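# File formats: the sensor-stream CSV dialect, run configuration (YAML),
# and result writers. The CSV dialect is comma-separated with a dot decimal
# mark and a mandatory header; timestamps are ISO 8601 in local pond time.

.SENSOR_MANDATORY <- c("timestamp", "do_mg_l", "temp_c")
.SENSOR_OPTIONAL <- c("chl_ug_l", "secchi_m", "ph_surface", "ph_bottom",
                      "source_id")

#' Read a sensor-stream CSV
#'
#' Parses and validates timestamped sensor records. Mandatory columns:
#' `timestamp` (ISO 8601), `do_mg_l`, `temp_c`; optional: `chl_ug_l`,
#' `secchi_m`, `ph_surface`, `ph_bottom`, `source_id`. In strict mode any
#' invalid row (unparseable timestamp, non-numeric or negative DO,
#' non-monotone time within a source) aborts with the offending line number;
#' in lenient mode invalid rows are dropped with a warning each.
#'
#' @param path CSV file path.
#' @param strict Abort on invalid rows (default) or skip them.
#' @param tz Time zone of the pond clock (default `"UTC"`).
#' @return Data frame of records with a POSIXct `timestamp` and a numeric
#'   `time` column (days since the first record).
#' @export
read_sensor_csv <- function(path, strict = TRUE, tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.SENSOR_MANDATORY, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  unknown <- setdiff(names(raw), c(.SENSOR_MANDATORY, .SENSOR_OPTIONAL))
  if (length(unknown))
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  n <- nrow(raw)
  ts <- as.POSIXct(raw$timestamp, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  bad <- is.na(ts)
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  do_v <- num("do_mg_l"); temp_v <- num("temp_c")
  bad <- bad | is.na(do_v) | is.na(temp_v) | do_v < 0
  if (any(bad)) {
    lines <- which(bad) + 1L   # header is line 1
    if (strict)
      stop("invalid row(s) at line(s) ", paste(lines, collapse = ", "),
           " of ", path)
    for (l in lines) warning("skipping invalid row at line ", l, call. = FALSE)
  }
  rec <- data.frame(timestamp = ts, do_mg_l = do_v, temp_c = temp_v)
  for (col in .SENSOR_OPTIONAL) {
    if (col %in% names(raw))
      rec[[col]] <- if (col == "source_id") raw[[col]] else num(col)
  }
  rec <- rec[!bad, , drop = FALSE]
  if (!nrow(rec)) stop("no valid records in ", path)
  srcs <- if ("source_id" %in% names(rec)) rec$source_id else rep("", nrow(rec))
  for (s in unique(srcs)) {
    tt <- rec$timestamp[srcs == s]
    if (length(tt) > 1L && any(diff(as.numeric(tt)) <= 0)) {
      off <- which(diff(as.numeric(tt)) <= 0)[1] + 1L
      msg <- paste0("non-monotone timestamps (record ", off,
                    if (nzchar(s)) paste0(" of source ", s), ")")
      if (strict) stop(msg) else warning(msg, call. = FALSE)
    }
  }
  rec$time <- as.numeric(difftime(rec$timestamp, rec$timestamp[1],
                                  units = "days"))
  rec
}

#' Write measurement records as a sensor-stream CSV
#'
#' @param records Data frame with a POSIXct `timestamp` (or numeric `time`
#'   in days, converted using `t_origin`) plus the sensor channels.
#' @param path Output file.
#' @param t_origin Origin timestamp used when only fractional-day `time` is
#'   present.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(records, path,
                             t_origin = as.POSIXct("2025-09-01 00:00:00",
                                                   tz = "UTC")) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (!"timestamp" %in% names(records)) {
    if (!"time" %in% names(records)) stop("records need 'timestamp' or 'time'")
    records$timestamp <- t_origin + records$time * 86400
  }
  out <- records[c("timestamp",
                   intersect(c("do_mg_l", "temp_c", .SENSOR_OPTIONAL),
                             names(records)))]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  for (col in names(out))
    if (is.numeric(out[[col]])) out[[col]] <- signif(out[[col]], 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.CONFIG_KEYS <- c("version", "seed", "ecosystem", "forcing", "noise",
                  "filter", "indirect", "species", "schedule", "x0",
                  "decision")

# Apply a config block to a constructor, rejecting unknown keys.
.block <- function(block, fn, name) {
  if (is.null(block)) return(fn())
  known <- names(formals(fn))
  unknown <- setdiff(names(block), known)
  if (length(unknown))
    stop("unknown key(s) in config block '", name, "': ",
         paste(unknown, collapse = ", "))
  do.call(fn, block)
}

#' Read and validate a run configuration
#'
#' A run configuration is a YAML (or JSON) file with blocks `ecosystem`,
#' `forcing`, `noise`, `filter`, `indirect`, `species`, `schedule`, plus
#' `seed`, `x0` and an optional `decision` block. Every block is validated
#' through its type constructor; unknown keys anywhere are an error.
#'
#' @param path Config file path.
#' @return An object of class `run_config` with fully constructed typed
#'   blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  x0 <- if (is.null(cfg$x0)) state_vec(1.5, 0.8, 0.3, 9.0)
        else do.call(state_vec, as.list(setNames(as.numeric(cfg$x0),
                                                 c("P", "Z", "F", "O"))))
  dec <- cfg$decision
  if (!is.null(dec)) {
    known <- c("curve_type", "critical", "preset_lead", "r_min",
               "abs_low", "abs_high", "neighbor_delta", "horizon")
    unknown <- setdiff(names(dec), known)
    if (length(unknown))
      stop("unknown key(s) in config block 'decision': ",
           paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$indirect)) cfg$indirect$quiet <- NULL
  ind <- if (is.null(cfg$indirect)) indirect_coeffs(quiet = TRUE)
         else .block(c(cfg$indirect, list(quiet = TRUE)), indirect_coeffs,
                     "indirect")
  structure(list(
    version = if (is.null(cfg$version)) 1L else cfg$version,
    seed = cfg$seed,
    ecosystem = .block(cfg$ecosystem, ecosystem_params, "ecosystem"),
    forcing = .block(cfg$forcing, temperature_forcing, "forcing"),
    noise = .block(c(cfg$noise, list(seed = cfg$seed)), noise_spec, "noise"),
    filter = .block(cfg$filter, filter_config, "filter"),
    indirect = ind,
    species = .block(cfg$species, species_limits, "species"),
    schedule = .block(cfg$schedule, sampling_schedule, "schedule"),
    x0 = x0,
    decision = dec,
    path = path), class = "run_config")
}

#' Write run results to CSV or JSON
#'
#' Deterministic column order; floating point written with 6 significant
#' digits; the JSON schema carries a version tag.
#'
#' @param results A data frame (trajectory, records, filter estimates) or a
#'   list of scalars/vectors.
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_outputs <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "ekf_run")) results <- results$estimates
  if (is.data.frame(results)) {
    if (!nrow(results)) stop("refusing to write empty results")
  } else if (!length(results)) stop("refusing to write empty results")
  if (format == "csv") {
    if (!is.data.frame(results)) stop("csv output requires tabular results")
    out <- results
    for (col in names(out))
      if (is.numeric(out[[col]])) out[[col]] <- signif(out[[col]], 6)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    payload <- list(schema = "pondcast/1", results = results)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 6,
                         na = "null", POSIXt = "ISO8601")
  }
  invisible(path)
}

# Provenance line for run logs: package version, seed, config file hash.
.provenance <- function(config_path = NULL, seed = NULL) {
  hash <- if (!is.null(config_path) && file.exists(config_path))
    unname(tools::md5sum(config_path)) else NA_character_
  sprintf("pondcast %s | seed=%s | config_md5=%s",
          as.character(utils::packageVersion("pondcast")),
          if (is.null(seed)) "none" else seed, hash)
}
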