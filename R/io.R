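# File formats: CSV dialects for detections, fixes and truth tracks; GPX 1.1
# export; GeoJSON-style polygon files; YAML run configuration; JSON run
# manifests. All CSVs are UTF-8 with '.' decimal separators regardless of
# locale (readr/readr defaults guarantee this).

DETECTION_COLS <- c("hydrophone_id", "transmitter_id", "emission_index",
                    "toa_s")
FIX_COLS <- c("transmitter_id", "timestamp_s", "x_m", "y_m", "dop", "cn",
              "rn", "subarray_id", "n_hydrophones")
TRUTH_COLS <- c("time_s", "x_m", "y_m")

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read and write the pipeline's CSV dialects
#'
#' Fixed-header, UTF-8, '.'-decimal CSV files for detection logs, position
#' fixes and truth tracks. Reading validates the header and errors naming
#' any missing column.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return Readers return tibbles; writers return `x` invisibly.
#' @name apt_io
NULL

#' @rdname apt_io
#' @export
write_detections <- function(x, path) {
  check_columns(x, DETECTION_COLS, "detection")
  readr::write_csv(x[, union(DETECTION_COLS, names(x))], path)
  invisible(x)
}

#' @rdname apt_io
#' @export
read_detections <- function(path) {
  x <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         hydrophone_id = readr::col_character(),
                         transmitter_id = readr::col_character(),
                         emission_index = readr::col_integer(),
                         toa_s = readr::col_double(),
                         .default = readr::col_guess())))
  check_columns(x, DETECTION_COLS, "detection")
  x
}

#' @rdname apt_io
#' @export
write_fixes <- function(x, path) {
  check_columns(x, FIX_COLS, "fix")
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname apt_io
#' @export
read_fixes <- function(path) {
  x <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         transmitter_id = readr::col_character(),
                         subarray_id = readr::col_character(),
                         rn = readr::col_integer(),
                         n_hydrophones = readr::col_integer(),
                         .default = readr::col_guess())))
  check_columns(x, FIX_COLS, "fix")
  x
}

#' @rdname apt_io
#' @export
write_truth_track <- function(x, path) {
  check_columns(x, TRUTH_COLS, "truth track")
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname apt_io
#' @export
read_truth_track <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(x, TRUTH_COLS, "truth track")
  x
}

#' Export a truth track as GPX 1.1
#'
#' Local ENU metres are mapped to WGS84 around a reference coordinate with
#' the equirectangular approximation (exact enough at lake scale), producing
#' a schema-valid GPX 1.1 track for interoperability with GIS/GPS tools.
#'
#' @param track Tibble with `time_s`, `x_m`, `y_m`.
#' @param path Output path.
#' @param ref_lat,ref_lon Reference latitude/longitude of the ENU origin.
#' @param t0 POSIXct time of `time_s = 0` (default 2010-09-01 UTC).
#' @return `path`, invisibly.
#' @export
write_gpx <- function(track, path, ref_lat = 52.99, ref_lon = 13.58,
                      t0 = as.POSIXct("2010-09-01", tz = "UTC")) {
  check_columns(track, TRUTH_COLS, "truth track")
  r_earth <- 6378137
  lat <- ref_lat + (track$y_m / r_earth) * 180 / pi
  lon <- ref_lon + (track$x_m / (r_earth * cos(ref_lat * pi / 180))) * 180 / pi
  doc <- xml2::xml_new_root(
    "gpx", version = "1.1", creator = "aptperf",
    xmlns = "http://www.topografix.com/GPX/1/1")
  trk <- xml2::xml_add_child(doc, "trk")
  xml2::xml_add_child(trk, "name", "truth")
  seg <- xml2::xml_add_child(trk, "trkseg")
  stamps <- format(t0 + track$time_s, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  for (i in seq_len(nrow(track))) {
    pt <- xml2::xml_add_child(seg, "trkpt",
                              lat = sprintf("%.8f", lat[i]),
                              lon = sprintf("%.8f", lon[i]))
    xml2::xml_add_child(pt, "time", stamps[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read and write polygon files (GeoJSON-style planar coordinates)
#'
#' @param polygon Tibble with `x`, `y`.
#' @param path File path.
#' @return `read_polygon()` returns the vertex tibble; vertices round-trip
#'   exactly.
#' @export
write_polygon <- function(polygon, path) {
  obj <- list(type = "Polygon",
              coordinates = list(mapply(function(x, y) c(x, y),
                                        polygon$x, polygon$y,
                                        SIMPLIFY = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(polygon)
}

#' @rdname write_polygon
#' @export
read_polygon <- function(path) {
  obj <- jsonlite::read_json(path)
  ring <- obj$coordinates[[1]]
  tibble(x = vapply(ring, function(p) as.numeric(p[[1]]), numeric(1)),
         y = vapply(ring, function(p) as.numeric(p[[2]]), numeric(1)))
}

#' Read a YAML run configuration
#'
#' A run configuration names the scenario (or user data files), filter
#' thresholds, smoother parameters and the seed. The seed is mandatory for
#' any simulation step.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) {
    stop("run configuration must specify an integer `seed`", call. = FALSE)
  }
  cfg
}

# Deterministic manifest describing a simulation run.
run_manifest <- function(scenario, files) {
  cfg_json <- jsonlite::toJSON(scenario$config, auto_unbox = TRUE, digits = NA)
  list(
    scenario = scenario$name,
    seed = scenario$seed,
    config_hash = sprintf("%08x", as.integer(simple_hash(as.character(cfg_json)) %% 2147483647)),
    files = files,
    package_version = as.character(utils::packageVersion("aptperf"))
  )
}

simple_hash <- function(s) {
  h <- 5381
  for (k in utf8ToInt(paste(s, collapse = "\n"))) {
    h <- (h * 33 + k) %% 4294967296
  }
  h
}

#' Simulate a scenario and write its data files
#'
#' Writes the detection log, tow truth tracks (CSV and GPX), depth readings
#' and a JSON manifest (scenario, seed, config hash, package version) into
#' `outdir`. Identical `(scenario, seed)` runs produce identical manifests.
#'
#' @param scenario An [build_scenario()] object.
#' @param outdir Output directory (created if needed).
#' @param overwrite Overwrite existing files (default `FALSE`; refusing to
#'   clobber is the default safety).
#' @return The [apt_simulate()] result, invisibly, with attribute
#'   `"manifest"`.
#' @export
apt_write_run <- function(scenario, outdir, overwrite = FALSE) {
  sim <- apt_simulate(scenario)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(detections = "detections.csv", truth = "truth_tracks.csv",
             depth = "depth_readings.csv", manifest = "manifest.json")
  paths <- file.path(outdir, files)
  if (!overwrite && any(file.exists(paths))) {
    stop("output files exist; use overwrite = TRUE", call. = FALSE)
  }
  write_detections(sim$detections, paths[1])
  if (nrow(sim$truth_tracks) > 0) {
    readr::write_csv(sim$truth_tracks, paths[2])
    first_tow <- sim$truth_tracks %>%
      filter(.data$trial_id == .data$trial_id[1]) %>%
      select("time_s", "x_m", "y_m")
    write_gpx(first_tow, file.path(outdir, "truth_tow1.gpx"))
  }
  readr::write_csv(sim$depth_readings, paths[3])
  manifest <- run_manifest(scenario, unname(files))
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, pretty = TRUE)
  attr(sim, "manifest") <- manifest
  invisible(sim)
}
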