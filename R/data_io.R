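#' Analysis configuration
#'
#' Holds the geographic and filtering conventions used when assembling
#' model-ready data: the regional boundaries, the plausible coordinate
#' bounding box, which footprint scale (1 km or 10 km radius) enters the
#' models, and the minimum number of marked individuals for a station to
#' contribute to the survival analysis.
#'
#' The region rule is: west if longitude is strictly less than
#' `west_boundary` (default -102); otherwise east if latitude is below
#' `east_max_lat` (default 47) and longitude is east of `east_meridian`
#' (default -90); otherwise central. Stations exactly on the western
#' boundary go central.
#'
#' @param west_boundary meridian separating west from central/east.
#' @param east_max_lat latitude below which eastern membership is possible.
#' @param east_meridian meridian east of which (strictly) a low-latitude
#'   station is eastern.
#' @param bbox plausible coordinate bounds `c(lon_min, lon_max, lat_min,
#'   lat_max)`; out-of-bounds coordinates are flagged `NA`, never silently
#'   classified.
#' @param hf_scale `"1km"` or `"10km"`; the two footprint scales are highly
#'   collinear and are always fitted separately.
#' @param min_marked_individuals survival-station inclusion threshold.
#' @return a list with class `"analysis_config"`.
#' @export
analysis_config <- function(west_boundary = -102, east_max_lat = 47,
                            east_meridian = -90,
                            bbox = c(lon_min = -170, lon_max = -50,
                                     lat_min = 20, lat_max = 75),
                            hf_scale = c("1km", "10km"),
                            min_marked_individuals = 5) {
  hf_scale <- match.arg(hf_scale)
  structure(list(west_boundary = west_boundary, east_max_lat = east_max_lat,
                 east_meridian = east_meridian, bbox = bbox,
                 hf_scale = hf_scale,
                 min_marked_individuals = min_marked_individuals),
            class = "analysis_config")
}

#' Read an analysis configuration from a key-value file
#'
#' Parses a flat `key: value` (or `key = value`) text file into an
#' [analysis_config()]. Recognized keys are the constructor's arguments;
#' `bbox` takes four comma-separated numbers (lon_min, lon_max, lat_min,
#' lat_max). Lines starting with `#` are comments; unknown keys raise an
#' error so typos cannot silently fall back to defaults.
#'
#' @param path path to the configuration file.
#' @return an [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.+)$", lines))
  if (any(lengths(kv) != 3)) .stopf("malformed config line: %s",
                                    lines[which(lengths(kv) != 3)[1]])
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  known <- names(formals(analysis_config))
  if (any(!keys %in% known)) {
    .stopf("unknown config key(s): %s",
           paste(setdiff(keys, known), collapse = ", "))
  }
  args <- list()
  for (j in seq_along(keys)) {
    v <- vals[j]
    args[[keys[j]]] <- if (keys[j] == "hf_scale") v
    else if (keys[j] == "bbox") {
      b <- as.numeric(strsplit(v, ",")[[1]])
      stats::setNames(b, c("lon_min", "lon_max", "lat_min", "lat_max"))
    } else as.numeric(v)
  }
  do.call(analysis_config, args)
}

#' Classify stations into breeding regions
#'
#' Assigns each coordinate pair to the west, central or east breeding
#' region using the boundary conventions in [analysis_config()].
#'
#' @param longitude,latitude decimal degrees (vectors of equal length).
#' @param config an [analysis_config()].
#' @return character vector in `{"west","central","east"}`, with `NA` (plus
#'   a warning) for coordinates outside the plausible bounding box.
#' @export
classify_region <- function(longitude, latitude, config = analysis_config()) {
  stopifnot(length(longitude) == length(latitude))
  bad <- longitude < config$bbox[["lon_min"]] | longitude > config$bbox[["lon_max"]] |
    latitude < config$bbox[["lat_min"]] | latitude > config$bbox[["lat_max"]] |
    !is.finite(longitude) | !is.finite(latitude)
  region <- ifelse(longitude < config$west_boundary, "west",
                   ifelse(latitude < config$east_max_lat &
                            longitude > config$east_meridian, "east", "central"))
  if (any(bad)) {
    warning(sprintf("%d coordinate(s) outside plausible bounds; flagged NA",
                    sum(bad)))
    region[bad] <- NA_character_
  }
  region
}

#' Assign a station-level footprint value from the two survey epochs
#'
#' The human-footprint rasters exist for 1993 and 2009 only. A station
#' active in both epoch years gets the average of the two values; any other
#' station gets the value from the epoch year nearest its median active
#' year, with exact ties broken toward 2009.
#'
#' @param active_years integer vector of calendar years the station
#'   operated (non-empty).
#' @param hf_1993,hf_2009 footprint index values for the two epochs.
#' @param station_id optional label used in error messages.
#' @return a single footprint value.
#' @export
assign_footprint_value <- function(active_years, hf_1993, hf_2009,
                                   station_id = NULL) {
  lab <- if (is.null(station_id)) "station" else paste0("station ", station_id)
  if (length(active_years) == 0) .stopf("%s has no active years", lab)
  if (!is.finite(hf_1993) || !is.finite(hf_2009)) {
    .stopf("%s is missing a footprint epoch value", lab)
  }
  if (1993 %in% active_years && 2009 %in% active_years) {
    return((hf_1993 + hf_2009) / 2)
  }
  med <- stats::median(active_years)
  if (abs(med - 1993) < abs(med - 2009)) hf_1993 else hf_2009
}

#' Station-filtering rules for the three analyses
#'
#' `filter_abundance_stations()` keeps stations with at least one captured
#' individual (adult or juvenile) over the study.
#' `filter_productivity_stations()` additionally drops stations whose
#' captures were all juveniles (no adult ever caught), since they carry no
#' information about the juvenile proportion's denominator contrast.
#' `filter_survival_stations()` keeps stations with at least
#' `min_marked` marked individuals across all years.
#'
#' All three are idempotent and return the retained station ids.
#'
#' @param counts adult count table (`station_id`, `adult_count`).
#' @param histories capture-history table (`station_id`, one row per
#'   individual); optional for the abundance filter.
#' @param productivity productivity table (`station_id`, `juveniles`,
#'   `total`).
#' @param min_marked survival inclusion threshold (default 5).
#' @return character vector of retained station ids.
#' @export
filter_abundance_stations <- function(counts, histories = NULL) {
  tot <- tapply(counts$adult_count, counts$station_id, sum)
  keep <- names(tot)[tot >= 1]
  if (!is.null(histories)) {
    keep <- union(keep, unique(as.character(histories$station_id)))
  }
  if (length(keep) == 0) warning("no station has any capture")
  sort(keep)
}

#' @rdname filter_abundance_stations
#' @export
filter_productivity_stations <- function(productivity) {
  adults <- tapply(productivity$total - productivity$juveniles,
                   productivity$station_id, sum)
  total <- tapply(productivity$total, productivity$station_id, sum)
  sort(names(adults)[adults >= 1 & total >= 1])
}

#' @rdname filter_abundance_stations
#' @export
filter_survival_stations <- function(histories, min_marked = 5) {
  n <- table(as.character(histories$station_id))
  sort(names(n)[n >= min_marked])
}

# Scaling constants shared by the generator and the fits: footprint z-scored
# across stations (per scale), effort z-scored across station-years, year
# centered at the study midpoint in units of one year.
.covariate_scaling <- function(stations, effort, first_year, n_years) {
  sc <- list(first_year = first_year, n_years = n_years,
             t_mid = (n_years - 1) / 2)
  for (v in c("hf_1km", "hf_10km")) {
    if (v %in% names(stations)) {
      m <- mean(stations[[v]]); s <- stats::sd(stations[[v]])
      if (!is.finite(s) || s == 0) {
        .stopf("covariate '%s' has zero variance across stations", v)
      }
      sc[[paste0(v, "_mean")]] <- m
      sc[[paste0(v, "_sd")]] <- s
    }
  }
  m <- mean(effort); s <- stats::sd(effort)
  if (!is.finite(s) || s == 0) .stopf("effort has zero variance across station-years")
  sc$effort_mean <- m
  sc$effort_sd <- s
  sc
}

#' Standardize model covariates
#'
#' Centers and scales the covariates the way every fit in the package
#' expects: footprint z-scored across stations, effort z-scored across
#' station-years, and the 0-based year index centered at the study midpoint
#' with unit = 1 calendar year (so trend coefficients stay per-year on the
#' link scale). The scaling constants are returned so coefficients can be
#' back-transformed to raw covariate units.
#'
#' @param stations station table with `hf_1km`/`hf_10km` columns.
#' @param counts count table with `effort` and `year` (calendar) columns.
#' @param config an [analysis_config()]; selects the footprint scale.
#' @param first_year,n_years study span; inferred from `counts` if omitted.
#' @return list with `stations` (plus `hf_z`), `counts` (plus `effort_z`,
#'   `t`, `t_c`) and `scaling` (the constants).
#' @export
standardize_covariates <- function(stations, counts, config = analysis_config(),
                                   first_year = NULL, n_years = NULL) {
  if (is.null(first_year)) first_year <- min(counts$year)
  if (is.null(n_years)) n_years <- max(counts$year) - first_year + 1
  sc <- .covariate_scaling(stations, counts$effort, first_year, n_years)
  hfcol <- paste0("hf_", config$hf_scale)
  stations$hf_z <- (stations[[hfcol]] - sc[[paste0(hfcol, "_mean")]]) /
    sc[[paste0(hfcol, "_sd")]]
  counts$t <- counts$year - first_year
  counts$t_c <- counts$t - sc$t_mid
  counts$effort_z <- (counts$effort - sc$effort_mean) / sc$effort_sd
  sc$hf_scale <- config$hf_scale
  list(stations = stations, counts = counts, scaling = sc)
}

#' Read and write the four banding-data tables
#'
#' `write_banding_data()` writes `stations.csv`, `counts.csv`,
#' `productivity.csv` and `captures.csv` (plus, when the dataset carries
#' simulation ground truth, a `truth.json` sidecar recording every true
#' parameter and the seed). `read_banding_data()` reads them back; the
#' round trip is lossless. Capture histories are stored wide (a fixed-width
#' 0/1 `detections` string spanning the full study) by default; a long form
#' with one row per individual-year detection is also read and written via
#' `captures_format = "long"`.
#'
#' @param data a `banding_data` list (as from [simulate_banding_data()]) or
#'   a list with elements `stations`, `counts`, `productivity`, `captures`.
#' @param dir directory to write to / read from.
#' @param captures_format `"wide"` or `"long"`.
#' @return `read_banding_data()` returns a `banding_data` list.
#' @export
write_banding_data <- function(data, dir, captures_format = c("wide", "long")) {
  captures_format <- match.arg(captures_format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- data$stations
  st$active_years <- vapply(st$active_years, paste, "", collapse = "|")
  if (!is.null(st$effort_by_year)) {
    st$effort_by_year <- vapply(st$effort_by_year,
                                function(e) paste(format(e, digits = 15, trim = TRUE),
                                                  collapse = "|"), "")
  }
  utils::write.csv(st, file.path(dir, "stations.csv"), row.names = FALSE)
  utils::write.csv(data$counts, file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(data$productivity, file.path(dir, "productivity.csv"),
                   row.names = FALSE)
  cap <- data$captures
  if (captures_format == "long") {
    mat <- detections_to_matrix(cap$detections)
    idx <- which(mat == 1L, arr.ind = TRUE)
    long <- data.frame(individual_id = cap$individual_id[idx[, 1]],
                       station_id = cap$station_id[idx[, 1]],
                       sex = cap$sex[idx[, 1]],
                       predetermined = cap$predetermined[idx[, 1]],
                       year = min(data$counts$year) + idx[, 2] - 1L)
    long <- long[order(long$individual_id, long$year), ]
    utils::write.csv(long, file.path(dir, "captures.csv"), row.names = FALSE)
  } else {
    utils::write.csv(cap, file.path(dir, "captures.csv"), row.names = FALSE)
  }
  if (!is.null(data$truth)) {
    jsonlite::write_json(data$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname write_banding_data
#' @export
read_banding_data <- function(dir, captures_format = c("wide", "long")) {
  captures_format <- match.arg(captures_format)
  st <- utils::read.csv(file.path(dir, "stations.csv"),
                        colClasses = c(station_id = "character"))
  st$active_years <- lapply(strsplit(st$active_years, "|", fixed = TRUE),
                            as.integer)
  if (!is.null(st$effort_by_year)) {
    st$effort_by_year <- lapply(seq_len(nrow(st)), function(i) {
      stats::setNames(as.numeric(strsplit(st$effort_by_year[i], "|",
                                          fixed = TRUE)[[1]]),
                      st$active_years[[i]])
    })
  }
  counts <- utils::read.csv(file.path(dir, "counts.csv"),
                            colClasses = c(station_id = "character"))
  prod <- utils::read.csv(file.path(dir, "productivity.csv"),
                          colClasses = c(station_id = "character"))
  cap_classes <- c(station_id = "character", individual_id = "character")
  if (captures_format == "wide") {
    cap_classes <- c(cap_classes, detections = "character")
  }
  cap <- utils::read.csv(file.path(dir, "captures.csv"),
                         colClasses = cap_classes)
  if (captures_format == "long") {
    first_year <- min(counts$year)
    n_years <- max(counts$year) - first_year + 1
    ids <- unique(cap$individual_id)
    mat <- matrix(0L, length(ids), n_years)
    rows <- match(cap$individual_id, ids)
    mat[cbind(rows, cap$year - first_year + 1L)] <- 1L
    keep <- !duplicated(cap$individual_id)
    cap <- data.frame(individual_id = ids,
                      station_id = cap$station_id[keep][match(ids, cap$individual_id[keep])],
                      sex = cap$sex[keep][match(ids, cap$individual_id[keep])],
                      first_year = first_year +
                        apply(mat, 1, function(r) which(r == 1L)[1]) - 1L,
                      detections = apply(mat, 1, paste, collapse = ""),
                      predetermined = cap$predetermined[keep][match(ids, cap$individual_id[keep])])
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path) else NULL
  structure(list(stations = st, counts = counts, productivity = prod,
                 captures = cap, truth = truth), class = "banding_data")
}

#' Convert detection strings to a binary matrix
#'
#' @param detections character vector of fixed-width 0/1 strings.
#' @return integer matrix, one row per individual.
#' @export
detections_to_matrix <- function(detections) {
  n <- nchar(detections)
  if (length(unique(n)) != 1) .stopf("detection strings have unequal widths")
  mat <- matrix(as.integer(unlist(strsplit(detections, ""))),
                nrow = length(detections), byrow = TRUE)
  if (any(is.na(mat)) || any(!mat %in% c(0L, 1L))) {
    .stopf("detection strings must contain only 0/1")
  }
  mat
}
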