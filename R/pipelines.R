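# Configuration-driven entry points tying the stages into the two workflows:
# backward source inference and nocturnal wind climatology. A YAML config
# (with the behavioural defaults as the zero-config parameterisation) drives
# both; outputs are CSV/GeoJSON/JSON plus a reproducibility manifest.

#' Surveillance trap sites
#'
#' Coordinates of the pheromone surveillance traps on Saibai Island, Erub
#' Island, Bamaga/Seisia and Badu Island used as default arrival sites.
#'
#' @return A tibble with `trap`, `site`, `lon`, `lat`.
#' @export
trap_sites <- function() {
  tibble::tribble(
    ~trap, ~site, ~lat, ~lon,
    "FAW-Erub001", "Erub", -9.590167, 143.75698,
    "FAW-Erub002", "Erub", -9.5915, 143.77208,
    "FAW-Saibai001", "Saibai", -9.382222, 142.6075,
    "FAW-Saibai002", "Saibai", -9.381111, 142.62528,
    "FAW-Bamaga001", "Bamaga", -10.89583, 142.38442,
    "FAW-Bamaga002", "Bamaga", -10.84815, 142.36731,
    "FAW-Badu001", "Badu", -10.15776, 142.1682,
    "FAW-Badu002", "Badu", -10.16836, 142.16694)[, c("trap", "site", "lon", "lat")]
}

#' Read and validate a run configuration
#'
#' Loads a YAML configuration for [run_backward_inference()] /
#' [run_climatology()]. Validation collects *every* problem before failing,
#' so a bad config reports all its errors at once.
#'
#' @param path Path to a YAML file, or a list already in config shape.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  config <- if (is.list(path)) path else yaml::read_yaml(path)
  problems <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)

  need(!is.null(config$output_dir), "`output_dir` is required")
  has_files <- !is.null(config$field) && !is.null(config$mask)
  has_scenario <- !is.null(config$scenario)
  need(has_files || has_scenario,
       "either `scenario` or both `field` and `mask` paths are required")
  if (has_files && !has_scenario) {
    for (p in c(config$field, config$mask)) {
      need(file.exists(p), sprintf("input file does not exist: %s", p))
    }
  }
  if (!is.null(config$sites)) {
    sites <- dplyr::bind_rows(config$sites)
    need(all(c("site", "lon", "lat") %in% names(sites)),
         "`sites` entries need `site`, `lon`, `lat`")
    if ("site" %in% names(sites)) {
      need(!anyDuplicated(sites$site), "site names must be unique")
    }
    config$sites <- sites
  }
  if (!is.null(config$arrival_nights)) {
    parsed <- tryCatch(as.Date(unlist(config$arrival_nights)),
                       error = function(e) as.Date(NA))
    need(!anyNA(parsed), "`arrival_nights` must be ISO dates (YYYY-MM-DD)")
    config$arrival_nights <- parsed
  }
  if (!is.null(config$flight)) {
    unknown <- setdiff(names(config$flight), names(formals(flight_params)))
    need(length(unknown) == 0,
         sprintf("unknown flight parameter(s): %s", paste(unknown, collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop(paste(c("invalid run configuration:",
                 paste0("  - ", problems)), collapse = "\n"), call. = FALSE)
  }
  config$seed <- config$seed %||% 1L
  structure(config, class = "run_config")
}

.config_params <- function(config) {
  do.call(flight_params, config$flight %||% list())
}

.config_field_mask <- function(config, params) {
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    scen <- make_monsoon_scenario(
      seed = config$seed,
      source_centroid = if (!is.null(sc$source)) unlist(sc$source),
      arrival_site = if (!is.null(sc$arrival)) unlist(sc$arrival) else c(142.6, -9.4),
      leg_count = sc$leg_count %||% 1,
      stopover = if (!is.null(sc$stopover)) unlist(sc$stopover),
      jet_speed = sc$jet_speed %||% 12,
      params = params)
    list(field = scen$field, mask = scen$mask, scenario = scen,
         checksums = character())
  } else {
    vm <- unlist(config$variable_map) %||% character()
    list(field = load_gridded_field(config$field, vm),
         mask = load_land_mask(config$mask), scenario = NULL,
         checksums = tools::md5sum(c(config$field, config$mask)))
  }
}

.write_manifest <- function(config, checksums, params, out_dir) {
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  manifest <- list(
    package = "mothwind",
    package_version = as.character(utils::packageVersion("mothwind")),
    config_hash = unname(tools::md5sum(cfg_file)),
    input_checksums = as.list(checksums),
    seed = config$seed,
    effective_flight_params = unclass(params))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the backward source-inference workflow
#'
#' For every configured site and arrival night, launches the hourly backward
#' fan with stepping-stone chaining ([run_multileg_backward()]), applies the
#' endpoint-validity filter ([filter_and_count()]) and writes, under
#' `output_dir`: per-point trajectory CSVs, GeoJSON LineStrings per leg, a
#' JSON validity report, a JSON-lines log of every candidate's termination
#' reason, and a reproducibility manifest. The run is deterministic given the
#' config (the seed covers synthetic generation).
#'
#' @param config A `run_config` from [read_run_config()] (or a path/list
#'   accepted by it).
#' @return A named list of `validity_report` objects (one per site x arrival
#'   night), invisibly; side effect: files under `output_dir`.
#' @export
run_backward_inference <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  params <- .config_params(config)
  fm <- .config_field_mask(config, params)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sites <- if (!is.null(config$sites)) config$sites else {
    if (!is.null(fm$scenario)) {
      tibble::tibble(site = "arrival",
                     lon = fm$scenario$truth$arrival_lon,
                     lat = fm$scenario$truth$arrival_lat)
    } else dplyr::distinct(trap_sites(), site, .keep_all = TRUE)[, c("site", "lon", "lat")]
  }
  nights <- if (!is.null(config$arrival_nights)) config$arrival_nights else {
    if (!is.null(fm$scenario)) fm$scenario$truth$expected_arrival_night else
      stop("`arrival_nights` required when no scenario supplies them", call. = FALSE)
  }
  span <- range(fm$field$times)
  for (night in as.list(nights)) {
    nt <- as.POSIXct(paste(format(night), "00:00:00"), tz = "UTC")
    if (nt < span[1] - 86400 || nt > span[2]) {
      stop(sprintf("arrival night %s is outside the met-field span %s .. %s",
                   format(night), format(span[1], "%Y-%m-%d %H:%M"),
                   format(span[2], "%Y-%m-%d %H:%M")), call. = FALSE)
    }
  }

  reports <- list()
  log_lines <- character()
  for (i in seq_len(nrow(sites))) {
    for (night in as.list(nights)) {
      key <- sprintf("%s_%s", sites$site[i], format(night))
      paths <- run_multileg_backward(sites$lon[i], sites$lat[i], night,
                                     fm$field, fm$mask, params)
      report <- filter_and_count(paths, fm$mask, params,
                                 host_mode = config$host_mode %||% "lenient")
      reports[[key]] <- report
      write_paths_csv(report$paths, file.path(out_dir, paste0("trajectories_", key, ".csv")))
      write_paths_geojson(report$paths, file.path(out_dir, paste0("trajectories_", key, ".geojson")))
      jsonlite::write_json(
        list(site = sites$site[i], arrival_night = format(night),
             counts = report$counts, durations = report$durations,
             endpoints = report$endpoints,
             source_region = if (sum(report$counts$n_valid) > 0) {
               s <- source_region_summary(report)
               list(centroid = as.list(s$centroid), hull = s$hull,
                    n_endpoints = s$n_endpoints, degenerate = s$degenerate)
             } else NULL),
        file.path(out_dir, paste0("report_", key, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, POSIXt = "ISO8601", na = "null")
      log_lines <- c(log_lines, purrr::map_chr(seq_len(nrow(report$paths)), function(j) {
        jsonlite::toJSON(list(run = key, path_id = report$paths$path_id[j],
                              n_legs = report$paths$n_legs[j],
                              termination_reason = report$paths$termination_reason[j],
                              valid = report$paths$valid[j]), auto_unbox = TRUE)
      }))
    }
  }
  writeLines(log_lines, file.path(out_dir, "run_log.jsonl"))
  .write_manifest(config, fm$checksums, params, out_dir)
  invisible(reports)
}

#' Run the nocturnal wind-climatology workflow
#'
#' Builds the nocturnal multi-level wind samples for the configured sites,
#' months and years, writes one wind rose per requested month (CSV), the
#' configured sector-group statistics (JSON), and a time-height omega profile
#' with downdraft events per site (CSV + JSON).
#'
#' @inheritParams run_backward_inference
#' @return A list with `samples`, `roses`, `group_stats`, `profiles`,
#'   `events`, invisibly; side effect: files under `output_dir`.
#' @export
run_climatology <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  params <- .config_params(config)
  fm <- .config_field_mask(config, params)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cl <- config$climatology %||% list()
  sites <- config$sites %||% dplyr::distinct(trap_sites(), site, .keep_all = TRUE)[, c("site", "lon", "lat")]
  months <- if (is.null(cl$months)) 1:12 else as.integer(unlist(cl$months))
  years <- if (is.null(cl$years)) {
    as.integer(unique(format(fm$field$times, "%Y")))
  } else as.integer(unlist(cl$years))
  levels_hpa <- if (is.null(cl$levels_hpa)) c(800, 825, 850, 875, 900) else
    unlist(cl$levels_hpa)

  if (length(months) == 0) {
    warning("empty month request: no climatology computed", call. = FALSE)
    .write_manifest(config, fm$checksums, params, out_dir)
    return(invisible(list(samples = tibble::tibble(), roses = list(),
                          group_stats = tibble::tibble(), profiles = list(),
                          events = list())))
  }

  samples <- nightly_level_samples(fm$field, sites, levels_hpa = levels_hpa,
                                   months = months, years = years)
  roses <- list()
  for (m in months) {
    rose <- monthly_wind_rose(samples, m)
    roses[[as.character(m)]] <- rose
    utils::write.csv(
      dplyr::mutate(as.data.frame(rose), month = m)[, c("month", "sector", "name",
                                                        "count", "frequency", "mean_speed")],
      file.path(out_dir, sprintf("wind_rose_%02d.csv", m)), row.names = FALSE)
  }
  groups <- cl$sector_groups %||% list(westerly = "W")
  group_stats <- purrr::imap_dfr(groups, function(sectors, nm) {
    dplyr::mutate(sector_group_stats(samples, months, unlist(sectors)),
                  group = nm, .before = 1)
  })
  jsonlite::write_json(group_stats, file.path(out_dir, "sector_groups.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  profiles <- list(); events <- list()
  for (i in seq_len(nrow(sites))) {
    prof <- vertical_velocity_profile(fm$field, sites$lon[i], sites$lat[i],
                                      levels_hpa = unlist(cl$profile_levels_hpa) %||%
                                        seq(800, 950, 25))
    ev <- downdraft_events(prof, threshold = cl$downdraft_threshold %||% 0.3,
                           airspeed = params$airspeed)
    profiles[[sites$site[i]]] <- prof
    events[[sites$site[i]]] <- ev
    utils::write.csv(as.data.frame(prof),
                     file.path(out_dir, sprintf("vv_profile_%s.csv", sites$site[i])),
                     row.names = FALSE)
    jsonlite::write_json(ev, file.path(out_dir, sprintf("downdraft_events_%s.json",
                                                        sites$site[i])),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, POSIXt = "ISO8601")
  }
  .write_manifest(config, fm$checksums, params, out_dir)
  invisible(list(samples = samples, roses = roses, group_stats = group_stats,
                 profiles = profiles, events = events))
}
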