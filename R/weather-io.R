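# Canonical daily-weather schema, validation, CSV I/O and a pluggable fetcher.

#' Canonical daily weather variable names
#'
#' The canonical per-day environmental factors used throughout the package,
#' in NASA POWER-style coding: top-of-atmosphere insolation (`TOA_RAD`),
#' downward shortwave at the surface (`SRAD_DOWN`), downward longwave
#' (`LWD`), wind speed (`WS`), mean/min/max air temperature at 2 m
#' (`T2M`, `T2M_MIN`, `T2M_MAX`), dew point (`T2MDEW`), relative humidity
#' (`RH2M`), precipitation (`PRECTOT`) and elevation (`ALT`).
#'
#' @return Character vector of canonical factor names.
#' @export
weather_factors <- function() {
  c("TOA_RAD", "SRAD_DOWN", "LWD", "WS", "T2M", "T2M_MIN", "T2M_MAX",
    "T2MDEW", "RH2M", "PRECTOT", "ALT")
}

# Columns appended by the ecophysiology processing step.
computed_factors <- function() {
  c("N", "n", "SRAD", "FRUE", "GDD", "T2M_RANGE", "SPV", "VPD", "ETP", "PETP")
}

#' Default alias table for weather column names
#'
#' Maps common provider spellings onto the canonical schema; in particular
#' the two dew-point spellings (`T2M_DEW` and `T2MDEW`) both resolve to
#' `T2MDEW`, and NASA POWER long codes resolve to their short forms.
#'
#' @return Named character vector: `names()` are source spellings, values
#'   are canonical names.
#' @export
weather_aliases <- function() {
  c(T2M_DEW = "T2MDEW",
    ALLSKY_SFC_SW_DWN = "SRAD_DOWN",
    ALLSKY_SFC_LW_DWN = "LWD",
    ALLSKY_TOA_SW_DWN = "TOA_RAD",
    PRECTOTCORR = "PRECTOT",
    WS2M = "WS",
    WS10M = "WS",
    env = "env_id",
    Srad = "SRAD")
}

#' Validate a daily weather table
#'
#' Checks the structural invariants of the canonical weather table:
#' `daysFromStart` strictly increasing and contiguous within each
#' environment, coordinates within valid WGS84 ranges, `T2M_MIN <= T2M_MAX`
#' where both are present, `RH2M` within \[0, 100\] and `PRECTOT >= 0`.
#'
#' @param w A weather tibble with at least `env_id` and `daysFromStart`.
#' @return `w` invisibly; errors describe the offending environment/rows.
#' @export
validate_weather <- function(w) {
  stopifnot(is.data.frame(w))
  if (!"env_id" %in% names(w)) {
    stop("weather table lacks an `env_id` column", call. = FALSE)
  }
  if (!"daysFromStart" %in% names(w)) {
    stop("weather table lacks a `daysFromStart` column", call. = FALSE)
  }
  bad_span <- w |>
    dplyr::group_by(.data$env_id) |>
    dplyr::summarise(
      ok = all(diff(.data$daysFromStart) == 1L) || dplyr::n() == 1L,
      .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad_span) > 0) {
    stop("daysFromStart not strictly increasing and contiguous in environment(s): ",
         paste(bad_span$env_id, collapse = ", "), call. = FALSE)
  }
  if ("lat" %in% names(w) && any(abs(w$lat) > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if ("lon" %in% names(w) && any(abs(w$lon) > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]", call. = FALSE)
  }
  if (all(c("T2M_MIN", "T2M_MAX") %in% names(w))) {
    bad <- which(w$T2M_MIN > w$T2M_MAX)
    if (length(bad) > 0) {
      stop("T2M_MIN > T2M_MAX on row(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if ("RH2M" %in% names(w) && any(w$RH2M < 0 | w$RH2M > 100, na.rm = TRUE)) {
    stop("RH2M outside [0, 100]", call. = FALSE)
  }
  if ("PRECTOT" %in% names(w) && any(w$PRECTOT < 0, na.rm = TRUE)) {
    stop("PRECTOT negative", call. = FALSE)
  }
  invisible(w)
}

canonicalize_names <- function(nms, alias_map = weather_aliases()) {
  hit <- nms %in% names(alias_map)
  nms[hit] <- unname(alias_map[nms[hit]])
  nms
}

#' Read a daily weather CSV into the canonical schema
#'
#' Reads a long daily table (one row per environment-day), renames columns
#' through the alias table, sorts by environment and day, and validates the
#' schema invariants.
#'
#' @param path Path to a CSV file with `.`-decimal UTF-8 content.
#' @param env_id_column Name of the column identifying the environment
#'   (renamed to `env_id`).
#' @param alias_map Named character vector mapping source spellings to
#'   canonical names; defaults to [weather_aliases()].
#' @return A tibble in canonical form, sorted by `env_id`, `daysFromStart`.
#' @export
read_weather <- function(path, env_id_column = "env",
                         alias_map = weather_aliases()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # base parser: exact decimal -> binary round-trip for doubles
  w <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (env_id_column %in% names(w)) {
    names(w)[names(w) == env_id_column] <- "env_id"
  }
  names(w) <- canonicalize_names(names(w), alias_map)
  for (col in intersect(weather_factors(), names(w))) {
    w[[col]] <- as.double(w[[col]])
  }
  if (!"env_id" %in% names(w)) {
    stop("environment column `", env_id_column, "` not found in ", path,
         call. = FALSE)
  }
  if ("date" %in% names(w) && !inherits(w$date, "Date")) {
    w$date <- as.Date(w$date)
  }
  if (!"daysFromStart" %in% names(w) && "date" %in% names(w)) {
    w <- w |>
      dplyr::group_by(.data$env_id) |>
      dplyr::mutate(daysFromStart = as.integer(.data$date - min(.data$date))) |>
      dplyr::ungroup()
  }
  w <- dplyr::arrange(w, .data$env_id, .data$daysFromStart)
  validate_weather(w)
  tibble::as_tibble(w)
}

#' Write a weather table to CSV
#'
#' @param w Weather tibble.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_weather <- function(w, path) {
  readr::write_csv(w, path, progress = FALSE)
  invisible(path)
}

#' Fetch daily weather through a pluggable backend
#'
#' Builds the inclusive daily calendar for each requested environment and
#' delegates the actual retrieval to `backend`, a function
#' `(env_id, lat, lon, dates)` returning a data frame with one row per
#' element of `dates`. The packaged [synthetic_weather_backend()] serves
#' offline use; an HTTP client can be plugged in with the same signature.
#' Vectors of environments are supported by recycling scalar arguments.
#'
#' @param env_id Environment label(s).
#' @param lat,lon Coordinates in decimal degrees WGS84 (vectorized).
#' @param start_day,end_day Inclusive date span (`Date` or "YYYY-MM-DD").
#' @param backend Fetch function; default [synthetic_weather_backend()].
#' @return Canonical weather tibble covering every day of every span.
#' @export
fetch_weather <- function(env_id, lat, lon, start_day, end_day,
                          backend = synthetic_weather_backend()) {
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("lat/lon out of range", call. = FALSE)
  }
  start_day <- as.Date(start_day)
  end_day <- as.Date(end_day)
  if (any(is.na(start_day)) || any(is.na(end_day))) {
    stop("start_day/end_day must be valid dates", call. = FALSE)
  }
  if (any(end_day < start_day)) {
    stop("start_day must not exceed end_day", call. = FALSE)
  }
  req <- tibble::tibble(env_id = env_id, lat = lat, lon = lon,
                        start_day = start_day, end_day = end_day)
  out <- purrr::pmap(req, function(env_id, lat, lon, start_day, end_day) {
    dates <- seq(start_day, end_day, by = "day")
    got <- tryCatch(backend(env_id, lat, lon, dates),
                    error = function(e) {
                      stop("weather fetch failed for environment `", env_id,
                           "`: ", conditionMessage(e), call. = FALSE)
                    })
    if (nrow(got) != length(dates)) {
      stop("weather fetch failed for environment `", env_id,
           "`: backend returned ", nrow(got), " rows for ",
           length(dates), " days", call. = FALSE)
    }
    tibble::tibble(env_id = env_id, lat = lat, lon = lon, date = dates,
                   daysFromStart = seq_along(dates) - 1L) |>
      dplyr::bind_cols(got[setdiff(names(got),
                                   c("env_id", "lat", "lon", "date",
                                     "daysFromStart"))])
  })
  w <- dplyr::bind_rows(out)
  validate_weather(w)
  w
}

#' Deterministic synthetic weather backend
#'
#' Returns a fetch backend (for [fetch_weather()]) that generates synthetic
#' but physically coherent daily weather from latitude, longitude and
#' calendar date alone, with no network access. Values are a pure function
#' of the request, so repeated fetches are identical. The climate emulates
#' a seasonal temperature cycle whose amplitude grows with |latitude| and a
#' rainfall regime with site-specific wet-day frequency.
#'
#' @param base_temp Mean annual temperature at the equator (degrees C).
#' @return A function `(env_id, lat, lon, dates)` returning a tibble of
#'   daily factors.
#' @export
synthetic_weather_backend <- function(base_temp = 26) {
  function(env_id, lat, lon, dates) {
    doy <- as.POSIXlt(dates)$yday + 1
    # deterministic per-site phase/noise seeds from coordinates
    site <- abs(sin(lat * 12.9898 + lon * 78.233)) * 43758.5453
    site <- site - floor(site)
    amp <- 2 + 18 * abs(lat) / 90
    phase <- if (lat >= 0) -0.5 * pi else 0.5 * pi
    t2m <- base_temp - 12 * abs(lat) / 90 +
      amp * sin(2 * pi * doy / 365 + phase) +
      2 * sin(2 * pi * (doy * (1 + site)) / 29.5)
    half_range <- 4 + 2 * site
    dewdep <- 2 + 6 * site
    ra <- extraterrestrial_radiation(lat, doy)
    cloud <- 0.3 + 0.4 * abs(sin(doy / 9.3 + site * 7))
    srad <- ra * (0.25 + 0.50 * (1 - cloud))
    rain_gate <- abs(sin(doy / 3.7 + site * 17))
    prec <- ifelse(rain_gate > 0.6, 25 * (rain_gate - 0.6)^1.5 * 10, 0)
    es <- sat_vapour_pressure(t2m)
    ea <- sat_vapour_pressure(t2m - dewdep)
    tibble::tibble(
      TOA_RAD = ra,
      SRAD_DOWN = srad,
      LWD = 30 + 0.3 * t2m,
      WS = 1.5 + 2 * site,
      T2M = t2m,
      T2M_MIN = t2m - half_range,
      T2M_MAX = t2m + half_range,
      T2MDEW = t2m - dewdep,
      RH2M = pmin(100, pmax(0, 100 * ea / es)),
      PRECTOT = prec,
      ALT = 50 + 1500 * site)
  }
}
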