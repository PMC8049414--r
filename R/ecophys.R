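# Ecophysiological covariates from daily weather: photoperiod and radiation,
# thermal time and temperature response, atmospheric water demand.
#
# Formulations follow FAO-56 (Allen et al. 1998) for the radiation and
# vapour-pressure terms and the Soltani & Sinclair cardinal-temperature
# framework for the trapezoidal temperature response.

solar_constant <- 0.0820  # MJ m-2 min-1

julian_day <- function(w) {
  if ("date" %in% names(w)) {
    as.POSIXlt(w$date)$yday + 1
  } else {
    # fall back on day offsets treated as days of year (mod 365)
    ((w$daysFromStart) %% 365L) + 1L
  }
}

solar_declination <- function(J) 0.409 * sin(2 * pi * J / 365 - 1.39)

inv_rel_distance <- function(J) 1 + 0.033 * cos(2 * pi * J / 365)

sunset_hour_angle <- function(lat_rad, decl) {
  x <- -tan(lat_rad) * tan(decl)
  acos(pmin(1, pmax(-1, x)))  # clipped at polar day/night
}

#' Extraterrestrial (top-of-atmosphere) radiation
#'
#' Daily extraterrestrial radiation from latitude and day of year
#' (FAO-56 Eq. 21), in MJ m-2 d-1.
#'
#' @param lat Latitude in decimal degrees.
#' @param J Day of year (1..365).
#' @return Numeric vector.
#' @export
extraterrestrial_radiation <- function(lat, J) {
  phi <- lat * pi / 180
  decl <- solar_declination(J)
  ws <- sunset_hour_angle(phi, decl)
  (24 * 60 / pi) * solar_constant * inv_rel_distance(J) *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
}

#' Saturation vapour pressure
#'
#' Tetens form `0.6108 exp(17.27 T / (T + 237.3))` (FAO-56 Eq. 11), kPa.
#'
#' @param temp Air temperature, degrees C.
#' @return Numeric vector, kPa.
#' @export
sat_vapour_pressure <- function(temp) {
  0.6108 * exp(17.27 * temp / (temp + 237.3))
}

# Slope of the saturation vapour pressure curve (FAO-56 Eq. 13), kPa / degC.
svp_slope <- function(temp) {
  4098 * sat_vapour_pressure(temp) / (temp + 237.3)^2
}

#' Radiation covariates: photoperiod, sunshine hours, global radiation
#'
#' Adds three columns to a daily weather table: `N`, the photoperiod
#' (astronomical daylength, hours) from the sunset hour angle; `n`, the
#' actual duration of sunshine hours, inverted from the Angstrom-Prescott
#' relation `SRAD_DOWN / Ra = as + bs n/N` and clipped to \[0, N\]; and
#' `SRAD`, the global solar radiation (MJ m-2 d-1) — the observed
#' `SRAD_DOWN` when available, otherwise the clear-sky Angstrom estimate
#' `(as + bs) Ra`. Beyond the polar circles the daylength saturates at 0 or
#' 24 h (warning).
#'
#' @param w Weather tibble with `lat` and `date` (or `daysFromStart`).
#' @param merge If `TRUE` (default) return `w` with the new columns;
#'   otherwise only the identification and new columns.
#' @param angstrom_a,angstrom_b Angstrom-Prescott coefficients
#'   (defaults 0.25, 0.50).
#' @return Tibble.
#' @export
param_radiation <- function(w, merge = TRUE,
                            angstrom_a = 0.25, angstrom_b = 0.50) {
  stopifnot("lat" %in% names(w))
  J <- julian_day(w)
  phi <- w$lat * pi / 180
  decl <- solar_declination(J)
  x <- -tan(phi) * tan(decl)
  if (any(abs(x) > 1, na.rm = TRUE)) {
    warning("polar day/night encountered; photoperiod clipped to [0, 24] h")
  }
  ws <- acos(pmin(1, pmax(-1, x)))
  N <- 24 / pi * ws
  Ra <- extraterrestrial_radiation(w$lat, J)
  if ("SRAD_DOWN" %in% names(w)) {
    frac <- w$SRAD_DOWN / Ra
    n <- N * (frac - angstrom_a) / angstrom_b
    n <- pmin(pmax(n, 0), N)
    SRAD <- ifelse(is.na(w$SRAD_DOWN),
                   (angstrom_a + angstrom_b) * Ra, w$SRAD_DOWN)
  } else {
    n <- N  # no cloudiness information: clear-sky assumption
    SRAD <- (angstrom_a + angstrom_b) * Ra
  }
  out <- dplyr::mutate(w, N = N, n = n, SRAD = SRAD)
  if (merge) out else dplyr::select(out, dplyr::any_of(c("env_id", "date",
                                                         "daysFromStart")),
                                    "N", "n", "SRAD")
}

#' Cardinal temperature set
#'
#' The four cardinal temperatures bounding a crop's temperature response:
#' lower base, lower optimum, upper optimum, upper base (degrees C),
#' ordered `Tbase1 <= Topt1 <= Topt2 <= Tbase2`.
#'
#' @param Tbase1,Topt1,Topt2,Tbase2 Cardinal temperatures, or a single
#'   species name in `Tbase1` to load the bundled set (see
#'   [species_cardinals()]).
#' @return A named list of class `cardinal_set`.
#' @examples
#' cardinal_set(8, 30, 37, 45)  # maize
#' cardinal_set("dry_bean")
#' @export
cardinal_set <- function(Tbase1, Topt1 = NULL, Topt2 = NULL, Tbase2 = NULL) {
  if (is.character(Tbase1)) {
    tab <- species_cardinals()
    hit <- tab[tab$species == Tbase1, ]
    if (nrow(hit) != 1) {
      stop("unknown species `", Tbase1, "`; see species_cardinals()",
           call. = FALSE)
    }
    return(cardinal_set(hit$Tbase1, hit$Topt1, hit$Topt2, hit$Tbase2))
  }
  stopifnot(Tbase1 <= Topt1, Topt1 <= Topt2, Topt2 <= Tbase2)
  structure(list(Tbase1 = Tbase1, Topt1 = Topt1, Topt2 = Topt2,
                 Tbase2 = Tbase2), class = "cardinal_set")
}

#' Bundled cardinal temperature table
#'
#' Cardinal temperature limits for phenological development of 14 crop
#' species, compiled from the crop ecophysiology literature.
#'
#' @return Tibble with columns `species`, `Tbase1`, `Topt1`, `Topt2`,
#'   `Tbase2`.
#' @export
species_cardinals <- function() {
  path <- system.file("extdata", "cardinal_temperatures.yaml",
                      package = "enviromics")
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(raw, tibble::as_tibble, .id = NULL) |>
    tibble::as_tibble()
}

#' Temperature effect on radiation use efficiency
#'
#' The trapezoidal temperature-response factor in \[0, 1\]: 0 at or below
#' `Tbase1` and at or above `Tbase2`, a linear rise to 1 between `Tbase1`
#' and `Topt1`, a plateau of 1 on \[`Topt1`, `Topt2`\], and a linear fall
#' back to 0 between `Topt2` and `Tbase2`.
#'
#' @param temp Daily (mean) temperature, degrees C; vectorized.
#' @param cardinals A [cardinal_set()].
#' @return Numeric vector in \[0, 1\].
#' @export
frue <- function(temp, cardinals) {
  stopifnot(inherits(cardinals, "cardinal_set"))
  c1 <- cardinals$Tbase1; o1 <- cardinals$Topt1
  o2 <- cardinals$Topt2; c2 <- cardinals$Tbase2
  up <- if (o1 > c1) (temp - c1) / (o1 - c1) else as.numeric(temp > c1)
  dn <- if (c2 > o2) (c2 - temp) / (c2 - o2) else as.numeric(temp < o2)
  pmin(1, pmax(0, pmin(up, dn)))
}

#' Thermal covariates: temperature range, FRUE, growing degree days
#'
#' Adds `T2M_RANGE = T2M_MAX - T2M_MIN`, `FRUE` evaluated at the daily
#' mean `(T2M_MAX + T2M_MIN)/2`, and `GDD = max(0, min(Tmean, Topt1) -
#' Tbase1)` — daily thermal time with the mean capped at the lower optimum
#' and floored at the base temperature.
#'
#' @param w Weather tibble.
#' @param cardinals A [cardinal_set()]; default maize (8, 30, 37, 45).
#' @param tmax,tmin Column names for the daily extreme temperatures.
#' @param merge If `TRUE` (default) return `w` plus the new columns.
#' @return Tibble.
#' @export
param_temperature <- function(w, cardinals = cardinal_set(8, 30, 37, 45),
                              tmax = "T2M_MAX", tmin = "T2M_MIN",
                              merge = TRUE) {
  if (!all(c(tmax, tmin) %in% names(w))) {
    stop("temperature columns `", tmax, "`/`", tmin, "` not found",
         call. = FALSE)
  }
  tmx <- w[[tmax]]
  tmn <- w[[tmin]]
  tmean <- (tmx + tmn) / 2
  out <- dplyr::mutate(
    w,
    T2M_RANGE = tmx - tmn,
    FRUE = frue(tmean, cardinals),
    GDD = pmax(0, pmin(tmean, cardinals$Topt1) - cardinals$Tbase1))
  if (merge) out else dplyr::select(out, dplyr::any_of(c("env_id", "date",
                                                         "daysFromStart")),
                                    "T2M_RANGE", "FRUE", "GDD")
}

#' Atmospheric demand covariates: vapour pressure and evapotranspiration
#'
#' Adds `SPV`, the slope of the saturation vapour pressure curve at `T2M`
#' (kPa / degC); `VPD`, the vapour pressure deficit, mean of the
#' saturation pressures at the daily extremes minus the actual vapour
#' pressure (from dew point when available, else from relative humidity);
#' `ETP`, Priestley-Taylor potential evapotranspiration
#' `alpha * Delta/(Delta+gamma) * (Rn - G) / lambda` (mm d-1, floored at
#' 0); and `PETP = PRECTOT - ETP`, the daily atmospheric water balance.
#' Net radiation `Rn` is shortwave `(1 - albedo) * SRAD` minus net
#' longwave; the latter uses the observed downward longwave `LWD` against
#' grey-body emission when present, and the FAO-56 clear-sky-scaled
#' estimate otherwise. The psychrometric constant is derived from
#' barometric pressure at elevation `alt`.
#'
#' @param w Weather tibble, after [param_radiation()] (needs `SRAD`).
#' @param alpha Priestley-Taylor coefficient (default 1.26).
#' @param g_flux Soil heat flux, MJ m-2 d-1 (default 0).
#' @param alt Elevation in m; default taken from an `ALT` column, else 0
#'   with a warning.
#' @param albedo Surface shortwave albedo (default 0.23, grass reference).
#' @param merge If `TRUE` (default) return `w` plus the new columns.
#' @return Tibble.
#' @export
param_atmospheric <- function(w, alpha = 1.26, g_flux = 0, alt = NULL,
                              albedo = 0.23, merge = TRUE) {
  needs <- c("T2M", "T2M_MAX", "T2M_MIN", "SRAD")
  if (!all(needs %in% names(w))) {
    stop("missing column(s): ",
         paste(setdiff(needs, names(w)), collapse = ", "),
         "; run param_radiation() first", call. = FALSE)
  }
  if (!any(c("T2MDEW", "RH2M") %in% names(w))) {
    stop("need T2MDEW or RH2M to compute actual vapour pressure",
         call. = FALSE)
  }
  if (is.null(alt)) {
    if ("ALT" %in% names(w)) {
      alt <- w$ALT
    } else {
      warning("no elevation available; assuming sea level (ALT = 0)")
      alt <- 0
    }
  }
  es_mean <- (sat_vapour_pressure(w$T2M_MAX) +
                sat_vapour_pressure(w$T2M_MIN)) / 2
  if ("T2MDEW" %in% names(w)) {
    ea <- sat_vapour_pressure(w$T2MDEW)
    if ("RH2M" %in% names(w)) {
      miss <- is.na(ea)
      ea[miss] <- w$RH2M[miss] / 100 * es_mean[miss]
    }
  } else {
    ea <- w$RH2M / 100 * es_mean
  }
  delta <- svp_slope(w$T2M)
  press <- 101.3 * ((293 - 0.0065 * alt) / 293)^5.26  # FAO-56 Eq. 7
  gamma <- 0.000665 * press
  sigma <- 4.903e-9  # MJ K-4 m-2 d-1
  tk4 <- ((w$T2M_MAX + 273.16)^4 + (w$T2M_MIN + 273.16)^4) / 2
  rns <- (1 - albedo) * w$SRAD
  if ("LWD" %in% names(w) && !all(is.na(w$LWD))) {
    rnl <- pmax(0, 0.98 * sigma * tk4 - w$LWD)
  } else {
    # FAO-56 Eq. 39 with clear-sky radiation from the Angstrom coefficients
    J <- julian_day(w)
    rso <- (0.75 + 2e-5 * alt) * extraterrestrial_radiation(w$lat, J)
    rel <- pmin(1, w$SRAD / rso)
    rnl <- sigma * tk4 * (0.34 - 0.14 * sqrt(pmax(ea, 0))) *
      (1.35 * rel - 0.35)
  }
  rn <- rns - rnl
  lambda <- 2.45  # MJ kg-1
  etp <- pmax(0, alpha * delta / (delta + gamma) * (rn - g_flux) / lambda)
  out <- dplyr::mutate(
    w,
    SPV = delta,
    VPD = pmax(0, es_mean - ea),
    ETP = etp,
    PETP = (if ("PRECTOT" %in% names(w)) w$PRECTOT else 0) - etp)
  if (merge) out else dplyr::select(out, dplyr::any_of(c("env_id", "date",
                                                         "daysFromStart")),
                                    "SPV", "VPD", "ETP", "PETP")
}

#' Full ecophysiological processing of a weather table
#'
#' Composes [param_radiation()], [param_temperature()] and
#' [param_atmospheric()], yielding the complete computed block
#' (`N`, `n`, `SRAD`, `T2M_RANGE`, `FRUE`, `GDD`, `SPV`, `VPD`, `ETP`,
#' `PETP`). Idempotent: processing an already processed table recomputes
#' the same columns.
#'
#' @param w Raw weather tibble.
#' @param cardinals A [cardinal_set()] for the thermal covariates.
#' @param alpha,g_flux,alt Passed to [param_atmospheric()].
#' @return Tibble with all computed columns appended.
#' @export
process_weather <- function(w, cardinals = cardinal_set(8, 30, 37, 45),
                            alpha = 1.26, g_flux = 0, alt = NULL) {
  validate_weather(w)
  w |>
    param_radiation(merge = TRUE) |>
    param_temperature(cardinals = cardinals, merge = TRUE) |>
    param_atmospheric(alpha = alpha, g_flux = g_flux, alt = alt,
                      merge = TRUE)
}
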