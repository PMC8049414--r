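# Shared fixtures and independent oracles, all built in code.

# Independently coded FAO-56-style scalar oracles, written as plain
# transliterations of the handbook equations (deliberately not sharing
# code with the package implementation).
oracle_daylength <- function(lat_deg, J) {
  phi <- lat_deg * pi / 180
  delta <- 0.409 * sin(0.0172142 * J - 1.39)
  arg <- -tan(phi) * tan(delta)
  arg <- min(1, max(-1, arg))
  (24 / pi) * acos(arg)
}

oracle_ra <- function(lat_deg, J) {
  phi <- lat_deg * pi / 180
  delta <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  dr <- 1 + 0.033 * cos(2 * pi * J / 365)
  ws <- acos(min(1, max(-1, -tan(phi) * tan(delta))))
  (24 * 60 * 0.0820) / pi * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

oracle_es <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

oracle_delta <- function(t) 4098 * oracle_es(t) / (t + 237.3)^2

oracle_frue <- function(t, c1, o1, o2, c2) {
  if (t <= c1 || t >= c2) return(0)
  if (t < o1) return((t - c1) / (o1 - c1))
  if (t <= o2) return(1)
  (c2 - t) / (c2 - o2)
}

oracle_gdd <- function(tmax, tmin, c1, o1) {
  max(0, min((tmax + tmin) / 2, o1) - c1)
}

# a small processed weather table shared across tests
tiny_weather <- function(q = 3, days = 60, seed = 101) {
  simulate_weather(sim_spec(q = q, days = days, seed = seed))
}

maize_cardinals <- function() cardinal_set(8, 30, 37, 45)

# balanced toy MET with known components
toy_met <- function(p = 20, q = 4, seed = 7, ...) {
  spec <- sim_spec(q = q, p = p, m = 300, seed = seed, ...)
  K_G <- simulate_kinship(p, 300, seed = seed + 1)
  W <- w_matrix(process_weather(simulate_weather(spec)))
  K_E <- env_kernel(W)$envCov
  met <- simulate_met(spec, K_G, K_E)
  list(spec = spec, K_G = K_G, K_E = K_E, data = met$data,
       truth = met$truth)
}

# weather CSV with NASA POWER-style headers, written to a temp file
nasa_power_csv <- function(n_days = 32, path = tempfile(fileext = ".csv")) {
  w <- fetch_weather("NAIROBI", -1.367, 36.834,
                     "2015-03-01", as.Date("2015-03-01") + n_days - 1)
  out <- data.frame(
    env = w$env_id, lat = w$lat, lon = w$lon, date = w$date,
    daysFromStart = w$daysFromStart,
    ALLSKY_TOA_SW_DWN = w$TOA_RAD, ALLSKY_SFC_SW_DWN = w$SRAD_DOWN,
    ALLSKY_SFC_LW_DWN = w$LWD, WS2M = w$WS, T2M = w$T2M,
    T2M_MIN = w$T2M_MIN, T2M_MAX = w$T2M_MAX, T2M_DEW = w$T2MDEW,
    RH2M = w$RH2M, PRECTOTCORR = w$PRECTOT, ALT = w$ALT)
  write.csv(out, path, row.names = FALSE)
  path
}
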