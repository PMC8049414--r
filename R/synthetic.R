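# Synthetic data with known structure: daily weather with seasonal
# signal, marker-derived genomic kinships, and multi-environment trial
# phenotypes drawn from the same covariance expansions the models fit.

#' Simulation specification
#'
#' Bundles the dimensions and generating variance components of a
#' synthetic multi-environment trial. Defaults emulate a tropical maize
#' toy design: 150 genotypes phenotyped in each of 5 environments
#' (750 records) over a 120-day season.
#'
#' @param q Number of environments.
#' @param p Number of genotypes.
#' @param m Number of markers for the kinship.
#' @param days Length of the daily weather record per environment.
#' @param sigma2_E,sigma2_G,sigma2_GE,sigma2_W,sigma2_GW,sigma2_e
#'   Generating variance components (environment main effect, genomic,
#'   genotype x environment, enviromic, genomic x enviromic, residual).
#' @param seed Integer seed.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(q = 5, p = 150, m = 1000, days = 120,
                     sigma2_E = 1, sigma2_G = 0.5, sigma2_GE = 0.3,
                     sigma2_W = 0, sigma2_GW = 0, sigma2_e = 0.8,
                     seed = 1) {
  s2 <- c(sigma2_E, sigma2_G, sigma2_GE, sigma2_W, sigma2_GW, sigma2_e)
  stopifnot(all(s2 >= 0), q >= 1, p >= 1, m >= 1, days >= 1)
  structure(list(q = q, p = p, m = m, days = days,
                 sigma2_E = sigma2_E, sigma2_G = sigma2_G,
                 sigma2_GE = sigma2_GE, sigma2_W = sigma2_W,
                 sigma2_GW = sigma2_GW, sigma2_e = sigma2_e,
                 seed = as.integer(seed)), class = "sim_spec")
}

#' Simulate daily weather with seasonal structure
#'
#' Generates a canonical daily weather table for `spec$q` environments:
#' mean temperature follows an environment-specific mean plus a single
#' annual sinusoid plus Gaussian noise; daily extremes are the mean plus
#' or minus a half-range; rainfall is a Bernoulli-gamma mixture; humidity,
#' dew point and shortwave radiation are generated consistently with
#' temperature and latitude. All physical-range invariants of
#' [validate_weather()] hold by construction.
#'
#' @param spec A [sim_spec()].
#' @param env_params Optional tibble with per-environment climate
#'   settings: `env_id`, `lat`, `lon`, `mean_temp`, `amplitude`, `phase`,
#'   `temp_sd`, `half_range`, `rain_prob`, `rain_shape`, `rain_scale`,
#'   `alt`. Missing columns get defaults spread over a realistic tropical
#'   to temperate gradient.
#' @param start_date First calendar day (default "2020-01-01").
#' @return Weather tibble (one row per environment-day).
#' @export
simulate_weather <- function(spec = sim_spec(), env_params = NULL,
                             start_date = as.Date("2020-01-01")) {
  set.seed(spec$seed)
  q <- spec$q
  defaults <- tibble::tibble(
    env_id = sprintf("E%02d", seq_len(q)),
    lat = seq(-25, 15, length.out = q),
    lon = seq(-52, -40, length.out = q),
    mean_temp = seq(20, 28, length.out = q),
    amplitude = seq(3, 7, length.out = q),
    phase = seq(0, pi, length.out = q),
    temp_sd = 1.5,
    half_range = 5,
    rain_prob = seq(0.25, 0.45, length.out = q),
    rain_shape = 1.2,
    rain_scale = seq(6, 12, length.out = q),
    alt = seq(100, 900, length.out = q))
  if (is.null(env_params)) {
    env_params <- defaults
  } else {
    miss <- setdiff(names(defaults), names(env_params))
    env_params <- dplyr::bind_cols(
      env_params, defaults[seq_len(nrow(env_params)), miss])
  }
  purrr::pmap(env_params, function(env_id, lat, lon, mean_temp, amplitude,
                                   phase, temp_sd, half_range, rain_prob,
                                   rain_shape, rain_scale, alt, ...) {
    dates <- seq(start_date, by = "day", length.out = spec$days)
    doy <- as.POSIXlt(dates)$yday + 1
    t2m <- mean_temp + amplitude * sin(2 * pi * doy / 365 + phase) +
      stats::rnorm(spec$days, sd = temp_sd)
    hr <- pmax(0.5, half_range + stats::rnorm(spec$days, sd = 0.8))
    wet <- stats::rbinom(spec$days, 1, rain_prob)
    rain <- wet * stats::rgamma(spec$days, shape = rain_shape,
                                scale = rain_scale)
    dewdep <- pmax(0, 3 + stats::rnorm(spec$days, sd = 1.5) - 0.15 * wet * 10)
    tdew <- t2m - dewdep
    rh <- 100 * sat_vapour_pressure(tdew) / sat_vapour_pressure(t2m)
    ra <- extraterrestrial_radiation(lat, doy)
    cloud <- pmin(1, pmax(0, 0.3 + 0.4 * wet +
                            stats::rnorm(spec$days, sd = 0.1)))
    srad <- ra * (0.25 + 0.50 * (1 - cloud))
    tibble::tibble(
      env_id = env_id, lat = lat, lon = lon, date = dates,
      daysFromStart = seq_len(spec$days) - 1L,
      TOA_RAD = ra, SRAD_DOWN = srad, LWD = 30 + 0.3 * t2m,
      WS = pmax(0.1, 2 + stats::rnorm(spec$days, sd = 0.7)),
      T2M = t2m, T2M_MIN = t2m - hr, T2M_MAX = t2m + hr,
      T2MDEW = tdew, RH2M = pmin(100, pmax(0, rh)),
      PRECTOT = rain, ALT = alt)
  }) |>
    dplyr::bind_rows() |>
    validate_weather()
}

#' Simulate a marker-derived genomic kinship
#'
#' Draws biallelic dosages `M_ij ~ Binomial(2, f_j)` with allele
#' frequencies `f_j ~ Uniform(maf_range)`, centers the dosage matrix and
#' returns the VanRaden kinship `K = M M' / (2 sum f (1 - f))`.
#'
#' @param p Number of genotypes.
#' @param m Number of markers (`m >= p` recommended).
#' @param maf_range Allele-frequency interval (default 0.05-0.5).
#' @param seed Integer seed.
#' @return p x p kinship matrix with genotype labels `G001`, ...,
#'   attribute `kind = "genomic"`.
#' @export
simulate_kinship <- function(p = 150, m = 1000,
                             maf_range = c(0.05, 0.5), seed = 1) {
  stopifnot(length(maf_range) == 2, maf_range[1] < maf_range[2],
            maf_range[1] > 0, maf_range[2] < 1)
  set.seed(as.integer(seed))
  f <- stats::runif(m, maf_range[1], maf_range[2])
  M <- vapply(f, function(fj) stats::rbinom(p, 2, fj), numeric(p))
  poly <- apply(M, 2, function(x) stats::var(x) > 0)
  if (!any(poly)) stop("all markers monomorphic; widen maf_range",
                       call. = FALSE)
  M <- M[, poly, drop = FALSE]
  f <- f[poly]
  Mc <- sweep(M, 2, 2 * f)
  K <- tcrossprod(Mc) / (2 * sum(f * (1 - f)))
  labels <- sprintf("G%03d", seq_len(p))
  dimnames(K) <- list(labels, labels)
  attr(K, "kind") <- "genomic"
  K
}

#' Simulate multi-environment trial phenotypes with known structure
#'
#' Draws `y = env + g + ge + w + gw + e`, each random component from
#' `N(0, sigma2 * K-structure)` using the same observation-level
#' expansions the models fit: `g` from the genomic kernel, `ge` from the
#' genomic kernel restricted within environments (block Hadamard), `w`
#' from the enviromic kernel, `gw` from the genomic x enviromic Hadamard
#' product. The returned truth record stores the realized components and
#' generating variances for recovery tests; it is never consumed by the
#' fitting code.
#'
#' @param spec A [sim_spec()] (its variance components drive the draw).
#' @param K_G p x p genomic kernel with labels (e.g.
#'   [simulate_kinship()]).
#' @param K_E q x q enviromic kernel with labels, or `NULL` when both
#'   `sigma2_W` and `sigma2_GW` are zero.
#' @return List with `data` (MET phenotype tibble env/gid/value) and
#'   `truth` (list of realized component vectors and the generating
#'   variances).
#' @export
simulate_met <- function(spec, K_G, K_E = NULL) {
  set.seed(spec$seed + 7L)
  p <- nrow(K_G)
  if (p != spec$p) stop("K_G dimension does not match spec$p",
                        call. = FALSE)
  if (is.null(K_E)) {
    if (spec$sigma2_W > 0 || spec$sigma2_GW > 0) {
      stop("enviromic variance requested but K_E is NULL", call. = FALSE)
    }
    envs <- sprintf("E%02d", seq_len(spec$q))
  } else {
    if (nrow(K_E) != spec$q) stop("K_E dimension does not match spec$q",
                                  call. = FALSE)
    envs <- rownames(K_E)
  }
  gids <- rownames(K_G)
  data <- tidyr::expand_grid(env = envs, gid = gids)
  n <- nrow(data)

  draw <- function(K, sigma2) {
    if (sigma2 == 0) return(numeric(n))
    e <- eigen(K, symmetric = TRUE)
    v <- pmax(e$values, 0)
    drop(e$vectors %*% (sqrt(v) * stats::rnorm(length(v)))) * sqrt(sigma2)
  }
  G_n <- expand_kernel(K_G, data$gid, "p")
  E_block <- outer(data$env, data$env, "==") * 1
  env_eff <- stats::rnorm(spec$q, sd = sqrt(spec$sigma2_E))
  comp <- list(
    env = env_eff[match(data$env, envs)],
    g = draw(G_n, spec$sigma2_G),
    ge = draw(G_n * E_block, spec$sigma2_GE),
    w = if (is.null(K_E)) numeric(n) else
      draw(expand_kernel(K_E, data$env, "q"), spec$sigma2_W),
    gw = if (is.null(K_E)) numeric(n) else
      draw(G_n * expand_kernel(K_E, data$env, "q"), spec$sigma2_GW),
    e = stats::rnorm(n, sd = sqrt(spec$sigma2_e)))
  data$value <- Reduce(`+`, comp)
  list(data = met_phenotypes(data),
       truth = c(comp, list(sigma2 = c(
         E = spec$sigma2_E, G = spec$sigma2_G, GE = spec$sigma2_GE,
         W = spec$sigma2_W, GW = spec$sigma2_GW, e = spec$sigma2_e))))
}
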