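test_that("photoperiod is 12 h at the equator and > 12 h in boreal summer", {
  w <- tibble::tibble(env_id = "eq", lat = 0, lon = 0,
                      date = as.Date("2020-03-01") + 0:9,
                      daysFromStart = 0:9,
                      SRAD_DOWN = 20)
  r <- param_radiation(w)
  expect_equal(r$N, rep(12, 10), tolerance = 1e-6)
  w_north <- dplyr::mutate(w, lat = 43.61,
                           date = as.Date("2020-06-20") + 0:9)
  r_north <- param_radiation(w_north)
  expect_true(all(r_north$N > 12))
  expect_equal(r_north$N[1],
               oracle_daylength(43.61, as.POSIXlt(w_north$date[1])$yday + 1),
               tolerance = 1e-9)
})

test_that("daylength is complementary across hemispheres", {
  for (lat in c(10, 35, 55)) {
    for (J in c(1, 80, 172, 300)) {
      d <- as.Date("2019-12-31") + J
      mk <- function(l) tibble::tibble(env_id = "x", lat = l, lon = 0,
                                       date = d, daysFromStart = 0L)
      N1 <- param_radiation(mk(lat))$N
      N2 <- param_radiation(mk(-lat))$N
      expect_equal(N1 + N2, 24, tolerance = 0.1)
    }
  }
})

test_that("sunshine hours invert the Angstrom relation and stay in [0, N]", {
  w <- tibble::tibble(env_id = "x", lat = 20, lon = 0,
                      date = as.Date("2020-05-01") + 0:2,
                      daysFromStart = 0:2,
                      SRAD_DOWN = c(0, 10, 1000))
  r <- param_radiation(w)
  expect_equal(r$n[1], 0)               # zero radiation floors at 0
  expect_true(all(r$n >= 0 & r$n <= r$N))
  expect_true(all(r$N >= 0 & r$N <= 24))
})

test_that("FRUE is the cardinal trapezoid", {
  mz <- maize_cardinals()
  expect_equal(frue(8, mz), 0)
  expect_equal(frue(45, mz), 0)
  expect_equal(frue(33, mz), 1)
  expect_equal(frue(19, mz), 0.5)
  expect_equal(frue(c(-10, 100), mz), c(0, 0))
})

test_that("FRUE matches the scalar oracle and is a valid response curve", {
  set.seed(14)
  mz <- maize_cardinals()
  temps <- runif(1000, -10, 60)
  expect_equal(frue(temps, mz),
               vapply(temps, oracle_frue, numeric(1), 8, 30, 37, 45),
               tolerance = 1e-12)
  expect_true(all(frue(temps, mz) >= 0 & frue(temps, mz) <= 1))
  grid_lo <- seq(-5, 30, by = 0.25)
  expect_true(all(diff(frue(grid_lo, mz)) >= 0))   # non-decreasing below Topt1
  grid_hi <- seq(37, 50, by = 0.25)
  expect_true(all(diff(frue(grid_hi, mz)) <= 0))   # non-increasing above Topt2
})

test_that("thermal covariates follow the cap-and-floor rules", {
  base <- tibble::tibble(env_id = "x", lat = 0, lon = 0,
                         daysFromStart = 0L)
  dry_bean <- cardinal_set("dry_bean")
  t1 <- param_temperature(dplyr::mutate(base, T2M_MAX = 30, T2M_MIN = 20),
                          dry_bean)
  expect_equal(t1$GDD, 17)   # mean 25 - Tbase1 8
  expect_equal(t1$T2M_RANGE, 10)
  t2 <- param_temperature(dplyr::mutate(base, T2M_MAX = 8, T2M_MIN = 8),
                          maize_cardinals())
  expect_equal(t2$GDD, 0)
  expect_equal(t2$FRUE, 0)
  t3 <- param_temperature(dplyr::mutate(base, T2M_MAX = 50, T2M_MIN = 40),
                          maize_cardinals())
  expect_equal(t3$GDD, 22)   # mean capped at Topt1 = 30
  expect_error(param_temperature(base), "T2M_MAX")
})

test_that("GDD is non-decreasing in the mean temperature below Topt1", {
  mz <- maize_cardinals()
  means <- seq(0, 30, by = 0.5)
  gdd <- pmax(0, pmin(means, mz$Topt1) - mz$Tbase1)
  w <- tibble::tibble(env_id = "x", daysFromStart = seq_along(means) - 1L,
                      T2M_MAX = means + 1, T2M_MIN = means - 1)
  expect_equal(param_temperature(w, mz)$GDD, gdd)
  expect_true(all(diff(gdd) >= 0))
})

test_that("vapour pressure slope matches the FAO-56 oracle", {
  expect_equal(sat_vapour_pressure(20), oracle_es(20), tolerance = 1e-12)
  w <- tibble::tibble(env_id = "x", lat = 0, lon = 0, daysFromStart = 0L,
                      date = as.Date("2020-01-01"),
                      T2M = 20, T2M_MAX = 25, T2M_MIN = 15, T2MDEW = 12,
                      RH2M = 60, PRECTOT = 0, SRAD_DOWN = 18, LWD = 35,
                      ALT = 0)
  a <- param_atmospheric(param_radiation(w))
  expect_lt(abs(a$SPV - 0.145), 0.001)
  expect_equal(a$SPV, oracle_delta(20), tolerance = 1e-9)
})

test_that("saturated air has zero vapour pressure deficit", {
  w <- tibble::tibble(env_id = "x", lat = 0, lon = 0, daysFromStart = 0L,
                      date = as.Date("2020-01-01"),
                      T2M = 22, T2M_MAX = 22, T2M_MIN = 22, T2MDEW = 22,
                      PRECTOT = 5, SRAD_DOWN = 18, LWD = 35, ALT = 100)
  a <- param_atmospheric(param_radiation(w))
  expect_equal(a$VPD, 0, tolerance = 1e-12)
})

test_that("evapotranspiration is zero when available energy is zero", {
  w <- tibble::tibble(env_id = "x", lat = 0, lon = 0, daysFromStart = 0L,
                      date = as.Date("2020-01-01"),
                      T2M = 20, T2M_MAX = 25, T2M_MIN = 15, T2MDEW = 10,
                      PRECTOT = 7, SRAD_DOWN = 0, LWD = 1000, ALT = 0)
  # LWD so large that net radiation is floored; with SRAD 0, Rn - G <= 0
  a <- param_atmospheric(param_radiation(w))
  expect_equal(a$ETP, 0)
  expect_equal(a$PETP, a$PRECTOT)
})

test_that("atmospheric formulas match independent oracles on random inputs", {
  set.seed(99)
  nrep <- 1000
  t2m <- runif(nrep, -5, 40)
  expect_equal(4098 * sat_vapour_pressure(t2m) / (t2m + 237.3)^2,
               vapply(t2m, oracle_delta, numeric(1)), tolerance = 1e-9)
  lat <- runif(nrep, -60, 60)
  J <- sample(1:365, nrep, replace = TRUE)
  expect_equal(extraterrestrial_radiation(lat, J),
               mapply(oracle_ra, lat, J), tolerance = 1e-6)
})

test_that("process_weather yields all computed columns, finite, idempotently", {
  w <- tiny_weather(q = 2, days = 45)
  done <- process_weather(w)
  computed <- c("N", "n", "SRAD", "T2M_RANGE", "FRUE", "GDD", "SPV",
                "VPD", "ETP", "PETP")
  expect_true(all(computed %in% names(done)))
  expect_true(all(vapply(done[computed], function(x) all(is.finite(x)),
                         logical(1))))
  again <- process_weather(done)
  expect_equal(again[computed], done[computed])
  expect_true(all(done$ETP >= 0))
  expect_equal(done$PETP[done$ETP == 0], done$PRECTOT[done$ETP == 0])
})

test_that("bundled cardinal table covers 14 species and loads by name", {
  tab <- species_cardinals()
  expect_equal(nrow(tab), 14)
  expect_true(all(tab$Tbase1 <= tab$Topt1 & tab$Topt1 <= tab$Topt2 &
                    tab$Topt2 <= tab$Tbase2))
  mz <- cardinal_set("maize")
  expect_equal(unlist(mz[c("Tbase1", "Topt1", "Topt2", "Tbase2")]),
               c(Tbase1 = 8, Topt1 = 30, Topt2 = 37, Tbase2 = 45))
  expect_error(cardinal_set("triticale"), "unknown species")
})
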