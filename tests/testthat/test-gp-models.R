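test_that("kernel expansion reproduces incidence algebra", {
  K <- diag(3)
  dimnames(K) <- list(c("a", "b", "c"), c("a", "b", "c"))
  mem <- c("a", "a", "b", "c", "c")
  E <- expand_kernel(K, mem)
  expect_equal(E, outer(mem, mem, "==") * 1, ignore_attr = TRUE)
  # one record per env: expansion is a reordering
  K2 <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("x", "y"),
                                                   c("x", "y")))
  expect_equal(expand_kernel(K2, c("y", "x")), K2[c(2, 1), c(2, 1)],
               ignore_attr = TRUE)
  expect_error(expand_kernel(K, c("a", "zz")), "zz")
  # observation-level pass-through checks dimension
  expect_equal(expand_kernel(matrix(0, 5, 5), mem, dimension = "n"),
               matrix(0, 5, 5))
  expect_error(expand_kernel(matrix(0, 4, 4), mem, dimension = "n"),
               "4 rows")
})

test_that("balanced Hadamard structures equal the Kronecker product", {
  set.seed(10)
  q <- 3; p <- 4
  K_E <- crossprod(matrix(rnorm(q * q), q)) / q
  dimnames(K_E) <- list(paste0("E", 1:q), paste0("E", 1:q))
  K_G <- crossprod(matrix(rnorm(p * p), p)) / p
  dimnames(K_G) <- list(paste0("G", 1:p), paste0("G", 1:p))
  data <- tidyr::expand_grid(env = rownames(K_E), gid = rownames(K_G))
  data$value <- rnorm(nrow(data))
  data <- met_phenotypes(data)  # env-major, gid-minor
  G_n <- expand_kernel(K_G, data$gid, "p")
  W_n <- expand_kernel(K_E, data$env, "q")
  expect_equal(G_n * W_n, kronecker(K_E, K_G), tolerance = 1e-12)
  E_block <- outer(data$env, data$env, "==") * 1
  expect_equal(G_n * E_block, kronecker(diag(q), K_G), tolerance = 1e-12)
})

test_that("model families assemble the documented term sets", {
  tm <- toy_met(p = 8, q = 3)
  mm <- get_kernel(K_G = list(G = tm$K_G), data = tm$data, family = "MM")
  expect_length(mm$terms, 1)
  expect_equal(attr(mm$terms$G, "tag"), "G")
  mds <- get_kernel(K_G = list(G = tm$K_G), data = tm$data, family = "MDs")
  expect_equal(purrr::map_chr(mds$terms, attr, "tag"),
               c(G = "G", GxE = "GE"))
  emm <- get_kernel(K_G = list(G = tm$K_G), K_E = list(E = tm$K_E),
                    data = tm$data, family = "EMM")
  expect_equal(purrr::map_chr(emm$terms, attr, "tag"),
               c(E = "W", G = "G"))
  rnmds <- get_kernel(K_G = list(G = tm$K_G), K_E = list(E = tm$K_E),
                      data = tm$data, family = "RNMDs")
  expect_equal(unname(purrr::map_chr(rnmds$terms, attr, "tag")),
               c("W", "G", "GE", "GW"))
  expect_error(get_kernel(K_G = list(G = tm$K_G), data = tm$data,
                          family = "RNMM"), "requires enviromic")
  expect_error(get_kernel(data = tm$data, family = "ABC"))
})

test_that("stage kernels multiply out to one W and one GW term per stage", {
  tm <- toy_met(p = 6, q = 5)
  stages <- purrr::map(1:4, ~ tm$K_E)
  names(stages) <- paste0("S", 1:4)
  rn <- get_kernel(K_G = list(G = tm$K_G), K_E = stages, data = tm$data,
                   family = "RNMM")
  expect_length(rn$terms, 9)  # 4 W + 1 G + 4 GW
  tags <- purrr::map_chr(rn$terms, attr, "tag")
  expect_equal(sum(tags == "W"), 4)
  expect_equal(sum(tags == "GW"), 4)
  expect_true(all(c("GxS1", "GxS4") %in% names(rn$terms)))
})

test_that("a missing genomic kernel falls back to identity relatedness", {
  tm <- toy_met(p = 5, q = 3)
  mm <- get_kernel(data = tm$data, family = "MM")
  d <- mm$data
  expect_equal(unname(mm$terms$G), outer(d$gid, d$gid, "==") * 1,
               ignore_attr = TRUE)
})

test_that("the sampler is deterministic under a fixed seed", {
  tm <- toy_met(p = 10, q = 3)
  terms <- get_kernel(K_G = list(G = tm$K_G), data = tm$data,
                      family = "MDs")
  f1 <- kernel_model(terms, iterations = 120, burnin = 40, thinning = 4,
                     seed = 42)
  f2 <- kernel_model(terms, iterations = 120, burnin = 40, thinning = 4,
                     seed = 42)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$yHat, f2$yHat)
  f3 <- kernel_model(terms, iterations = 120, burnin = 40, thinning = 4,
                     seed = 43)
  expect_false(identical(f1$samples, f3$samples))
})

test_that("posterior mean prediction matches the BLUP closed form", {
  set.seed(42)
  p <- 80
  K <- simulate_kinship(p, 600, seed = 5)
  s2g <- 0.7; s2e <- 0.5
  e <- eigen(K, symmetric = TRUE)
  u_true <- drop(e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(p))) *
    sqrt(s2g)
  y <- 2 + u_true + rnorm(p, sd = sqrt(s2e))
  data <- tibble::tibble(env = "E1", gid = rownames(K), value = y)
  fit <- kernel_model(list(G = unname(K)), data = data,
                      fixed = matrix(1, p, 1),
                      iterations = 5000, burnin = 1000, thinning = 2,
                      seed = 9, fix_variances = c(G = s2g, residual = s2e))
  V <- s2g * K + s2e * diag(p)
  Vi <- solve(V)
  X <- matrix(1, p, 1)
  beta_gls <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  oracle <- drop(X %*% beta_gls + s2g * K %*% Vi %*% (y - X %*% beta_gls))
  expect_gt(cor(fit$yHat, oracle), 0.999)
})

test_that("credible intervals are ordered and variances non-negative", {
  tm <- toy_met(p = 10, q = 3)
  terms <- get_kernel(K_G = list(G = tm$K_G), K_E = list(E = tm$K_E),
                      data = tm$data, family = "RNMM")
  fit <- kernel_model(terms, iterations = 200, burnin = 50, thinning = 5,
                      seed = 2)
  vc <- tidy(fit)
  expect_true(all(vc$lower <= vc$estimate & vc$estimate <= vc$upper))
  expect_true(all(fit$samples >= 0))
  expect_equal(nrow(vc), 4)
})

test_that("non-PSD terms are rejected with a repair hint", {
  tm <- toy_met(p = 5, q = 3)
  bad <- diag(15)
  bad[1, 2] <- bad[2, 1] <- 2  # indefinite
  expect_error(
    kernel_model(list(B = bad), data = tm$data),
    "psd_repair")
})

test_that("training fit beats the intercept-only baseline", {
  for (seed in c(1, 2, 3)) {
    tm <- toy_met(p = 12, q = 4, seed = seed)
    terms <- get_kernel(K_G = list(G = tm$K_G), data = tm$data,
                        family = "MDs")
    fit <- kernel_model(terms, iterations = 400, burnin = 100,
                        thinning = 5, seed = seed)
    r_model <- cor(tm$data$value, fit$yHat)
    # intercept-only: predictions constant, correlation undefined; the
    # comparable baseline is the env-means model implied by the fixed part
    env_means <- ave(tm$data$value, tm$data$env)
    r_fixed <- cor(tm$data$value, env_means)
    expect_gt(r_model, r_fixed)
  }
})

test_that("missing phenotypes are imputed and reported as predictions", {
  tm <- toy_met(p = 12, q = 4, seed = 5)
  data <- tm$data
  hide <- seq(1, nrow(data), by = 5)
  data$value[hide] <- NA
  terms <- get_kernel(K_G = list(G = tm$K_G), data = data, family = "MDs")
  fit <- kernel_model(terms, iterations = 400, burnin = 100, thinning = 5,
                      seed = 3)
  expect_equal(sum(fit$missing), length(hide))
  expect_true(all(is.finite(fit$yHat)))
  r_hidden <- cor(tm$data$value[fit$missing], fit$yHat[fit$missing])
  expect_gt(r_hidden, 0.2)  # genomic relatedness makes held-out gids predictable
  aug <- augment(fit)
  expect_equal(sum(aug$.predicted), length(hide))
})

test_that("CV1 splits sample whole genotypes without leakage", {
  tm <- toy_met(p = 150, q = 5)
  splits <- cv1_split(tm$data$gid, f = 0.2, rep = 3, seed = 11)
  expect_length(splits, 3)
  for (tr in splits) {
    tr_gids <- unique(tm$data$gid[tr])
    expect_length(tr_gids, 30)  # ceiling(0.2 * 150)
    # every record of a training genotype is in training
    expect_setequal(tr, which(tm$data$gid %in% tr_gids))
  }
  same <- cv1_split(tm$data$gid, f = 0.2, rep = 2, seed = 11)
  expect_identical(same[[1]], splits[[1]])
  expect_false(identical(splits[[1]], splits[[2]]))
  expect_error(cv1_split(tm$data$gid, f = 0.999, rep = 1, seed = 1),
               "no test")
  expect_error(cv1_split(tm$data$gid, f = 0, rep = 1, seed = 1))
})

test_that("CV00 test sets contain only novel genotypes in novel envs", {
  tm <- toy_met(p = 150, q = 5)
  splits <- cv00_split(tm$data, n_train_envs = 3, f = 0.2, rep = 3,
                       seed = 13)
  for (sp in splits) {
    expect_length(sp$train, 90)  # 30 genotypes x 3 envs, balanced
    tr_envs <- unique(tm$data$env[sp$train])
    tr_gids <- unique(tm$data$gid[sp$train])
    expect_length(tr_envs, 3)
    expect_false(any(tm$data$env[sp$test] %in% tr_envs))
    expect_false(any(tm$data$gid[sp$test] %in% tr_gids))
  }
  expect_error(cv00_split(tm$data, n_train_envs = 5), "smaller")
})

test_that("accuracy evaluation reproduces exact correlation cases", {
  tm <- toy_met(p = 10, q = 3)
  n <- nrow(tm$data)
  train <- 1:10
  test <- 11:n
  fits <- tibble::tibble(
    model = c("perfect", "inverted"), rep = 1L,
    train = list(train, train), test = list(test, test),
    yHat = list(tm$data$value, -tm$data$value))
  tab <- evaluate_cv(fits, tm$data)
  expect_equal(tab$r_test, c(1, -1))
  # random predictions decorrelate
  set.seed(6)
  big <- tibble::tibble(env = "E1", gid = sprintf("g%04d", 1:1000),
                        value = rnorm(1000))
  fits2 <- tibble::tibble(model = "noise", rep = 1L, train = list(1:10),
                          test = list(11:1000),
                          yHat = list(rnorm(1000)))
  expect_lt(abs(evaluate_cv(fits2, big)$r_test), 0.1)
  # degenerate predictions flag as NA
  fits3 <- tibble::tibble(model = "flat", rep = 1L, train = list(train),
                          test = list(test),
                          yHat = list(rep(0, n)))
  tab3 <- suppressWarnings(evaluate_cv(fits3, tm$data))
  expect_true(is.na(tab3$r_test))
})
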