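# Hierarchical Bayesian mixed model fitted by an eigendecomposition Gibbs
# sampler. Each covariance term K_k is eigendecomposed once; random effects
# are sampled in the rotated basis where their full conditionals are
# independent Gaussians, which keeps every sweep at O(n * rank) per term.

#' Fit a Bayesian kernel mixed model
#'
#' Samples from the posterior of
#' `y = X beta + sum_k u_k + e`, `u_k ~ N(0, sigma2_k K_k)`,
#' `e ~ N(0, sigma2_e I)`, with a flat prior on the fixed effects and
#' scaled-inverse-chi-square priors (df 5) on the variance components,
#' scaled so the random terms jointly receive a prior mode of half of
#' `var(y)` split equally and the residual the other half.
#'
#' Each `K_k` is eigendecomposed once and rank-truncated at eigenvalue
#' 1e-8. Per sweep the rotated coordinates `b_ki` are drawn from their
#' independent Gaussian full conditionals with posterior variance
#' `(1/sigma2_e + 1/(sigma2_k s_i))^-1`, and the variance components from
#' their scaled-inverse-chi-square full conditionals using
#' `u_k' K_k^+ u_k = sum_i b_ki^2 / s_i`. Missing phenotypes are treated
#' as prediction targets and imputed from their conditional each sweep
#' (data augmentation), so the fit predicts them in `yHat`. Fixed effects
#' and the residual variance are conditioned on the observed records
#' only; a fixed-effect column with no observed records (e.g. an
#' entirely held-out environment) is pinned at zero, so held-out levels
#' are predicted at the baseline rather than drifting under the flat
#' prior.
#'
#' @param terms A `model_terms` object from [get_kernel()], or a named
#'   list of n x n covariance matrices (then `data` is required).
#' @param data MET phenotype tibble; defaults to the one carried by
#'   `terms`.
#' @param fixed Fixed-effect design matrix (n rows); defaults to the
#'   environment-membership matrix from `terms`, or an intercept.
#' @param iterations,burnin,thinning Sampler settings (defaults 1000, 200,
#'   10); `iterations` must exceed `burnin`.
#' @param seed Integer seed; same seed gives bit-identical chains.
#' @param prior_df Prior degrees of freedom (default 5).
#' @param fix_variances Optional named numeric vector holding selected
#'   variance components fixed (names are term names and/or
#'   `"residual"`); useful for closed-form cross-checks.
#' @param ci Credible-interval mass for `VarComp` (default 0.95,
#'   equal-tailed).
#' @return Object of class `kernel_fit` with elements `yHat` (posterior
#'   mean prediction per record), `VarComp` (tibble of posterior mean and
#'   credible interval per variance component), `samples` (thinned
#'   post-burn-in draws of the variance components), `data`, `fixed_eff`
#'   (posterior mean of beta) and the sampler settings.
#' @export
kernel_model <- function(terms, data = NULL, fixed = NULL,
                         iterations = 1000, burnin = 200, thinning = 10,
                         seed = NULL, prior_df = 5, ci = 0.95,
                         fix_variances = NULL) {
  if (inherits(terms, "model_terms")) {
    if (is.null(data)) data <- terms$data
    if (is.null(fixed)) fixed <- terms$fixed
    terms <- terms$terms
  }
  if (is.null(data)) stop("`data` is required", call. = FALSE)
  data <- met_phenotypes(data)
  n <- nrow(data)
  iterations <- as.integer(iterations)
  burnin <- as.integer(burnin)
  thinning <- as.integer(thinning)
  stopifnot(iterations > burnin, thinning >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(fixed)) fixed <- matrix(1, n, 1, dimnames = list(NULL, "mu"))
  fixed <- as.matrix(fixed)
  stopifnot(nrow(fixed) == n)
  if (is.null(names(terms))) names(terms) <- paste0("K", seq_along(terms))
  nk <- length(terms)

  # one-time eigendecompositions, rank-truncated
  eig <- purrr::map(terms, function(K) {
    if (nrow(K) != n) stop("covariance term is not n x n", call. = FALSE)
    e <- eigen(K, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values))) {
      stop("covariance term is not positive semi-definite; ",
           "consider psd_repair()", call. = FALSE)
    }
    keep <- e$values > 1e-8
    if (!any(keep)) stop("covariance term has rank 0", call. = FALSE)
    list(U = e$vectors[, keep, drop = FALSE], s = e$values[keep])
  })

  y_obs <- data$value
  miss <- is.na(y_obs)
  vy <- stats::var(y_obs[!miss])
  df0 <- prior_df
  # prior modes: random terms share 50% of var(y) equally, residual 50%
  S0_k <- 0.5 * vy / nk * (df0 + 2) / df0
  S0_e <- 0.5 * vy * (df0 + 2) / df0

  obs <- !miss
  n_obs <- sum(obs)
  X_obs <- fixed[obs, , drop = FALSE]
  identified <- colSums(X_obs^2) > 0
  XtX <- crossprod(X_obs)
  XtX_chol <- chol(XtX + diag(1e-8, ncol(fixed)))

  # state
  y_cur <- y_obs
  y_cur[miss] <- mean(y_obs[!miss])
  s2_k <- rep(0.5 * vy / nk, nk)
  s2_e <- 0.5 * vy
  fixed_k <- match(names(terms), names(fix_variances))
  s2_k[!is.na(fixed_k)] <- fix_variances[fixed_k[!is.na(fixed_k)]]
  fix_e <- "residual" %in% names(fix_variances)
  if (fix_e) s2_e <- fix_variances[["residual"]]
  b <- purrr::map(eig, ~ numeric(length(.x$s)))
  u <- purrr::map(eig, ~ numeric(n))
  beta <- numeric(ncol(fixed))
  total_u <- numeric(n)

  keep_iter <- seq.int(burnin + thinning, iterations, by = thinning)
  n_keep <- length(keep_iter)
  if (n_keep == 0) stop("no post-burn-in samples kept", call. = FALSE)
  samples <- matrix(NA_real_, n_keep, nk + 1,
                    dimnames = list(NULL, c(names(terms), "residual")))
  yhat_acc <- numeric(n)
  beta_acc <- numeric(ncol(fixed))
  kept <- 0L

  for (it in seq_len(iterations)) {
    # fixed effects, flat prior, conditioned on observed records
    rhs <- crossprod(X_obs, (y_cur - total_u)[obs])
    mean_b <- backsolve(XtX_chol, forwardsolve(t(XtX_chol), rhs))
    z <- stats::rnorm(ncol(fixed))
    beta <- drop(mean_b + sqrt(s2_e) * backsolve(XtX_chol, z))
    beta[!identified] <- 0
    xb <- drop(fixed %*% beta)

    # random terms in the rotated basis
    for (k in seq_len(nk)) {
      Uk <- eig[[k]]$U
      sk <- eig[[k]]$s
      e_k <- y_cur - xb - (total_u - u[[k]])
      r <- drop(crossprod(Uk, e_k))
      v <- 1 / (1 / s2_e + 1 / (s2_k[k] * sk))
      b[[k]] <- stats::rnorm(length(sk), mean = v * r / s2_e,
                             sd = sqrt(v))
      new_u <- drop(Uk %*% b[[k]])
      total_u <- total_u - u[[k]] + new_u
      u[[k]] <- new_u
      if (is.na(fixed_k[k])) {
        ss <- sum(b[[k]]^2 / sk)
        s2_k[k] <- (ss + df0 * S0_k) /
          stats::rchisq(1, df = length(sk) + df0)
      }
    }

    fitted <- xb + total_u
    if (!fix_e) {
      sse <- sum((y_cur[obs] - fitted[obs])^2)
      s2_e <- (sse + df0 * S0_e) / stats::rchisq(1, df = n_obs + df0)
    }

    if (!all(is.finite(c(beta, s2_k, s2_e)))) {
      stop("non-finite draw at sweep ", it, call. = FALSE)
    }

    if (any(miss)) {
      y_cur[miss] <- fitted[miss] +
        stats::rnorm(sum(miss), sd = sqrt(s2_e))
    }

    if (it %in% keep_iter) {
      kept <- kept + 1L
      samples[kept, ] <- c(s2_k, s2_e)
      yhat_acc <- yhat_acc + fitted
      beta_acc <- beta_acc + beta
    }
  }

  alpha <- (1 - ci) / 2
  vc <- tibble::tibble(
    term = colnames(samples),
    tag = c(purrr::map_chr(terms, ~ attr(.x, "tag") %||% "K"), "residual"),
    estimate = colMeans(samples),
    lower = apply(samples, 2, stats::quantile, probs = alpha),
    upper = apply(samples, 2, stats::quantile, probs = 1 - alpha))

  structure(list(
    yHat = yhat_acc / n_keep,
    VarComp = vc,
    samples = samples,
    fixed_eff = stats::setNames(beta_acc / n_keep, colnames(fixed)),
    data = data,
    missing = miss,
    iterations = iterations, burnin = burnin, thinning = thinning,
    seed = seed, ci = ci), class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat("<kernel_fit> ", nrow(x$data), " records (", sum(x$missing),
      " predicted), ", x$iterations, " sweeps (burn-in ", x$burnin,
      ", thin ", x$thinning, ")\n", sep = "")
  print(x$VarComp)
  invisible(x)
}

#' Tidy the variance components of a kernel model fit
#'
#' @param x A `kernel_fit`.
#' @param ... Unused.
#' @return Tibble with one row per variance component: `term`, `tag`,
#'   `estimate` (posterior mean), `lower`, `upper` (equal-tailed credible
#'   interval).
#' @export
tidy.kernel_fit <- function(x, ...) x$VarComp

#' One-row summary of a kernel model fit
#'
#' @param x A `kernel_fit`.
#' @param ... Unused.
#' @return Tibble with record counts, training-set correlation between
#'   observed and predicted values, residual variance and sampler
#'   settings.
#' @export
glance.kernel_fit <- function(x, ...) {
  obs <- !x$missing
  tibble::tibble(
    n = nrow(x$data),
    n_predicted = sum(x$missing),
    r_train = stats::cor(x$data$value[obs], x$yHat[obs]),
    sigma2_e = x$VarComp$estimate[x$VarComp$term == "residual"],
    iterations = x$iterations,
    burnin = x$burnin,
    thinning = x$thinning)
}

#' Augment MET data with model predictions
#'
#' @param x A `kernel_fit`.
#' @param ... Unused.
#' @return The canonicalized phenotype tibble with `.fitted` (posterior
#'   mean prediction) and `.predicted` (whether the record's value was
#'   missing, i.e. a prediction target).
#' @export
augment.kernel_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$yHat, .predicted = x$missing)
}
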