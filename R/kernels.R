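# Enviromic similarity kernels: linear variance-covariance and Gaussian.

#' Enviromic similarity kernels
#'
#' Builds environment x environment similarity kernels from an environment
#' x descriptor matrix (a [w_matrix()] output, an [env_typing()] profile,
#' or any labeled numeric matrix).
#'
#' The linear kernel is the trace-normalized variance-covariance matrix
#' `K_E = X X' / (trace(X X') / nrow(X))`, so that `trace(K_E) = nrow(X)`
#' (mean diagonal 1). The Gaussian kernel is
#' `K_E = exp(-h D^2 / Q)` with `D^2` the squared Euclidean distances
#' between environment rows, `Q` the median of the off-diagonal `D^2`
#' (the structural zero diagonal is excluded), and `h` a bandwidth factor,
#' 1 by default or estimated from phenotypes via [estimate_bandwidth()]
#' when `Y` is given.
#'
#' @param X Environment x descriptor matrix, or an `envirotype_profile`.
#' @param gaussian If `TRUE` use the Gaussian kernel; default linear.
#' @param h Gaussian bandwidth; `NULL` means 1, or data-driven when `Y`
#'   is supplied.
#' @param Y Optional phenotype tibble (`env_id`/`env`, `value`) used to
#'   estimate `h` by marginal likelihood.
#' @param stages Optional stage labels. Column names carrying a stage
#'   label (the `w_matrix()` `var_stat_window` convention) are grouped,
#'   and one environment kernel is returned per stage.
#' @return A list with `varCov` (descriptor x descriptor relatedness,
#'   diagnostics only) and `envCov` (the enviromic kernel `K_E`, or a
#'   named list of stage kernels when `stages` is given).
#' @export
env_kernel <- function(X, gaussian = FALSE, h = NULL, Y = NULL,
                       stages = NULL) {
  if (inherits(X, "envirotype_profile")) X <- profile_matrix(X)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 environments", call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- paste0("E", seq_len(nrow(X)))
  build <- function(Xs) {
    if (gaussian) {
      D2 <- as.matrix(stats::dist(Xs))^2
      hh <- h
      if (is.null(hh)) {
        hh <- if (is.null(Y)) 1 else estimate_bandwidth(D2, Y)
      }
      Q <- stats::median(D2[upper.tri(D2)])
      if (!is.finite(Q) || Q <= 0) {
        warning("identical environment rows: distance median floored")
        Q <- max(.Machine$double.eps * max(1, max(D2)), 1e-12)
      }
      K <- exp(-hh * D2 / Q)
      attr(K, "h") <- hh
      attr(K, "Q") <- Q
      attr(K, "kind") <- "gaussian"
    } else {
      XXt <- tcrossprod(Xs)
      tr <- sum(diag(XXt))
      if (tr <= 0) stop("all-zero descriptor matrix: zero trace",
                        call. = FALSE)
      K <- XXt / (tr / nrow(Xs))
      attr(K, "kind") <- "linear"
    }
    K
  }
  var_cov <- function(Xs) {
    if (gaussian) {
      D2 <- as.matrix(stats::dist(t(Xs)))^2
      Q <- stats::median(D2[upper.tri(D2)])
      if (!is.finite(Q) || Q <= 0) Q <- 1
      exp(-(if (is.null(h)) 1 else h) * D2 / Q)
    } else {
      XtX <- crossprod(Xs)
      tr <- sum(diag(XtX))
      if (tr <= 0) XtX else XtX / (tr / ncol(Xs))
    }
  }
  if (is.null(stages)) {
    list(varCov = var_cov(X), envCov = build(X))
  } else {
    ks <- purrr::map(stages, function(s) {
      cols <- grepl(paste0("_", s, "$"), colnames(X)) |
        grepl(paste0("_", s, "_"), colnames(X))
      if (!any(cols)) {
        stop("no descriptor columns found for stage `", s, "`",
             call. = FALSE)
      }
      build(X[, cols, drop = FALSE])
    })
    names(ks) <- stages
    list(varCov = var_cov(X), envCov = ks)
  }
}

#' Bandwidth estimation for the Gaussian kernel
#'
#' Grid search maximizing the Gaussian-process profile marginal likelihood
#' of environment-mean phenotypes under `K(h) = exp(-h D^2 / Q)` (plus a
#' small nugget): the intercept and scale are profiled out analytically,
#' and the grid value with the highest log marginal likelihood is
#' returned.
#'
#' @param D2 Squared-Euclidean distance matrix between environments, with
#'   environment rownames.
#' @param Y Phenotype tibble with an environment column (`env_id` or
#'   `env`) and a `value` column, or a named vector of environment means;
#'   `NULL` returns the default bandwidth 1.
#' @param grid Candidate bandwidths (default `2^(-3:3)`).
#' @param nugget Relative diagonal jitter (default 1e-4).
#' @return The selected bandwidth (scalar).
#' @export
estimate_bandwidth <- function(D2, Y, grid = 2^(-3:3), nugget = 1e-4) {
  if (is.null(Y)) return(1)
  if (is.data.frame(Y)) {
    env_col <- intersect(c("env_id", "env"), names(Y))[1]
    if (is.na(env_col)) stop("Y needs an `env_id` or `env` column",
                             call. = FALSE)
    ym <- tapply(Y$value, Y[[env_col]], mean, na.rm = TRUE)
  } else {
    ym <- Y
  }
  if (!is.null(rownames(D2)) && !is.null(names(ym))) {
    common <- intersect(rownames(D2), names(ym))
    if (length(common) < 2) stop("Y does not align with D2 environments",
                                 call. = FALSE)
    ym <- ym[common]
    D2 <- D2[common, common]
  }
  y <- as.numeric(ym)
  n <- length(y)
  if (stats::sd(y) == 0) {
    warning("constant phenotypes: flat marginal likelihood, returning h = 1")
    return(1)
  }
  Q <- stats::median(D2[upper.tri(D2)])
  if (!is.finite(Q) || Q <= 0) Q <- 1
  ll <- purrr::map_dbl(grid, function(hh) {
    V <- exp(-hh * D2 / Q) + diag(nugget, n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    mu <- sum(Vi_y) / sum(Vi_1)
    r <- y - mu
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    s2 <- sum(r * Vi_r) / n
    -0.5 * (n * log(s2) + logdet + n)
  })
  grid[which.max(ll)]
}

#' Repair a nearly positive semi-definite kernel
#'
#' Floors eigenvalues below `eps` and reconstructs the matrix. For
#' Gaussian-kind kernels (attribute `kind == "gaussian"`) the unit
#' diagonal is restored after reconstruction.
#'
#' @param K Symmetric matrix (asymmetry beyond 1e-8 is an error).
#' @param eps Eigenvalue floor (default 1e-8).
#' @return Repaired matrix with the same dimnames and attributes.
#' @export
psd_repair <- function(K, eps = 1e-8) {
  if (max(abs(K - t(K))) > 1e-8) {
    stop("kernel is not symmetric", call. = FALSE)
  }
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) >= eps) return(K)
  v <- pmax(e$values, eps)
  R <- e$vectors %*% (v * t(e$vectors))
  dimnames(R) <- dimnames(K)
  if (identical(attr(K, "kind"), "gaussian")) {
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
  }
  for (a in c("kind", "h", "Q")) attr(R, a) <- attr(K, a)
  R
}
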