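# Assembly of observation-level covariance structures for the six
# genomic x enviromic model families.

#' Validate and canonicalize a MET phenotype table
#'
#' Checks the multi-environment-trial phenotype contract — columns `env`,
#' `gid`, `value`; unique (env, gid) pairs; at least one non-missing
#' value — and sorts records env-major, gid-minor, the canonical ordering
#' shared by every covariance term and design matrix.
#'
#' @param data Tibble with columns `env`, `gid`, `value` (missing values
#'   mark prediction targets).
#' @return The canonicalized tibble.
#' @export
met_phenotypes <- function(data) {
  stopifnot(all(c("env", "gid", "value") %in% names(data)))
  if (anyDuplicated(data[c("env", "gid")]) > 0) {
    stop("duplicate (env, gid) records", call. = FALSE)
  }
  if (all(is.na(data$value))) {
    stop("all phenotype values are missing", call. = FALSE)
  }
  data |>
    dplyr::mutate(env = as.character(.data$env),
                  gid = as.character(.data$gid)) |>
    dplyr::arrange(.data$env, .data$gid) |>
    tibble::as_tibble()
}

#' Expand a q x q or p x p kernel to the observation level
#'
#' Computes `Z K Z'` where `Z` is the 0/1 incidence of records onto the
#' kernel's labels — equivalently `K[membership, membership]`. With
#' `dimension = "n"` the kernel is already at the observation level and is
#' passed through after an order check against `membership`.
#'
#' @param K Labeled square kernel matrix.
#' @param membership Character vector mapping each record to a kernel
#'   label (e.g. `data$env` or `data$gid`).
#' @param dimension `"q"`/`"p"` (expand by incidence) or `"n"`
#'   (observation-level pass-through).
#' @return Dense n x n covariance matrix, n = `length(membership)`.
#' @export
expand_kernel <- function(K, membership, dimension = "q") {
  if (dimension == "n") {
    if (nrow(K) != length(membership)) {
      stop("observation-level kernel has ", nrow(K), " rows for ",
           length(membership), " records", call. = FALSE)
    }
    return(unname(K))
  }
  if (is.null(rownames(K))) {
    stop("kernel lacks row labels", call. = FALSE)
  }
  idx <- match(membership, rownames(K))
  if (anyNA(idx)) {
    stop("record label(s) not found in kernel: ",
         paste(unique(membership[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  unname(K[idx, idx, drop = FALSE])
}

model_families <- c("MM", "MDs", "EMM", "EMDs", "RNMM", "RNMDs")

#' Assemble covariance terms for a model family
#'
#' Builds the ordered list of observation-level covariance structures for
#' one of the six model families combining genomic main effects (G),
#' genotype x environment deviations (GE), enviromic main effects (W) and
#' genomic x enviromic reaction-norm interactions (GW):
#' \describe{
#'   \item{MM}{G}
#'   \item{MDs}{G + GE (block-diagonal genomic deviation per environment)}
#'   \item{EMM}{W + G}
#'   \item{EMDs}{W + G + GE}
#'   \item{RNMM}{W + G + GW}
#'   \item{RNMDs}{W + G + GE + GW}
#' }
#' Multiple kernels on either side produce the cross-product of
#' interaction terms (e.g. one W and one GW term per development stage).
#' `K_G = NULL` assumes an identity genotype kernel (no relatedness).
#'
#' @param K_G Named list of p x p genomic kernels (or `NULL`).
#' @param K_E Named list of q x q enviromic kernels (required for E/RN
#'   families); a list of stage kernels from [env_kernel()] works
#'   directly.
#' @param data MET phenotype tibble (see [met_phenotypes()]).
#' @param family Model family name.
#' @param dimension_KE `"q"` (environment-level kernels, default) or
#'   `"n"` (observation-level kernels).
#' @param fixed_effects `"env"` (default) for the environment-membership
#'   design matrix, or `"intercept"` for a global mean only. With a W
#'   term in the model, per-environment fixed effects absorb the
#'   environment levels and leave the enviromic kernel nothing to
#'   predict at new environments; use `"intercept"` when predicting
#'   untested environments through environmental relatedness.
#' @return Object of class `model_terms`: list with `terms` (named list
#'   of n x n matrices with a `tag` attribute in G/GE/W/GW), `fixed`
#'   (environment-membership design matrix), `family` and the
#'   canonicalized `data`.
#' @export
get_kernel <- function(K_G = NULL, K_E = NULL, data, family = "MM",
                       dimension_KE = "q",
                       fixed_effects = c("env", "intercept")) {
  family <- match.arg(family, model_families)
  fixed_effects <- match.arg(fixed_effects)
  data <- met_phenotypes(data)
  n <- nrow(data)
  if (is.null(K_G)) {
    gids <- sort(unique(data$gid))
    K_G <- list(G = diag(length(gids)))
    dimnames(K_G$G) <- list(gids, gids)
  }
  if (!is.list(K_G)) K_G <- list(G = K_G)
  if (is.null(names(K_G))) names(K_G) <- paste0("G", seq_along(K_G))
  needs_E <- family %in% c("EMM", "EMDs", "RNMM", "RNMDs")
  if (needs_E && is.null(K_E)) {
    stop("family ", family, " requires enviromic kernels (K_E)",
         call. = FALSE)
  }
  if (!is.null(K_E) && !is.list(K_E)) K_E <- list(E = K_E)
  if (!is.null(K_E) && is.null(names(K_E))) {
    names(K_E) <- paste0("E", seq_along(K_E))
  }
  G_n <- purrr::map(K_G, expand_kernel, membership = data$gid,
                    dimension = "p")
  E_block <- outer(data$env, data$env, "==") * 1
  W_n <- purrr::map(K_E, expand_kernel, membership = data$env,
                    dimension = dimension_KE)
  terms <- list()
  add <- function(terms, label, M, tag) {
    attr(M, "tag") <- tag
    terms[[label]] <- M
    terms
  }
  if (needs_E) {
    for (e in names(W_n)) terms <- add(terms, e, W_n[[e]], "W")
  }
  for (g in names(G_n)) terms <- add(terms, g, G_n[[g]], "G")
  if (family %in% c("MDs", "EMDs", "RNMDs")) {
    for (g in names(G_n)) {
      terms <- add(terms, paste0(g, "xE"), G_n[[g]] * E_block, "GE")
    }
  }
  if (family %in% c("RNMM", "RNMDs")) {
    for (g in names(G_n)) {
      for (e in names(W_n)) {
        lbl <- paste0(g, "x", e)
        # the block-diagonal GE deviation may already own this label
        if (lbl %in% names(terms)) lbl <- paste0(lbl, "w")
        terms <- add(terms, lbl, G_n[[g]] * W_n[[e]], "GW")
      }
    }
  }
  if (fixed_effects == "env") {
    fixed <- stats::model.matrix(~ 0 + env, data = data)
    colnames(fixed) <- sub("^env", "", colnames(fixed))
  } else {
    fixed <- matrix(1, n, 1, dimnames = list(NULL, "mu"))
  }
  structure(list(terms = terms, fixed = fixed, family = family,
                 data = data),
            class = "model_terms")
}

#' @export
print.model_terms <- function(x, ...) {
  tags <- purrr::map_chr(x$terms, ~ attr(.x, "tag"))
  cat("<model_terms> family ", x$family, ", ", nrow(x$data), " records\n",
      sep = "")
  cat("  random terms: ",
      paste(paste0(names(x$terms), " [", tags, "]"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
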