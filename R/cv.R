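# Cross-validation schemes for multi-environment trials: CV1 (novel
# genotypes, known environments) and CV00 (novel genotypes in novel
# environments).

#' CV1 training splits: novel genotypes at known environments
#'
#' Per replicate, samples `ceiling(f * p)` genotypes without replacement;
#' training records are all records of the sampled genotypes across all
#' environments, and the test set is every record of the remaining
#' genotypes.
#'
#' @param gids Genotype label per record (e.g. `data$gid`).
#' @param f Training fraction of genotypes, in (0, 1).
#' @param rep Number of replicates.
#' @param seed Integer seed.
#' @return List of integer vectors of training record indices, one per
#'   replicate.
#' @export
cv1_split <- function(gids, f = 0.2, rep = 1, seed = NULL) {
  stopifnot(f > 0, f < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ug <- unique(gids)
  p <- length(ug)
  n_tr <- ceiling(f * p)
  if (n_tr < 1) stop("f * p < 1: no genotypes to train on", call. = FALSE)
  if (n_tr >= p) {
    stop("training fraction leaves no test genotypes", call. = FALSE)
  }
  purrr::map(seq_len(rep), function(r) {
    tr_g <- sample(ug, n_tr)
    which(gids %in% tr_g)
  })
}

#' CV00 training splits: novel genotypes at novel environments
#'
#' Per replicate, samples `n_train_envs` environments and
#' `ceiling(f * p)` genotypes; training records are the sampled genotypes
#' within the sampled environments, and the test set is the records of
#' unsampled genotypes in unsampled environments (records mixing a
#' training genotype with a test environment, or vice versa, belong to
#' neither set). Replicates with an empty test cell are resampled (with a
#' message).
#'
#' @param data MET phenotype tibble (`env`, `gid`, `value`).
#' @param n_train_envs Number of training environments, `< q`.
#' @param f Training fraction of genotypes.
#' @param rep Number of replicates.
#' @param seed Integer seed.
#' @return List of splits, each a list with `train` and `test` integer
#'   record indices.
#' @export
cv00_split <- function(data, n_train_envs, f = 0.2, rep = 1, seed = NULL) {
  data <- met_phenotypes(data)
  stopifnot(f > 0, f < 1)
  ue <- unique(data$env)
  ug <- unique(data$gid)
  q <- length(ue)
  p <- length(ug)
  if (n_train_envs >= q) {
    stop("n_train_envs must be smaller than the number of environments",
         call. = FALSE)
  }
  n_tr_g <- ceiling(f * p)
  if (n_tr_g < 1 || n_tr_g >= p) {
    stop("genotype training fraction out of range", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  purrr::map(seq_len(rep), function(r) {
    for (attempt in 1:100) {
      tr_e <- sample(ue, n_train_envs)
      tr_g <- sample(ug, n_tr_g)
      train <- which(data$env %in% tr_e & data$gid %in% tr_g)
      test <- which(!(data$env %in% tr_e) & !(data$gid %in% tr_g))
      if (length(train) > 0 && length(test) > 0) {
        return(list(train = train, test = test))
      }
      message("empty train/test cell in CV00 replicate ", r,
              "; resampling")
    }
    stop("could not draw a non-empty CV00 split", call. = FALSE)
  })
}

#' Fit model families across cross-validation splits
#'
#' Masks the phenotypes outside each training set, fits every model on
#' the masked data, and collects the predictions. Terms (covariance
#' structures) do not depend on the phenotype values, so they are
#' assembled once per model and reused across replicates.
#'
#' @param models Named list of `model_terms` objects (see [get_kernel()]).
#' @param splits List of splits: integer training-index vectors (CV1) or
#'   `list(train, test)` pairs (CV00).
#' @param iterations,burnin,thinning Sampler settings per fit.
#' @param seed Integer seed; each (model, replicate) fit gets a distinct
#'   deterministic sub-seed.
#' @return Tibble with one row per model x replicate: `model`, `rep`,
#'   `train` (list of indices), `test` (list), `yHat` (list of predicted
#'   values for all records).
#' @export
run_cv <- function(models, splits, iterations = 1000, burnin = 200,
                   thinning = 10, seed = 1) {
  stopifnot(is.list(models), !is.null(names(models)))
  grid <- tidyr::expand_grid(model = names(models),
                             rep = seq_along(splits))
  res <- purrr::pmap(grid, function(model, rep) {
    sp <- splits[[rep]]
    train <- if (is.list(sp)) sp$train else sp
    test <- if (is.list(sp)) sp$test else setdiff(
      seq_len(nrow(models[[model]]$data)), train)
    terms <- models[[model]]
    masked <- terms$data
    masked$value[-train] <- NA
    sub_seed <- (as.integer(seed) * 1009L + rep * 101L +
                   match(model, names(models))) %% .Machine$integer.max
    fit <- kernel_model(terms, data = masked,
                        iterations = iterations, burnin = burnin,
                        thinning = thinning, seed = sub_seed)
    tibble::tibble(model = model, rep = rep, train = list(train),
                   test = list(test), yHat = list(fit$yHat))
  })
  dplyr::bind_rows(res)
}

#' Predictive accuracy per model and replicate
#'
#' Pearson correlation between observed and predicted phenotypes on the
#' training and test partitions of each replicate.
#'
#' @param fits Output of [run_cv()] (or a tibble with columns `model`,
#'   `rep`, `train`, `test`, `yHat`).
#' @param data The unmasked MET phenotype tibble the splits refer to.
#' @return Tibble with columns `model`, `rep`, `r_train`, `r_test`.
#'   Zero-variance predictions yield `NA` with a warning.
#' @export
evaluate_cv <- function(fits, data) {
  data <- met_phenotypes(data)
  y <- data$value
  safe_cor <- function(a, b) {
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      warning("zero-variance or degenerate predictions; correlation is NA")
      return(NA_real_)
    }
    stats::cor(a[ok], b[ok])
  }
  purrr::pmap(fits[c("model", "rep", "train", "test", "yHat")],
              function(model, rep, train, test, yHat) {
    tibble::tibble(
      model = model, rep = rep,
      r_train = safe_cor(y[train], yHat[train]),
      r_test = safe_cor(y[test], yHat[test]))
  }) |>
    dplyr::bind_rows()
}

#' Summarize cross-validation accuracy across replicates
#'
#' @param cv_table Output of [evaluate_cv()].
#' @return Tibble with the mean and standard deviation of the test (and
#'   train) correlation per model.
#' @export
cv_summary <- function(cv_table) {
  cv_table |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      r_train_mean = mean(.data$r_train, na.rm = TRUE),
      r_train_sd = stats::sd(.data$r_train, na.rm = TRUE),
      r_test_mean = mean(.data$r_test, na.rm = TRUE),
      r_test_sd = stats::sd(.data$r_test, na.rm = TRUE),
      .groups = "drop")
}
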