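# Environmental characterization: time windows, weather summaries,
# envirotype frequency profiles, and the environment x covariate matrix W.

#' Define time windows over the crop cycle
#'
#' Windows are half-open intervals `[b_i, b_{i+1})` on `daysFromStart`.
#' With one name per interval (`length(names) == length(boundaries) - 1`)
#' the final boundary closes the last window; with one name per boundary
#' the last window is open-ended (extends to the last observed day).
#'
#' @param boundaries Strictly increasing day offsets, e.g.
#'   `c(0, 7, 30, 65, 70, 84, 105)`.
#' @param names Window labels; default `"W1"`, `"W2"`, ...
#' @return Tibble of class `time_windows` with columns `window`, `start`,
#'   `end` (last `end` may be `Inf`).
#' @export
time_windows <- function(boundaries, names = NULL) {
  stopifnot(length(boundaries) >= 2)
  if (any(diff(boundaries) <= 0)) {
    stop("window boundaries must be strictly increasing", call. = FALSE)
  }
  n_int <- length(boundaries) - 1L
  if (is.null(names)) names <- paste0("W", seq_len(n_int))
  if (length(names) == n_int) {
    start <- boundaries[-length(boundaries)]
    end <- boundaries[-1]
  } else if (length(names) == length(boundaries)) {
    start <- boundaries
    end <- c(boundaries[-1], Inf)
  } else {
    stop("`names` must have length(boundaries) or length(boundaries) - 1",
         call. = FALSE)
  }
  structure(tibble::tibble(window = names, start = start, end = end),
            class = c("time_windows", "tbl_df", "tbl", "data.frame"))
}

assign_window <- function(days, windows) {
  out <- rep(NA_character_, length(days))
  for (i in seq_len(nrow(windows))) {
    hit <- days >= windows$start[i] & days < windows$end[i]
    out[hit] <- windows$window[i]
  }
  factor(out, levels = windows$window)
}

#' Summarize daily weather by environment and time window
#'
#' Reduces a daily weather table to one row per environment (and per time
#' window, if given) with one column per variable x statistic. Quantiles
#' use the standard linear-interpolation definition.
#'
#' @param w Weather tibble.
#' @param var_ids Variables to summarize; default every canonical or
#'   computed factor present in `w`.
#' @param statistic One of `"mean"`, `"sum"`, `"quantile"`.
#' @param probs Quantile probabilities when `statistic = "quantile"`
#'   (default 0.25, 0.50, 0.75).
#' @param windows A [time_windows()] or `NULL` for the whole cycle.
#' @return Wide tibble keyed by `env_id` (and `window`), columns named
#'   `var_stat`. Empty windows yield `NA` cells with a warning.
#' @export
summarize_weather <- function(w, var_ids = NULL,
                              statistic = c("mean", "sum", "quantile"),
                              probs = c(0.25, 0.50, 0.75),
                              windows = NULL) {
  statistic <- match.arg(statistic)
  if (is.null(var_ids)) {
    var_ids <- intersect(c(weather_factors(), computed_factors()), names(w))
    var_ids <- setdiff(var_ids, "ALT")
  }
  missing_vars <- setdiff(var_ids, names(w))
  if (length(missing_vars) > 0) {
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  if (statistic == "quantile" && any(probs < 0 | probs > 1)) {
    stop("probs must lie in [0, 1]", call. = FALSE)
  }
  long <- w |>
    dplyr::select("env_id", "daysFromStart", dplyr::all_of(var_ids)) |>
    tidyr::pivot_longer(dplyr::all_of(var_ids), names_to = "var",
                        values_to = "value") |>
    dplyr::mutate(var = factor(.data$var, levels = var_ids))
  keys <- "env_id"
  if (!is.null(windows)) {
    long <- long |>
      dplyr::mutate(window = assign_window(.data$daysFromStart, windows)) |>
      dplyr::filter(!is.na(.data$window))
    keys <- c("env_id", "window")
  }
  stat_fun <- switch(statistic,
    mean = function(x) tibble::tibble(stat = "mean",
                                      value = mean(x, na.rm = TRUE)),
    sum = function(x) tibble::tibble(stat = "sum",
                                     value = sum(x, na.rm = TRUE)),
    quantile = function(x) tibble::tibble(
      stat = paste0("q", formatC(100 * probs, format = "d")),
      value = unname(stats::quantile(x, probs = probs, na.rm = TRUE))))
  res <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "var")))) |>
    dplyr::reframe(stat_fun(.data$value)) |>
    dplyr::mutate(column = paste(.data$var, .data$stat, sep = "_"))
  stat_levels <- unique(res$stat)
  res <- res |>
    dplyr::mutate(column = factor(
      .data$column,
      levels = as.vector(t(outer(var_ids, stat_levels, paste, sep = "_")))))
  wide <- res |>
    dplyr::select(dplyr::all_of(keys), "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value",
                       names_expand = TRUE)
  if (!is.null(windows)) {
    full <- tidyr::expand_grid(env_id = unique(w$env_id),
                               window = factor(windows$window,
                                               levels = windows$window))
    wide <- dplyr::left_join(full, wide, by = c("env_id", "window"))
    if (anyNA(wide[setdiff(names(wide), keys)])) {
      warning("empty window(s): some environment x window cells have no days")
    }
  }
  wide
}

#' Envirotype frequency profile
#'
#' Bins each day's value of each variable into discrete envirotypes and
#' returns the relative frequency of occurrence of each envirotype per
#' environment (and per time window). Bins are half-open `[c_k, c_{k+1})`.
#' With `cardinals = NULL` for a variable, data-driven breaks are taken as
#' pooled quantiles across all environments (default 10/25/50/75/90%)
#' guarded by `-Inf`/`+Inf`.
#'
#' @param w Weather tibble.
#' @param var_ids Variables to type.
#' @param cardinals `NULL`, a numeric vector (applied to a single
#'   variable), or a named list mapping variables to sorted break vectors
#'   (may end with `Inf`). Values outside the given breaks are assigned to
#'   the outermost bin with a warning.
#' @param quantiles Probabilities for data-driven breaks.
#' @param windows A [time_windows()] or `NULL`.
#' @return Long tibble of class `envirotype_profile` with columns
#'   `env_id`, (`window`,) `var`, `bin`, `freq`; per environment (x
#'   window) and variable the frequencies sum to 1.
#' @export
env_typing <- function(w, var_ids, cardinals = NULL,
                       quantiles = c(0.10, 0.25, 0.50, 0.75, 0.90),
                       windows = NULL) {
  stopifnot(all(var_ids %in% names(w)))
  if (is.numeric(cardinals)) {
    if (length(var_ids) != 1) {
      stop("a bare numeric `cardinals` vector needs a single variable",
           call. = FALSE)
    }
    cardinals <- stats::setNames(list(cardinals), var_ids)
  }
  breaks_for <- function(v) {
    br <- cardinals[[v]]
    if (is.null(br)) {
      br <- unique(stats::quantile(w[[v]], probs = quantiles, na.rm = TRUE))
      br <- c(-Inf, br, Inf)
    } else {
      if (is.unsorted(br, strictly = TRUE)) {
        stop("cardinals for `", v, "` must be strictly increasing",
             call. = FALSE)
      }
    }
    br
  }
  long <- w |>
    dplyr::select("env_id", "daysFromStart", dplyr::all_of(var_ids)) |>
    tidyr::pivot_longer(dplyr::all_of(var_ids), names_to = "var",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  keys <- "env_id"
  if (!is.null(windows)) {
    long <- long |>
      dplyr::mutate(window = assign_window(.data$daysFromStart, windows)) |>
      dplyr::filter(!is.na(.data$window))
    keys <- c("env_id", "window")
  }
  out <- purrr::map(var_ids, function(v) {
    br <- breaks_for(v)
    lab <- paste0("[", format(br[-length(br)], trim = TRUE, digits = 6),
                  ",", format(br[-1], trim = TRUE, digits = 6), ")")
    d <- dplyr::filter(long, .data$var == v)
    x <- d$value
    if (any(x < br[1] | x >= br[length(br)])) {
      warning("values of `", v,
              "` outside the cardinal range; assigned to outermost bins")
      x <- pmin(pmax(x, br[1]), br[length(br)] - .Machine$double.eps^0.5)
    }
    idx <- findInterval(x, br, rightmost.closed = FALSE, left.open = FALSE)
    idx <- pmin(pmax(idx, 1L), length(lab))
    d$bin <- factor(lab[idx], levels = lab)
    d |>
      dplyr::count(dplyr::across(dplyr::all_of(keys)), .data$var, .data$bin,
                   .drop = FALSE) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "var")))) |>
      dplyr::mutate(freq = .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.nan(.data$freq)) |>  # env x window cells with no days
      dplyr::select(-"n")
  }) |>
    dplyr::bind_rows() |>
    dplyr::filter(.data$var %in% var_ids)  # drop all-NA var groups
  class(out) <- c("envirotype_profile", class(out))
  out
}

#' Pivot an envirotype profile to a wide frequency matrix
#'
#' @param profile Output of [env_typing()].
#' @return Numeric matrix; rows are environments, columns are
#'   `var_bin(_window)` frequency descriptors.
#' @export
profile_matrix <- function(profile) {
  p <- tibble::as_tibble(profile)
  p$column <- if ("window" %in% names(p)) {
    paste(p$var, p$bin, p$window, sep = "_")
  } else {
    paste(p$var, p$bin, sep = "_")
  }
  p$column <- factor(p$column, levels = unique(p$column))
  wide <- p |>
    dplyr::select("env_id", "column", "freq") |>
    tidyr::pivot_wider(names_from = "column", values_from = "freq",
                       values_fill = 0)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$env_id
  m
}

#' Environment x covariate matrix W
#'
#' Builds the quantitative environmental descriptor matrix: variables are
#' summarized per environment (and per window) with [summarize_weather()],
#' pivoted to one row per environment with columns named
#' `var_stat(_window)` in var-major, then statistic, then window order,
#' then optionally mean-centered and scaled (sample sd, `n - 1`) per
#' column. Quality control removes zero-variance columns and columns whose
#' standardized values exceed `sd_tol` in absolute value; removals are
#' recorded in the `qc_log` attribute.
#'
#' @param w Weather tibble.
#' @param var_ids Variables to include.
#' @param statistic Summary statistic (see [summarize_weather()]).
#' @param probs Quantile probabilities when `statistic = "quantile"`.
#' @param windows A [time_windows()] or `NULL`.
#' @param center,scale Center/scale columns (default `TRUE`).
#' @param qc Apply the outlier screen (default `TRUE`).
#' @param sd_tol Standard-deviation tolerance for the screen (default 3).
#' @return Numeric matrix with environment rownames; attribute `qc_log`
#'   is a tibble of removed columns and reasons.
#' @export
w_matrix <- function(w, var_ids = NULL, statistic = "mean",
                     probs = c(0.25, 0.50, 0.75), windows = NULL,
                     center = TRUE, scale = TRUE, qc = TRUE, sd_tol = 3) {
  s <- summarize_weather(w, var_ids = var_ids, statistic = statistic,
                         probs = probs, windows = windows)
  if (!is.null(windows)) {
    long <- s |>
      tidyr::pivot_longer(-c("env_id", "window"), names_to = "column",
                          values_to = "value") |>
      dplyr::mutate(column = factor(paste(.data$column, .data$window,
                                          sep = "_")))
    # var-major, stat, then window order: windows vary fastest
    base_cols <- setdiff(names(s), c("env_id", "window"))
    lev <- as.vector(t(outer(base_cols, levels(s$window), paste, sep = "_")))
    long$column <- factor(as.character(long$column), levels = lev)
    s <- long |>
      dplyr::select("env_id", "column", "value") |>
      tidyr::pivot_wider(names_from = "column", values_from = "value",
                         names_expand = TRUE)
  }
  m <- as.matrix(s[setdiff(names(s), "env_id")])
  rownames(m) <- s$env_id
  if (nrow(m) < 2 && (center || scale)) {
    stop("need at least 2 environments to center/scale W", call. = FALSE)
  }
  if (anyNA(m)) {
    stop("W has missing cells (empty windows or missing data); ",
         "fill or drop them before building W", call. = FALSE)
  }
  mu <- colMeans(m)
  sd_ <- apply(m, 2, stats::sd)
  std <- sweep(sweep(m, 2, mu), 2, ifelse(sd_ > 0, sd_, 1), "/")
  qc_log <- tibble::tibble(column = character(), reason = character(),
                           value = numeric())
  keep <- rep(TRUE, ncol(m))
  if (qc) {
    zerovar <- sd_ == 0 | !is.finite(sd_)
    outlier <- apply(abs(std), 2, max) > sd_tol & !zerovar
    keep <- !(zerovar | outlier)
    qc_log <- dplyr::bind_rows(
      tibble::tibble(column = colnames(m)[zerovar], reason = "zero_variance",
                     value = 0),
      tibble::tibble(column = colnames(m)[outlier],
                     reason = paste0("abs_std_above_", sd_tol),
                     value = apply(abs(std), 2, max)[outlier]))
    if (!any(keep)) {
      stop("QC removed every column of W (sd_tol = ", sd_tol, "); ",
           "qc_log: ", paste(qc_log$column, collapse = ", "), call. = FALSE)
    }
  }
  out <- if (center && scale) std else if (center) sweep(m, 2, mu)
    else if (scale) sweep(m, 2, ifelse(sd_ > 0, sd_, 1), "/") else m
  out <- out[, keep, drop = FALSE]
  attr(out, "qc_log") <- qc_log
  attr(out, "centered") <- center
  attr(out, "scaled") <- scale
  out
}
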