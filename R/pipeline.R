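# End-to-end pipeline: YAML config in, artifacts + JSON manifest out.

read_square_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(d[-1])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

write_square_csv <- function(m, path) {
  d <- tibble::as_tibble(as.data.frame(m), rownames = "id")
  readr::write_csv(d, path, progress = FALSE)
  invisible(path)
}

default_config <- function() {
  list(
    seed = 1,
    out_dir = "enviromics-run",
    weather = list(synthetic = TRUE),
    species = "maize",
    variables = c("T2M", "T2M_MAX", "T2M_MIN", "PRECTOT", "FRUE", "PETP"),
    windows = NULL,
    kernel = list(gaussian = FALSE, h = 1, stages = NULL),
    model = list(family = "RNMM", iterations = 1000, burnin = 200,
                 thinning = 10),
    phenotypes = list(synthetic = TRUE),
    kinship = list(synthetic = TRUE),
    sim = list(q = 5, p = 50, m = 500, days = 120,
               sigma2_E = 1, sigma2_G = 0.5, sigma2_GE = 0.3,
               sigma2_W = 0.2, sigma2_GW = 0.2, sigma2_e = 0.8),
    cv = NULL)
}

#' Run the full envirotyping-to-prediction pipeline
#'
#' Executes the five pipeline stages — weather input, ecophysiological
#' processing, environmental characterization (typing + W matrix), kernel
#' construction, and model fitting (optionally under cross-validation) —
#' writing every artifact and a JSON run manifest to the output directory.
#' Outputs are a pure function of (inputs, config, seed).
#'
#' @param config Path to a YAML config file, or a config list. Omitted
#'   entries fall back to a synthetic demonstration configuration.
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (!cfg$model$family %in% model_families) {
    stop("unknown model family `", cfg$model$family, "`", call. = FALSE)
  }
  for (p in c(cfg$weather$path, cfg$phenotypes$path, cfg$kinship$path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list(),
                   package_version = as.character(utils::packageVersion(
                     "enviromics")))
  art <- function(name) file.path(cfg$out_dir, name)
  log_stage <- function(stage, outputs) {
    manifest$stages[[stage]] <<- list(
      outputs = outputs,
      md5 = unname(tools::md5sum(outputs)))
  }
  spec <- do.call(sim_spec, c(cfg$sim, list(seed = cfg$seed)))

  # 1. weather input
  weather <- if (!is.null(cfg$weather$path)) {
    read_weather(cfg$weather$path, env_id_column = cfg$weather$env_id %||%
                   "env")
  } else {
    simulate_weather(spec)
  }
  write_weather(weather, art("weather_raw.csv"))
  log_stage("weather", art("weather_raw.csv"))

  # 2. ecophysiological processing
  cardinals <- if (!is.null(cfg$cardinals)) {
    do.call(cardinal_set, cfg$cardinals)
  } else {
    cardinal_set(cfg$species)
  }
  processed <- process_weather(weather, cardinals = cardinals)
  write_weather(processed, art("weather_processed.csv"))
  log_stage("process", art("weather_processed.csv"))

  # 3. characterization
  windows <- if (!is.null(cfg$windows)) {
    time_windows(unlist(cfg$windows$boundaries),
                 unlist(cfg$windows$names))
  }
  typing <- env_typing(processed, var_ids = cfg$variables,
                       windows = windows)
  readr::write_csv(typing, art("envirotypes.csv"), progress = FALSE)
  W <- w_matrix(processed, var_ids = cfg$variables, windows = windows)
  write_square_csv(W, art("w_matrix.csv"))
  jsonlite::write_json(attr(W, "qc_log"), art("w_matrix_qc.json"),
                       dataframe = "rows", pretty = TRUE)
  log_stage("characterization",
            c(art("envirotypes.csv"), art("w_matrix.csv"),
              art("w_matrix_qc.json")))

  # 4. kernels
  KE <- env_kernel(W, gaussian = isTRUE(cfg$kernel$gaussian),
                   h = cfg$kernel$h, stages = cfg$kernel$stages)$envCov
  if (!is.list(KE)) KE <- list(E = KE)
  kernel_files <- purrr::imap_chr(KE, function(K, nm) {
    write_square_csv(K, art(paste0("kernel_", nm, ".csv")))
  })
  log_stage("kernels", unname(kernel_files))

  # 5. model fit (and optional cross-validation)
  K_G <- if (!is.null(cfg$kinship$path)) {
    read_square_csv(cfg$kinship$path)
  } else {
    simulate_kinship(spec$p, spec$m, seed = cfg$seed)
  }
  pheno <- if (!is.null(cfg$phenotypes$path)) {
    met_phenotypes(readr::read_csv(cfg$phenotypes$path,
                                   show_col_types = FALSE))
  } else {
    KE_sim <- env_kernel(W)$envCov
    simulate_met(spec, K_G, KE_sim)$data
  }
  terms <- get_kernel(K_G = list(G = K_G), K_E = KE, data = pheno,
                      family = cfg$model$family)
  fit <- kernel_model(terms, iterations = cfg$model$iterations,
                      burnin = cfg$model$burnin,
                      thinning = cfg$model$thinning, seed = cfg$seed)
  readr::write_csv(tidy(fit), art("varcomp.csv"), progress = FALSE)
  readr::write_csv(augment(fit), art("predictions.csv"), progress = FALSE)
  outputs <- c(art("varcomp.csv"), art("predictions.csv"))
  if (!is.null(cfg$cv)) {
    splits <- if (identical(cfg$cv$scheme, "cv00")) {
      cv00_split(pheno, n_train_envs = cfg$cv$train_envs,
                 f = cfg$cv$f %||% 0.2, rep = cfg$cv$rep %||% 5,
                 seed = cfg$seed)
    } else {
      cv1_split(pheno$gid, f = cfg$cv$f %||% 0.2,
                rep = cfg$cv$rep %||% 5, seed = cfg$seed)
    }
    fits <- run_cv(list(fit = terms), splits,
                   iterations = cfg$model$iterations,
                   burnin = cfg$model$burnin,
                   thinning = cfg$model$thinning, seed = cfg$seed)
    cv_tab <- evaluate_cv(fits, pheno)
    readr::write_csv(cv_tab, art("cv_accuracy.csv"), progress = FALSE)
    outputs <- c(outputs, art("cv_accuracy.csv"))
  }
  log_stage("model", outputs)

  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
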