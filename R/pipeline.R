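#' Run the end-to-end analysis pipeline
#'
#' Executes any subset of the stages `generate` (synthetic data set),
#' `extract` (trajectory features), `filter` (Tukey outlier screen), `fit`
#' (regression + division-asymmetry estimation), `simulate` (branching
#' pedigree), `deterministic` (curves + equilibria) and `report`
#' (simulation-based correlation table, cv summary), writing every artifact
#' to `out_dir` together with a manifest recording the configuration, its
#' hash, the master seed and each stage's inputs and outputs. Stage seeds are
#' derived deterministically from the master seed and the stage name, so
#' re-running a configuration reproduces every artifact byte-identically.
#'
#' The configuration is a named list or a JSON file with keys:
#' `data_set` (1-4) or `params_file`; `seed`; `stages` (character vector, in
#' any order — executed in the canonical order above); and optional stage
#' options `n_cells`, `dt`, `measurement_cv`, `outlier_fraction`,
#' `outlier_ratio_range`, `generations`, `cap`, `burn_in`, `n_cells_target`,
#' `k`, `sides`, `t1_link`, `noise_convention`, `ancestor_x0`.
#'
#' @param config Named list or path to a JSON configuration file.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  params <- if (!is.null(cfg$params_file)) {
    read_params_json(cfg$params_file)
  } else {
    prc1_params(cfg$data_set, noise_convention = cfg$noise_convention)
  }
  path_of <- function(name) file.path(out_dir, name)
  write_params_json(params, path_of("params.json"))

  manifest <- list(config = cfg, config_hash = config_hash(cfg),
                   seed = cfg$seed, stages = list())
  state <- list(features = NULL, features_source = NULL)
  log_stage <- function(stage, t0, inputs, outputs, info = list()) {
    message(sprintf("[prc1dyn] %-12s %5.2fs  %s", stage,
                    as.numeric(Sys.time()) - t0,
                    paste(outputs, collapse = ", ")))
    manifest$stages[[stage]] <<- c(list(inputs = inputs, outputs = outputs),
                                   info)
  }
  ordered <- intersect(c("generate", "extract", "filter", "fit", "simulate",
                         "deterministic", "report"), cfg$stages)

  for (stage in ordered) {
    t0 <- as.numeric(Sys.time())
    sseed <- derive_seed(cfg$seed, stage)
    switch(stage,
      generate = {
        ds <- generate_dataset(
          params, n_cells = cfg$n_cells, dt = cfg$dt,
          measurement_cv = cfg$measurement_cv,
          outlier_fraction = cfg$outlier_fraction,
          outlier_ratio_range = cfg$outlier_ratio_range,
          burn_in = cfg$burn_in, seed = sseed)
        write_trajectories_csv(ds$trajectories, path_of("trajectories.csv"))
        write_truth_tsv(ds$truth, path_of("truth.tsv"))
        log_stage(stage, t0, "params.json", c("trajectories.csv", "truth.tsv"),
                  list(n_cells = nrow(ds$truth),
                       n_outliers = sum(ds$truth$outlier)))
      },
      extract = {
        if (!file.exists(path_of("trajectories.csv"))) {
          abort("Stage `extract` needs trajectories.csv (run `generate` first).")
        }
        traj <- read_trajectories_csv(path_of("trajectories.csv"))
        feats <- extract_features(traj, smoothing_window = cfg$smoothing_window)
        write_features_tsv(feats, path_of("features.tsv"))
        state$features <- feats
        state$features_source <- "features.tsv"
        log_stage(stage, t0, "trajectories.csv", "features.tsv",
                  list(n_extracted = nrow(feats),
                       n_rejected = nrow(attr(feats, "rejected"))))
      },
      filter = {
        if (is.null(state$features)) {
          if (!file.exists(path_of("features.tsv"))) {
            abort("Stage `filter` needs a feature table (run `extract` first).")
          }
          state$features <- read_features_tsv(path_of("features.tsv"))
        }
        flt <- tukey_filter(state$features, k = cfg$k, sides = cfg$sides)
        write_features_tsv(flt$kept, path_of("features_filtered.tsv"))
        writeLines(as.character(flt$removed$cell_id),
                   path_of("removed_ids.txt"))
        jsonlite::write_json(
          list(fences = as.list(flt$fences), k = flt$k, sides = flt$sides,
               n_in = flt$n_in, n_removed = flt$n_removed),
          path_of("filter_report.json"), auto_unbox = TRUE, digits = NA,
          pretty = TRUE)
        state$features <- flt$kept
        state$features_source <- "features_filtered.tsv"
        log_stage(stage, t0, "features.tsv",
                  c("features_filtered.tsv", "removed_ids.txt",
                    "filter_report.json"),
                  list(n_removed = flt$n_removed))
      },
      fit = {
        if (is.null(state$features)) {
          for (cand in c("features_filtered.tsv", "features.tsv")) {
            if (file.exists(path_of(cand))) {
              state$features <- read_features_tsv(path_of(cand))
              state$features_source <- cand
              break
            }
          }
          if (is.null(state$features)) {
            abort("Stage `fit` needs a feature table (run `extract` first).")
          }
        }
        fit <- fit_regressions(state$features, t1_link = cfg$t1_link)
        div <- estimate_division_asymmetry(state$features)
        write_params_json(fitted_params(fit, div), path_of("fitted_params.json"))
        log_stage(stage, t0, state$features_source, "fitted_params.json",
                  list(n_records = fit$n, alpha = div$alpha))
      },
      simulate = {
        ped <- simulate_pedigree(params, n_generations = cfg$generations,
                                 cap = cfg$cap, seed = sseed,
                                 ancestor_x0 = cfg$ancestor_x0)
        write_pedigree_tsv(ped, path_of("pedigree.tsv"))
        log_stage(stage, t0, "params.json", "pedigree.tsv",
                  list(n_cells = nrow(ped)))
      },
      deterministic = {
        grid <- exp(seq(log(cfg$curve_range[1]), log(cfg$curve_range[2]),
                        length.out = cfg$curve_points))
        curves <- cycle_curves(params, grid)
        readr::write_tsv(as_tibble(curves), path_of("curves.tsv"),
                         progress = FALSE)
        eq <- find_equilibria(params)
        jsonlite::write_json(
          list(interval = c(1e3, 1e6), tolerance = 1e-8,
               roots = as.list(as.data.frame(eq))),
          path_of("equilibria.json"), auto_unbox = TRUE, digits = NA,
          pretty = TRUE)
        log_stage(stage, t0, "params.json", c("curves.tsv", "equilibria.json"),
                  list(n_roots = nrow(eq)))
      },
      report = {
        ct <- simulated_correlation_table(
          params, n_cells_target = cfg$n_cells_target, burn_in = cfg$burn_in,
          cap = cfg$cap, seed = sseed, ancestor_x0 = cfg$ancestor_x0)
        write_correlation_tsv(ct, path_of("correlations_simulated.tsv"))
        outputs <- "correlations_simulated.tsv"
        if (!is.null(state$features)) {
          write_correlation_tsv(correlation_table(state$features),
                                path_of("correlations_features.tsv"))
          readr::write_tsv(cv_summary(state$features),
                           path_of("cv_summary.tsv"), progress = FALSE)
          outputs <- c(outputs, "correlations_features.tsv", "cv_summary.tsv")
        }
        log_stage(stage, t0, "params.json", outputs,
                  list(n_cells = attr(ct, "n_cells")))
      }
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

pipeline_defaults <- list(
  stages = c("simulate", "report"),
  n_cells = 500, dt = 0.25, measurement_cv = 0.05, outlier_fraction = 0.1,
  outlier_ratio_range = c(10, 50), smoothing_window = 5,
  generations = 10, cap = 1024, burn_in = 5, n_cells_target = 10000,
  k = 2.5, sides = "both", t1_link = "log", noise_convention = NULL,
  ancestor_x0 = NULL, curve_range = c(1e4, 4e5), curve_points = 200
)

validate_config <- function(config) {
  stopifnot(is.list(config))
  known <- c(names(pipeline_defaults), "data_set", "params_file", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(pipeline_defaults, config, keep.null = TRUE)
  if (is.null(cfg$params_file)) {
    if (is.null(cfg$data_set) || length(cfg$data_set) != 1 ||
        !cfg$data_set %in% 1:4) {
      abort("Config must set `data_set` in 1..4 (or `params_file`).")
    }
  } else if (!file.exists(cfg$params_file)) {
    abort(sprintf("params_file '%s' does not exist.", cfg$params_file))
  }
  if (is.null(cfg$seed) || length(cfg$seed) != 1 || !is.finite(cfg$seed)) {
    abort("Config must set a single integer `seed`.")
  }
  cfg$seed <- as.integer(cfg$seed)
  bad <- setdiff(cfg$stages, c("generate", "extract", "filter", "fit",
                               "simulate", "deterministic", "report"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  if ("fit" %in% cfg$stages && cfg$t1_link == "log" &&
      !is.null(cfg$data_set) && identical(as.integer(cfg$data_set), 2L) &&
      is.null(config$t1_link)) {
    cfg$t1_link <- "identity"  # data set 2's T1 equation is identity-scale
  }
  cfg
}

# deterministic stage seed below 2^31, from the master seed and a label
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(master) * 7919 + h) %% 2147483629)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}
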