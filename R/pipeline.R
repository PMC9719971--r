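#' Experiment configuration
#'
#' Bundles the simulator, split, encoder, synthetic-control and evaluation
#' settings of one end-to-end experiment. `seed`, when given, re-seeds every
#' stage deterministically (simulator: `seed`; split: `seed + 1`; LOS /
#' mortality encoders: `seed + 2` / `seed + 3`; evaluation bootstrap:
#' `seed + 4`).
#'
#' @param sim a [sim_config()].
#' @param split a [split_spec()].
#' @param encoder_los,encoder_mort [encoder_config()]s for the two tasks.
#' @param tasks outcome tasks to run (`"los"`, `"mortality"`).
#' @param k,lambda synthetic-control donor count and ridge penalty.
#' @param donor_mode `"full"` (train+val+test minus the subject, the
#'   leave-one-out full-dataset assumption) or `"test-only"`.
#' @param ablation disable embedding-space segregation.
#' @param n_boot bootstrap resamples for mortality CIs.
#' @param alpha significance level.
#' @param whatif_cutoffs treatment-duration cutoffs (days) for the what-if
#'   analyses (empty vector disables).
#' @param seed optional master seed overriding all stage seeds.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(sim = sim_config(), split = split_spec(),
                              encoder_los = encoder_config("los"),
                              encoder_mort = encoder_config("mortality"),
                              tasks = c("los", "mortality"),
                              k = 10L, lambda = 1, donor_mode = c("full", "test-only"),
                              ablation = FALSE, n_boot = 1000L, alpha = 0.05,
                              whatif_cutoffs = 7L, seed = NULL) {
  donor_mode <- match.arg(donor_mode)
  tasks <- match.arg(tasks, several.ok = TRUE)
  cfg <- list(sim = sim, split = split, encoder_los = encoder_los,
              encoder_mort = encoder_mort, tasks = tasks, k = as.integer(k),
              lambda = lambda, donor_mode = donor_mode,
              ablation = isTRUE(ablation), n_boot = as.integer(n_boot),
              alpha = alpha, whatif_cutoffs = as.integer(whatif_cutoffs),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (!is.null(cfg$seed)) {
    cfg$sim$seed <- cfg$seed
    cfg$split$seed <- cfg$seed + 1L
    cfg$encoder_los$seed <- cfg$seed + 2L
    cfg$encoder_mort$seed <- cfg$seed + 3L
  }
  class(cfg) <- "experiment_config"
  cfg
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys `sim`, `split`, `encoder_los`, `encoder_mort` map to the
#' corresponding constructor arguments; remaining keys map to
#' [experiment_config()] arguments.
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$split)) args$split <- do.call(split_spec, y$split)
  if (!is.null(y$encoder_los)) {
    args$encoder_los <- do.call(encoder_config,
                                c(list(task = "los"), y$encoder_los))
  }
  if (!is.null(y$encoder_mort)) {
    args$encoder_mort <- do.call(encoder_config,
                                 c(list(task = "mortality"), y$encoder_mort))
  }
  rest <- y[setdiff(names(y), c("sim", "split", "encoder_los", "encoder_mort"))]
  do.call(experiment_config, c(args, rest))
}

write_table <- function(dt, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("parquet output requires the arrow package")
    }
    arrow::write_parquet(dt, path)
  } else {
    data.table::fwrite(dt, path)
  }
  path
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end experiment
#'
#' simulate -> preprocess -> train -> estimate -> evaluate, writing every
#' stage artefact plus a manifest (config hash and per-file MD5 checksums)
#' under `out_dir`. Rerunning with an identical configuration reproduces the
#' estimate tables bit-identically.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if missing).
#' @param stages which stages to run (a trailing subset may be omitted).
#' @param format on-disk table format, `"csv"` or `"parquet"`.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory artefacts: `cohort`,
#'   `dataset`, `models`, `embeddings`, `estimates`, `reports`, `whatif`,
#'   `manifest`.
#' @export
run_experiment <- function(config, out_dir,
                           stages = c("simulate", "preprocess", "train",
                                      "estimate", "evaluate"),
                           format = "csv", quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[abxsc] ", ...)
  art <- list()
  ext <- if (format == "parquet") "parquet" else "csv"

  say("simulating cohort (", config$sim$n_stays, " stays)")
  art$cohort <- simulate_cohort(config$sim)
  write_table(art$cohort$events, file.path(out_dir, paste0("events.", ext)), format)
  write_table(art$cohort$abx, file.path(out_dir, paste0("antibiotics.", ext)), format)
  write_table(art$cohort$labels, file.path(out_dir, paste0("labels.", ext)), format)
  # ground truth lives in its own file, never read by the estimator
  write_table(art$cohort$ground_truth$counterfactuals,
              file.path(out_dir, paste0("ground_truth.", ext)), format)
  if (!"preprocess" %in% stages) return(finish_experiment(art, config, out_dir, quiet))

  say("preprocessing")
  art$dataset <- preprocess_cohort(art$cohort$events, art$cohort$abx,
                                   art$cohort$labels, split = config$split,
                                   quiet = quiet)
  jsonlite::write_json(
    list(feature_names = art$dataset$feature_names,
         stats = unclass(art$dataset$stats),
         split = art$dataset$split,
         removed = as.list(art$dataset$removed)),
    file.path(out_dir, "preprocess_meta.json"), auto_unbox = TRUE, digits = NA)
  if (!"train" %in% stages) return(finish_experiment(art, config, out_dir, quiet))

  art$models <- list()
  for (task in config$tasks) {
    enc_cfg <- if (task == "los") config$encoder_los else config$encoder_mort
    say("training ", task, " autoencoder (", enc_cfg$epochs, " epochs)")
    m <- train_autoencoder(art$dataset, enc_cfg, quiet = quiet)
    art$models[[task]] <- m
    save_encoder(m, file.path(out_dir, paste0("encoder_", task, ".rds")))
    hist_path <- file.path(out_dir, paste0("training_log_", task, ".jsonl"))
    writeLines(vapply(seq_len(nrow(m$history)), function(i) {
      jsonlite::toJSON(as.list(m$history[i, ]), auto_unbox = TRUE, digits = NA)
    }, character(1)), hist_path)
  }
  if (!"estimate" %in% stages) return(finish_experiment(art, config, out_dir, quiet))

  art$embeddings <- list(); art$estimates <- list()
  for (task in config$tasks) {
    say("estimating ", task, " outcomes (k=", config$k,
        ", lambda=", config$lambda, ", donors=", config$donor_mode,
        if (config$ablation) ", ablation" else "", ")")
    emb <- embed_antibiotic_days(art$models[[task]], art$dataset)
    art$embeddings[[task]] <- emb
    subj <- if (config$donor_mode == "test-only") art$dataset$split$test else NULL
    donors <- if (config$donor_mode == "test-only") art$dataset$split$test else NULL
    outc <- if (task == "los") "los" else "mortality"
    art$estimates[[task]] <- estimate_all(
      emb, outcome = outc, k = config$k, lambda = config$lambda,
      subject_stays = subj, donor_stays = donors, ablation = config$ablation)
    write_table(art$estimates[[task]],
                file.path(out_dir, paste0("estimates_", task, ".", ext)), format)
  }
  if (!"evaluate" %in% stages) return(finish_experiment(art, config, out_dir, quiet))

  say("evaluating")
  art$reports <- list(); art$whatif <- list()
  boot_seed <- if (is.null(config$seed)) 1L else config$seed + 4L
  for (task in config$tasks) {
    rep <- evaluate_estimates(art$estimates[[task]], alpha = config$alpha,
                              n_boot = if (task == "mortality") config$n_boot else 0L,
                              seed = boot_seed)
    art$reports[[task]] <- rep
    write_table(rep$table, file.path(out_dir, paste0("eval_", task, ".csv")))
  }
  if ("los" %in% config$tasks && length(config$whatif_cutoffs)) {
    for (cut in config$whatif_cutoffs) {
      wi <- whatif_stop_after(art$estimates$los, cut, alpha = config$alpha)
      art$whatif[[as.character(cut)]] <- wi
    }
    jsonlite::write_json(
      lapply(art$whatif, function(w) w[setdiff(names(w), "per_stay")]),
      file.path(out_dir, "whatif.json"), auto_unbox = TRUE, digits = NA)
  }
  finish_experiment(art, config, out_dir, quiet)
}

finish_experiment <- function(art, config, out_dir, quiet) {
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    config_hash = config_hash(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("abxsc")),
    files = lapply(setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))),
           bytes = file.info(file.path(out_dir, f))$size)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  art$manifest <- manifest
  if (!quiet) message("[abxsc] artefacts written to ", normalizePath(out_dir))
  invisible(art)
}
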