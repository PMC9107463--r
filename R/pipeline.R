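default_pipeline_config <- function() {
  list(
    work_dir = "clockvae_run",
    seed = 1,
    canvas_px = 256,
    cohorts = list(
      n_unlabeled = 2000,
      unlabeled_dementia_frac = 0.15,
      fine_tune_dementia = 53, fine_tune_control = 60,
      test_dementia = 18, test_control = 20,
      secondary_dementia = 41, secondary_control = 50
    ),
    preprocess = list(max_pixels = 40000, target_size = 100),
    vae = list(epochs = 50, batch_size = 16, hidden_dim = 512,
               latent_dim = 2, learning_rate = 1e-3, kl_weight = 1),
    classifier = list(head_hidden = 512, epochs = 10, batch_size = 16,
                      learning_rate = 1e-3),
    knn = list(k = 13, region_resolution = 50),
    evaluate = list(n_boot = 100, threshold = 0.5),
    traversal = list(steps = 9, range = c(-4, 4))
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    if (!key %in% names(defaults)) {
      known <- names(defaults)
      d <- utils::adist(key, known)
      hint <- if (min(d) <= 3) {
        sprintf("; did you mean \"%s\"?", known[which.min(d)])
      } else ""
      stop(sprintf("unknown config key \"%s\"%s",
                   paste(c(path, key), collapse = "."), hint),
           call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      user_val <- user[[key]]
      if (!is.list(user_val)) {
        stop(sprintf("config key \"%s\" must be a mapping",
                     paste(c(path, key), collapse = ".")), call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user_val,
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and complete a pipeline configuration
#'
#' Accepts `NULL` (all defaults), a YAML file path, a YAML string, or a
#' nested list. Unknown keys are rejected with a nearest-match suggestion;
#' values are range-checked; missing keys are filled with defaults.
#'
#' @param raw Configuration source.
#' @return An object of class `pipeline_config` (the fully resolved nested
#'   list).
#' @export
validate_config <- function(raw = NULL) {
  user <- if (is.null(raw)) {
    list()
  } else if (is.character(raw) && length(raw) == 1L) {
    parsed <- if (file.exists(raw)) yaml::read_yaml(raw) else yaml::yaml.load(raw)
    if (is.null(parsed)) list() else parsed
  } else if (is.list(raw)) {
    raw
  } else {
    stop("config must be NULL, a YAML path/string, or a list", call. = FALSE)
  }
  cfg <- merge_config(default_pipeline_config(), user)
  check_range(cfg$seed, "seed", 0, .Machine$integer.max, integer = TRUE)
  check_range(cfg$canvas_px, "canvas_px", 64, 4096, integer = TRUE)
  co <- cfg$cohorts
  check_range(co$n_unlabeled, "cohorts.n_unlabeled", 2, 1e6, integer = TRUE)
  check_range(co$unlabeled_dementia_frac, "cohorts.unlabeled_dementia_frac",
              0, 1)
  for (nm in c("fine_tune_dementia", "fine_tune_control", "test_dementia",
               "test_control", "secondary_dementia", "secondary_control")) {
    check_range(co[[nm]], paste0("cohorts.", nm), 1, 1e6, integer = TRUE)
  }
  check_range(cfg$preprocess$max_pixels, "preprocess.max_pixels", 1, 1e9)
  check_range(cfg$preprocess$target_size, "preprocess.target_size", 8, 1024,
              integer = TRUE)
  check_range(cfg$vae$epochs, "vae.epochs", 1, 1e6, integer = TRUE)
  check_range(cfg$vae$batch_size, "vae.batch_size", 1, 1e6, integer = TRUE)
  check_range(cfg$vae$hidden_dim, "vae.hidden_dim", 1, 1e5, integer = TRUE)
  check_range(cfg$vae$latent_dim, "vae.latent_dim", 1, 64, integer = TRUE)
  check_range(cfg$classifier$epochs, "classifier.epochs", 0, 1e6,
              integer = TRUE)
  check_range(cfg$classifier$head_hidden, "classifier.head_hidden", 1, 1e5,
              integer = TRUE)
  check_range(cfg$knn$k, "knn.k", 1, 1e5, integer = TRUE)
  if (cfg$knn$k %% 2 == 0) stop("knn.k must be odd", call. = FALSE)
  check_range(cfg$evaluate$n_boot, "evaluate.n_boot", 2, 1e6, integer = TRUE)
  check_range(cfg$traversal$steps, "traversal.steps", 2, 512, integer = TRUE)
  structure(cfg, class = "pipeline_config")
}

pipeline_stages <- function() {
  c("synth", "preprocess", "train", "finetune", "knn", "evaluate", "traverse")
}

manifest_row <- function(stage, artifact, seed, seconds) {
  data.frame(stage = stage, artifact = artifact,
             md5 = unname(tools::md5sum(artifact)),
             seed = seed, seconds = round(seconds, 3))
}

#' Run the full experiment pipeline
#'
#' Executes, in order: synthetic cohort generation (written as PNG + CSV
#' manifests), preprocessing to 10,000-vectors, VAE pre-training, encoder
#' fine-tuning, kNN operationalization of the latent plane, metric
#' evaluation with bootstrap CIs on the test and secondary-validation
#' cohorts, and a latent traversal montage. Every stage seed is derived
#' deterministically from the master seed. Stages whose artifacts already
#' exist with the recorded content hashes are skipped, so a run interrupted
#' (or partially deleted) resumes from the first missing artifact.
#'
#' @param config A [validate_config()] result, or anything it accepts.
#' @return Invisibly, the run manifest: data frame of stage, artifact path,
#'   md5 hash, stage seed and wall seconds, also written to
#'   `work_dir/run_manifest.csv`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  wd <- cfg$work_dir
  if (!dir.exists(wd)) dir.create(wd, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(wd, "resolved_config.yaml"))
  seeds <- derive_seeds(cfg$seed, length(pipeline_stages()))
  names(seeds) <- pipeline_stages()

  prev_path <- file.path(wd, "run_manifest.csv")
  prev <- if (file.exists(prev_path)) {
    utils::read.csv(prev_path, stringsAsFactors = FALSE)
  } else NULL
  can_skip <- function(artifacts) {
    if (is.null(prev)) return(FALSE)
    all(vapply(artifacts, function(a) {
      file.exists(a) && a %in% prev$artifact &&
        identical(unname(tools::md5sum(a)), prev$md5[prev$artifact == a][1])
    }, logical(1)))
  }
  manifest <- data.frame()
  run_stage <- function(stage, artifacts, fn) {
    if (can_skip(artifacts)) {
      rows <- prev[prev$artifact %in% artifacts, , drop = FALSE]
      manifest <<- rbind(manifest, rows)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    fn(seeds[[stage]])
    el <- proc.time()[["elapsed"]] - t0
    for (a in artifacts) {
      if (!file.exists(a)) {
        stop(sprintf("stage \"%s\" did not produce %s", stage, a),
             call. = FALSE)
      }
      manifest <<- rbind(manifest, manifest_row(stage, a, seeds[[stage]], el))
    }
  }

  co <- cfg$cohorts
  dirs <- file.path(wd, c("unlabeled", "fine_tune", "test", "secondary"))
  names(dirs) <- c("unlabeled", "fine_tune", "test", "secondary")

  # --- stage 1: synthesize cohorts ---------------------------------------
  run_stage("synth", file.path(dirs, "manifest.csv"), function(seed) {
    ss <- derive_seeds(seed, 4)
    n_dem <- round(co$n_unlabeled * co$unlabeled_dementia_frac)
    specs <- list(
      unlabeled = cohort_spec(co$n_unlabeled - n_dem, n_dem, ss[1],
                              canvas_px = cfg$canvas_px),
      fine_tune = cohort_spec(co$fine_tune_control, co$fine_tune_dementia,
                              ss[2], canvas_px = cfg$canvas_px),
      test = cohort_spec(co$test_control, co$test_dementia, ss[3],
                         canvas_px = cfg$canvas_px),
      secondary = cohort_spec(co$secondary_control, co$secondary_dementia,
                              ss[4], canvas_px = cfg$canvas_px)
    )
    for (nm in names(specs)) {
      split_tag <- if (nm == "unlabeled") "train_unlabeled" else
        sub("secondary", "secondary_validation", nm)
      write_cohort(sample_cohort(specs[[nm]]), dirs[[nm]], split = split_tag)
    }
  })

  # --- stage 2: preprocess ------------------------------------------------
  vec_path <- file.path(wd, "vectors.rds")
  run_stage("preprocess", vec_path, function(seed) {
    pp <- cfg$preprocess
    sets <- lapply(names(dirs), function(nm) {
      ch <- read_cohort(dirs[[nm]])
      rep_ <- preprocess_pages(ch$pages, pp$max_pixels, pp$target_size)
      list(x = rep_$vectors, y = ch$manifest$label[rep_$kept],
           n_blank = rep_$n_blank, n_filtered = rep_$n_filtered)
    })
    names(sets) <- names(dirs)
    saveRDS(sets, vec_path, compress = FALSE)
  })

  # --- stage 3: pre-train the VAE ----------------------------------------
  vae_path <- file.path(wd, "vae.rds")
  hist_path <- file.path(wd, "vae_loss_history.csv")
  run_stage("train", c(vae_path, hist_path), function(seed) {
    sets <- readRDS(vec_path)
    fit <- train_vae(sets$unlabeled$x,
                     train_config(epochs = cfg$vae$epochs,
                                  batch_size = cfg$vae$batch_size,
                                  seed = seed,
                                  learning_rate = cfg$vae$learning_rate,
                                  kl_weight = cfg$vae$kl_weight),
                     hidden_dim = cfg$vae$hidden_dim,
                     latent_dim = cfg$vae$latent_dim)
    saveRDS(fit, vae_path, compress = FALSE)
    utils::write.csv(fit$history, hist_path, row.names = FALSE)
  })

  # --- stage 4: fine-tune the encoder classifier -------------------------
  clf_path <- file.path(wd, "classifier.rds")
  run_stage("finetune", clf_path, function(seed) {
    sets <- readRDS(vec_path)
    vae <- readRDS(vae_path)$params
    clf <- init_from_encoder(vae, cfg$classifier$head_hidden, seed)
    ft <- fine_tune(clf, sets$fine_tune$x, sets$fine_tune$y,
                    epochs = cfg$classifier$epochs,
                    batch_size = cfg$classifier$batch_size,
                    learning_rate = cfg$classifier$learning_rate,
                    seed = seed)
    saveRDS(ft, clf_path, compress = FALSE)
  })

  # --- stage 5: kNN operationalization -----------------------------------
  knn_path <- file.path(wd, "knn.rds")
  region_csv <- file.path(wd, "region_map.csv")
  run_stage("knn", c(knn_path, region_csv), function(seed) {
    sets <- readRDS(vec_path)
    vae <- readRDS(vae_path)$params
    lat <- project_cohort(vae, sets$fine_tune$x)
    model <- fit_knn(lat, sets$fine_tune$y, cfg$knn$k)
    rm_ <- region_map(model, resolution = cfg$knn$region_resolution)
    saveRDS(list(model = model, region = rm_), knn_path, compress = FALSE)
    grid <- expand.grid(Z0 = rm_$z0, Z1 = rm_$z1)
    grid$label <- as.vector(rm_$labels)
    utils::write.csv(grid, region_csv, row.names = FALSE)
  })

  # --- stage 6: evaluation with bootstrap CIs ----------------------------
  eval_paths <- file.path(wd, c("report_test.json", "report_secondary.json"))
  run_stage("evaluate", eval_paths, function(seed) {
    sets <- readRDS(vec_path)
    clf <- readRDS(clf_path)$params
    for (i in 1:2) {
      set_nm <- c("test", "secondary")[i]
      s <- sets[[set_nm]]
      rep_ <- bootstrap_ci(s$y, predict_proba(clf, s$x),
                           n_boot = cfg$evaluate$n_boot, seed = seed,
                           threshold = cfg$evaluate$threshold)
      write_metric_report(rep_, eval_paths[i])
    }
  })

  # --- stage 7: latent traversal montage ---------------------------------
  trav_path <- file.path(wd, "traversal.png")
  run_stage("traverse", trav_path, function(seed) {
    vae <- readRDS(vae_path)$params
    grid <- traverse(vae, steps = cfg$traversal$steps,
                     range = cfg$traversal$range,
                     side = cfg$preprocess$target_size)
    write_traversal_png(grid, trav_path)
  })

  utils::write.csv(manifest, prev_path, row.names = FALSE)
  invisible(manifest)
}

#' Write a metric report as JSON
#'
#' @param report A `metric_report` from [bootstrap_ci()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(
    list(metrics = report$metrics,
         confusion = as.list(report$confusion),
         pr_auc = report$pr_auc,
         roc = report$roc, pr = report$pr,
         n_boot = report$n_boot,
         n_boot_effective = report$n_boot_effective,
         seed = report$seed, threshold = report$threshold),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
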