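#' Configuration for an end-to-end synthetic run
#'
#' Bundles every stage's parameters plus a single seed. The defaults define
#' the package's scaled-down synthetic benchmark: 9 training and 3 validation
#' scenes of 16 pods give just over 500 augmented patches per class after
#' placement losses; the
#' shallow DenseNet variant (4 layers per block) is trained for 10 epochs
#' from random initialisation (learning rate 0.01, the standard from-scratch
#' regime rescaled for batch size 8; the step-down schedule, momentum,
#' weight decay and batch size follow [train_config()]); 30 held-out scenes
#' with 5-25 pods each are then tiled, classified, reconstructed and counted.
#'
#' @param out_dir directory for artefacts (config, model, label images,
#'   per-image results, report)
#' @param seed master seed; every stage derives its randomness from it
#' @param arch `"densenet"` or `"lenet"`
#' @param n_train_scenes,n_val_scenes,n_test_scenes scene counts
#' @param pods_per_scene pods in each training/validation scene
#' @param test_pod_range min/max pods of the held-out scenes (cycled across scenes)
#' @param layers_per_block DenseNet depth used for the benchmark
#' @param epochs training epochs
#' @param base_lr benchmark learning rate
#' @param augment_per_point augmented patches per annotation
#' @param points_per_body,points_per_stem annotation density
#' @param scene_args extra arguments passed to [scene_spec()]
#' @param write_scene_images also write the rendered scene PNGs (off by
#'   default; label images, model, results and config are always written)
#' @return a `run_config` list
#' @export
run_config <- function(out_dir = tempfile("podquant_run_"), seed = 1,
                       arch = c("densenet", "lenet"),
                       n_train_scenes = 9, n_val_scenes = 3,
                       n_test_scenes = 30, pods_per_scene = 16,
                       test_pod_range = c(4, 18),
                       layers_per_block = 4, epochs = 10, base_lr = 0.01,
                       augment_per_point = 4, points_per_body = 1,
                       points_per_stem = 16, scene_args = list(),
                       write_scene_images = FALSE) {
  arch <- match.arg(arch)
  structure(as.list(environment()), class = "run_config")
}

scene_seed <- function(master, k) as.integer(master %% 1000000L) * 1000L + k

#' Run the full pipeline on synthetic scenes
#'
#' Generates scenes, builds the augmented patch dataset and normalisation
#' statistics, trains the classifier, then predicts, reconstructs and counts
#' the held-out scenes and evaluates the counts against the generator truth.
#' All stage artefacts are materialised under `config$out_dir`
#' (`config.yaml`, `patch_dataset.rds`, `normalization.json`, `model.rds`,
#' `labels/*.png`, `results.csv`, `report.json`); a rerun with the same
#' config reuses artefacts that already exist when `resume = TRUE`.
#'
#' @param config a [run_config()]
#' @param resume reuse existing artefacts in `out_dir`
#' @param verbose print stage progress
#' @return list with `val_accuracy`, `history`, `agreement`
#'   (from [count_agreement()]), `results` (per-image data frame),
#'   `model_path`, `out_dir`
#' @export
run_pipeline <- function(config, resume = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(c(list(package_version = as.character(utils::packageVersion("podquant"))),
                     config[setdiff(names(config), "scene_args")]),
                   file.path(config$out_dir, "config.yaml"))
  say <- function(...) if (verbose) message(sprintf(...))

  spec_for <- function(k, n_pods) {
    args <- c(list(n_siliques = n_pods, seed = scene_seed(config$seed, k)),
              config$scene_args)
    args$n_overlap_pairs <- if (!is.null(config$scene_args$n_overlap_pairs))
      config$scene_args$n_overlap_pairs else if (n_pods >= 2) 1 else 0
    do.call(scene_spec, args)
  }

  # --- stage 1: classifier (scenes -> patches -> stats -> training) ---
  model_path <- file.path(config$out_dir, "model.rds")
  ds_path <- file.path(config$out_dir, "patch_dataset.rds")
  if (resume && file.exists(model_path)) {
    say("reusing trained model at %s", model_path)
    model <- load_model(model_path)
    stats <- model$norm_stats
    history <- model$history
    val_accuracy <- model$val_accuracy
  } else {
    if (resume && file.exists(ds_path)) {
      ds <- readRDS(ds_path)
    } else {
      say("generating %d training and %d validation scenes",
          config$n_train_scenes, config$n_val_scenes)
      train_scenes <- lapply(seq_len(config$n_train_scenes), function(k)
        generate_scene(spec_for(k, config$pods_per_scene)))
      val_scenes <- lapply(seq_len(config$n_val_scenes), function(k)
        generate_scene(spec_for(100 + k, config$pods_per_scene)))
      if (config$write_scene_images)
        for (s in c(train_scenes, val_scenes))
          write_scene(s, file.path(config$out_dir, "scenes"))
      anns <- function(scenes) lapply(scenes, scene_to_annotations,
                                      points_per_body = config$points_per_body,
                                      points_per_stem = config$points_per_stem)
      train_set <- build_patch_dataset(train_scenes, anns(train_scenes),
                                       augment = TRUE,
                                       augment_per_point = config$augment_per_point,
                                       seed = config$seed)
      val_set <- build_patch_dataset(val_scenes, anns(val_scenes),
                                     augment = FALSE, seed = config$seed + 1)
      ds <- list(train = train_set, val = val_set)
      saveRDS(ds, ds_path)
    }
    say("training on %d patches (%s), validating on %d",
        length(ds$train$y), paste(ds$train$counts, collapse = "/"),
        length(ds$val$y))
    stats <- fit_normalization(ds$train$x)
    jsonlite::write_json(list(channel_means = stats$channel_means,
                              channel_sds = stats$channel_sds),
                         file.path(config$out_dir, "normalization.json"),
                         digits = NA)
    jsonlite::write_json(list(train_annotations_per_class = as.list(ds$train$counts),
                              train_border_skips = ds$train$skipped,
                              val_annotations_per_class = as.list(ds$val$counts),
                              val_border_skips = ds$val$skipped),
                         file.path(config$out_dir, "annotation_counts.json"),
                         auto_unbox = TRUE, digits = NA)
    xs_train <- apply_normalization(ds$train$x, stats)
    xs_val <- apply_normalization(ds$val$x, stats)
    mcfg <- if (config$arch == "densenet")
      densenet_config(layers_per_block = config$layers_per_block)
    else lenet_config()
    tcfg <- train_config(config$arch, base_lr = config$base_lr,
                         epochs = config$epochs, seed = config$seed)
    model <- build_model(mcfg, seed = config$seed)
    fit <- train_classifier(model, list(x = xs_train, y = ds$train$y),
                            list(x = xs_val, y = ds$val$y), tcfg,
                            verbose = verbose)
    model <- fit$model
    history <- fit$history
    val_accuracy <- max(history$val_accuracy)
    model$norm_stats <- stats
    model$history <- history
    model$val_accuracy <- val_accuracy
    save_model(model, model_path)
    write.csv(history, file.path(config$out_dir, "history.csv"),
              row.names = FALSE)
  }

  # --- stage 2: held-out scenes -> tiles -> label images -> counts ---
  labels_dir <- file.path(config$out_dir, "labels")
  dir.create(labels_dir, showWarnings = FALSE)
  pr <- config$test_pod_range
  rows <- vector("list", config$n_test_scenes)
  truths <- integer(config$n_test_scenes)
  for (k in seq_len(config$n_test_scenes)) {
    n_pods <- pr[1] + (k - 1) %% (pr[2] - pr[1] + 1)
    truth <- generate_scene(spec_for(200 + k, n_pods))
    lab_path <- file.path(labels_dir, paste0(truth$image_id, "_labels.png"))
    if (resume && file.exists(lab_path)) {
      lab <- read_mask(lab_path)
    } else {
      grid <- predict_image(model, truth$image, stats)
      rec <- reconstruct_labels(grid)
      lab <- rec$labels
      write_labels(rec, lab_path)
    }
    cnt <- count_image(lab, counter_config(), image_id = truth$image_id)
    s <- cnt$summary
    s$true_count <- truth$true_count
    rows[[k]] <- s
    say("scene %2d: true %d predicted %d", k, truth$true_count, cnt$count)
  }
  results <- do.call(rbind, rows)
  write.csv(results, file.path(config$out_dir, "results.csv"),
            row.names = FALSE)
  agreement <- tryCatch(
    count_agreement(results$predicted_count, results$true_count),
    error = function(e) {
      warning("count agreement not computable: ", conditionMessage(e))
      list(correlation_coefficient = NA_real_, r_squared = NA_real_,
           rmse = sqrt(mean((results$true_count - results$predicted_count)^2)),
           errors = results$true_count - results$predicted_count)
    })
  report <- list(val_accuracy = val_accuracy,
                 correlation_coefficient = agreement$correlation_coefficient,
                 r_squared = agreement$r_squared, rmse = agreement$rmse,
                 n_scenes = config$n_test_scenes)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  list(val_accuracy = val_accuracy, history = history, agreement = agreement,
       results = results, model_path = model_path, out_dir = config$out_dir)
}

#' Compare the two architectures on a shared synthetic patch benchmark
#'
#' Trains LeNet and a shallow DenseNet on the same synthetic patch dataset
#' under the same protocol and reports the best validation accuracy of each,
#' per seed. Used to assert the directional claim that the deeper network is
#' at least as accurate as the baseline.
#'
#' @param seeds integer seeds, one run per seed
#' @param n_train_scenes,n_val_scenes,pods_per_scene dataset size
#' @param epochs training epochs for both models
#' @param layers_per_block DenseNet depth for the comparison
#' @param base_lr learning rate for both models
#' @param verbose print progress
#' @return data frame with seed, lenet and densenet validation accuracies
#' @export
benchmark_architectures <- function(seeds = 1:3, n_train_scenes = 4,
                                    n_val_scenes = 2, pods_per_scene = 12,
                                    epochs = 6, layers_per_block = 2,
                                    base_lr = 0.01, verbose = FALSE) {
  out <- lapply(seeds, function(sd) {
    train_scenes <- lapply(seq_len(n_train_scenes), function(k)
      generate_scene(scene_spec(n_siliques = pods_per_scene,
                                seed = scene_seed(sd, 500 + k))))
    val_scenes <- lapply(seq_len(n_val_scenes), function(k)
      generate_scene(scene_spec(n_siliques = pods_per_scene,
                                seed = scene_seed(sd, 600 + k))))
    anns <- function(scenes) lapply(scenes, scene_to_annotations,
                                    points_per_body = 1, points_per_stem = 12)
    tr <- build_patch_dataset(train_scenes, anns(train_scenes),
                              augment = TRUE, augment_per_point = 3, seed = sd)
    va <- build_patch_dataset(val_scenes, anns(val_scenes), augment = FALSE,
                              seed = sd + 1)
    stats <- fit_normalization(tr$x)
    trn <- list(x = apply_normalization(tr$x, stats), y = tr$y)
    vln <- list(x = apply_normalization(va$x, stats), y = va$y)
    accs <- vapply(c("lenet", "densenet"), function(arch) {
      mcfg <- if (arch == "densenet")
        densenet_config(layers_per_block = layers_per_block)
      else lenet_config()
      tcfg <- train_config(arch, base_lr = base_lr, epochs = epochs, seed = sd)
      fit <- train_classifier(build_model(mcfg, seed = sd), trn, vln, tcfg,
                              verbose = verbose)
      max(fit$history$val_accuracy)
    }, numeric(1))
    data.frame(seed = sd, lenet = accs[["lenet"]],
               densenet = accs[["densenet"]])
  })
  do.call(rbind, out)
}
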