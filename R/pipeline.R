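#' Default run configuration
#'
#' Nested list of every stage's parameters with the package defaults.  Use
#' [run_config()] to override fields; unknown keys are rejected.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    seed = 7L,
    out_dir = NULL,
    data = list(simulate = TRUE, n_per_class = 150L, size = 96L,
                noise_sigma = 0.03, manifest = NULL),
    preprocess = list(kernel_size = 5L, sigma = 1.0, min_object_px = 64L,
                      cleanup = TRUE, normalize = "minmax"),
    detect = list(k = 0.04, window_size = 5L, window_type = "rectangular",
                  rel_threshold = 0.01, nms_radius = 5L, max_points = 200L),
    extract = list(pool = "mean_max", shift_code = FALSE, clip = 0.2),
    augment = list(enabled = FALSE, factor = 2, noise_sigma = 0.02,
                   rotate_deg = 15, shift_frac = 0.1),
    classify = list(models = c("svm", "knn", "dnn"),
                    svm = list(kernel = "radial", C = 1, gamma = NULL),
                    knn = list(k = 1L),
                    dnn = list(hidden_layers = 9L, hidden_width = 128L,
                               learning_rate = 0.01, batch_size = 32L,
                               epochs = 50L, dropout = 0.3, l2 = 0.001,
                               early_stop_patience = 10L)),
    evaluate = list(n_folds = 5L))
}

merge_config <- function(defaults, override, path = "") {
  if (is.null(override)) return(defaults)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[nm] <- list(merge_config(defaults[[nm]], override[[nm]],
                                        paste0(path, nm, "$")))
    } else {
      # single-bracket assignment keeps keys whose new value is NULL
      defaults[nm] <- list(override[[nm]])
    }
  }
  defaults
}

#' Build and validate a run configuration
#'
#' Starts from [default_config()] and applies overrides from a nested list
#' and/or a YAML file.  Any key not present in the defaults is rejected
#' before any work happens, and the structure round-trips losslessly
#' through YAML.
#'
#' @param ... Named overrides (nested lists), e.g.
#'   `data = list(n_per_class = 20)`.
#' @param file Optional YAML config file applied before `...`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- default_config()
  if (!is.null(file)) cfg <- merge_config(cfg, yaml::read_yaml(file))
  cfg <- merge_config(cfg, list(...))
  structure(cfg, class = c("run_config", "list"))
}

load_manifest_images <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "label") %in% names(man)))
  base <- dirname(manifest_path)
  images <- lapply(man$path, function(p) {
    fp <- if (file.exists(p)) p else file.path(base, p)
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", fp)))
    px <- if (ext %in% c("png", "tif", "tiff")) {
      a <- as_pixel_matrix(EBImage::imageData(
        EBImage::channel(EBImage::readImage(fp), "gray")))
      t(a)  # EBImage stores x (columns) first
    } else if (ext == "nii") {
      v <- read_volume(fp)
      as_pixel_matrix(extract_slices(v, list(axis = 3L, n = 1L))[[1]])
    } else stop("unsupported image format: ", fp)
    px
  })
  list(images = images, labels = man$label,
       ids = sprintf("img_%03d", seq_len(nrow(man))))
}

preprocess_image <- function(px, pp) {
  img <- normalize_intensity(px, method = pp$normalize)
  img <- smooth_slice(img, gaussian_kernel(pp$kernel_size, pp$sigma))
  if (isTRUE(pp$cleanup)) {
    img <- suppressWarnings(morphological_cleanup(img, pp$min_object_px))
  }
  img
}

#' Run the full staging pipeline
#'
#' Executes preprocess -> detect -> extract -> aggregate -> cross-validate
#' for every configured classifier head, from either simulated phantoms or a
#' manifest of image files.  When `cfg$out_dir` is set, writes the feature
#' table, a metrics JSON, per-fold confusion CSVs, ROC point CSVs and a YAML
#' log of every effective parameter and seed.  Single-threaded reruns of the
#' same config reproduce the outputs bitwise.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return List with `features` (tibble), `cv` (named list of `stage_cv`),
#'   `folds`, and `config`.
#' @export
run_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  # --- data ------------------------------------------------------------
  if (isTRUE(cfg$data$simulate)) {
    say("simulating ", cfg$data$n_per_class, " phantoms per class")
    ds <- make_dataset(cfg$data$n_per_class,
                       presets = phantom_presets(size = cfg$data$size,
                                                 noise_sigma = cfg$data$noise_sigma),
                       seed = derive_seed(cfg$seed, "simulate"))
    images <- ds$images; labels <- as.character(ds$labels)
    ids <- ds$manifest$id
  } else {
    if (is.null(cfg$data$manifest)) stop("no manifest configured and simulate = FALSE")
    say("loading images from ", cfg$data$manifest)
    loaded <- load_manifest_images(cfg$data$manifest)
    images <- loaded$images; labels <- loaded$labels; ids <- loaded$ids
  }
  # --- preprocess ------------------------------------------------------
  say("preprocessing ", length(images), " slices")
  pre <- lapply(images, preprocess_image, pp = cfg$preprocess)
  # --- detect + extract + aggregate ------------------------------------
  hc <- harris_config(k = cfg$detect$k, window_size = cfg$detect$window_size,
                      window_type = cfg$detect$window_type,
                      rel_threshold = cfg$detect$rel_threshold,
                      nms_radius = cfg$detect$nms_radius,
                      max_points = cfg$detect$max_points)
  say("extracting descriptors")
  features <- suppressWarnings(
    compute_feature_set(pre, labels, ids = ids, cfg = hc,
                        pool = cfg$extract$pool,
                        shift_code = cfg$extract$shift_code,
                        clip = cfg$extract$clip))
  # --- augmentation hook (training folds only; default off) -------------
  augment_fn <- NULL
  if (isTRUE(cfg$augment$enabled)) {
    img_by_id <- stats::setNames(pre, ids)
    lab_by_id <- stats::setNames(labels, ids)
    aug_seed <- derive_seed(cfg$seed, "augment")
    augment_fn <- function(train_data) {
      tr_ids <- train_data$id
      spec <- augmentation_spec(noise_sigma = cfg$augment$noise_sigma,
                                rotate_deg = cfg$augment$rotate_deg,
                                shift_frac = cfg$augment$shift_frac,
                                seed = aug_seed)
      aug <- augment(img_by_id[tr_ids], lab_by_id[tr_ids], spec,
                     n_out = round(cfg$augment$factor * length(tr_ids)),
                     ids = tr_ids)
      new <- seq_along(aug$ids) > length(tr_ids)
      if (!any(new)) return(NULL)
      suppressWarnings(
        compute_feature_set(aug$images[new], aug$labels[new],
                            ids = aug$ids[new], cfg = hc,
                            pool = cfg$extract$pool,
                            shift_code = cfg$extract$shift_code,
                            clip = cfg$extract$clip))
    }
  }
  # --- cross-validate each head ----------------------------------------
  folds <- make_folds(features$label, cfg$evaluate$n_folds,
                      seed = derive_seed(cfg$seed, "folds"))
  head_cfg <- list(
    svm = svm_config(kernel = cfg$classify$svm$kernel, C = cfg$classify$svm$C,
                     gamma = cfg$classify$svm$gamma),
    knn = knn_config(cfg$classify$knn$k),
    dnn = dnn_config(input_width = ncol(feature_matrix(features)),
                     hidden_layers = cfg$classify$dnn$hidden_layers,
                     hidden_width = cfg$classify$dnn$hidden_width,
                     learning_rate = cfg$classify$dnn$learning_rate,
                     batch_size = cfg$classify$dnn$batch_size,
                     epochs = cfg$classify$dnn$epochs,
                     dropout = cfg$classify$dnn$dropout,
                     l2 = cfg$classify$dnn$l2,
                     early_stop_patience = cfg$classify$dnn$early_stop_patience))
  cv <- list()
  for (model in cfg$classify$models) {
    say("cross-validating ", model)
    cv[[model]] <- cross_validate(features, model, cfg = head_cfg[[model]],
                                  folds = folds,
                                  seed = derive_seed(cfg$seed, model),
                                  augment_fn = augment_fn)
  }
  out <- list(features = features, cv = cv, folds = folds, config = cfg)
  # --- artifacts --------------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(features, file.path(cfg$out_dir, "features.csv"),
              row.names = FALSE)
    metrics <- lapply(cv, function(x) {
      g <- glance(x)
      c(as.list(g), list(per_fold_accuracy = x$per_fold$accuracy,
                         auc = stats::setNames(x$roc$auc$auc, x$roc$auc$class)))
    })
    jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (model in names(cv)) {
      for (f in seq_len(cv[[model]]$n_folds)) {
        write.csv(as.data.frame(unclass(cv[[model]]$confusion[[f]])),
                  file.path(cfg$out_dir,
                            sprintf("confusion_%s_fold%d.csv", model, f)))
      }
      write.csv(cv[[model]]$roc$points,
                file.path(cfg$out_dir, sprintf("roc_%s.csv", model)),
                row.names = FALSE)
    }
    log <- list(config = unclass_deep(cfg),
                seeds = list(global = cfg$seed,
                             simulate = derive_seed(cfg$seed, "simulate"),
                             folds = derive_seed(cfg$seed, "folds")),
                n_images = length(images),
                elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    yaml::write_yaml(log, file.path(cfg$out_dir, "run_log.yaml"))
  }
  out
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
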