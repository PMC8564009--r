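#' Extract all three feature blocks from one calibrated cube
#'
#' @param cube a calibrated [msi_cube()].
#' @param roi an [roi_mask()] or `NULL`.
#' @param glcm a [glcm_config()].
#' @param mapping an [rgb_mapping()].
#' @param white_point reference white for the CIELAB conversion.
#' @return Named list of named numeric vectors `ms` (n_bands), `cielab`
#'   (3) and `texture` (4 x n_bands).
#' @export
extract_features <- function(cube, roi = NULL, glcm = glcm_config(),
                             mapping = rgb_mapping(),
                             white_point = default_white_point()) {
  list(ms = ms_features(cube, roi),
       cielab = cielab_features(cube, roi, mapping, white_point),
       texture = extract_texture(cube, roi, glcm))
}

#' The six feature-set definitions of the experiment grid
#'
#' Three single-modality sets and three fused sets, with block order fixed
#' for reproducible column ordering: MS (6), CIELAB (3), Texture (24),
#' MS + Texture (30), CIELAB + Texture (27), MS + Texture + CIELAB (33).
#'
#' @return Named list mapping feature-set name to its ordered modalities.
#' @export
default_feature_sets <- function() {
  list("MS" = "MS",
       "CIELAB" = "CIELAB",
       "Texture" = "Texture",
       "MS + Texture" = c("MS", "Texture"),
       "CIELAB + Texture" = c("CIELAB", "Texture"),
       "MS + Texture + CIELAB" = c("MS", "Texture", "CIELAB"))
}

features_to_blocks <- function(feat_rows, labels) {
  tags <- c(ms = "MS", cielab = "CIELAB", texture = "Texture")
  blocks <- lapply(names(tags), function(part) {
    x <- do.call(rbind, lapply(feat_rows, `[[`, part))
    feature_matrix(x, rep(tags[[part]], ncol(x)), labels)
  })
  names(blocks) <- tags
  blocks
}

#' Build per-modality feature blocks from a synthetic dataset
#'
#' Streams through the generator sample by sample (generate, calibrate,
#' extract, discard the cube) so large datasets never sit in memory, and
#' returns the three modality blocks plus the generator manifest.
#'
#' @param gen_config a [generator_config()].
#' @param glcm a [glcm_config()].
#' @param mapping an [rgb_mapping()].
#' @param white_point reference white.
#' @param roi_method passed to [segment_roi()].
#' @return List with `blocks` (named list of `feature_matrix`: MS, CIELAB,
#'   Texture), `labels` and `manifest`.
#' @export
build_feature_dataset <- function(gen_config = generator_config(),
                                  glcm = glcm_config(),
                                  mapping = rgb_mapping(),
                                  white_point = default_white_point(),
                                  roi_method = "full_frame") {
  classes <- names(gen_config$n_per_class)
  labels <- factor(rep(classes, gen_config$n_per_class), levels = classes)
  n <- length(labels)
  seeds <- withr::with_seed(gen_config$seed, sample.int(2147483646L, n))
  feat_rows <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tpl <- gen_config$class_templates[[as.character(labels[i])]]
    s <- generate_sample(tpl, gen_config, seed = seeds[i])
    cal <- calibrate(s$raw, s$frames)
    roi <- if (roi_method == "full_frame") s$roi
           else segment_roi(cal, roi_method)
    feat_rows[[i]] <- extract_features(cal, roi, glcm, mapping, white_point)
    rows[[i]] <- data.frame(id = i, class = s$truth$class, seed = seeds[i])
  }
  list(blocks = features_to_blocks(feat_rows, labels), labels = labels,
       manifest = do.call(rbind, rows))
}

#' Read a directory of cubes with a labels manifest into feature blocks
#'
#' The directory must contain `manifest.csv` with columns `file` and
#' `class`; each file is a cube saved by [save_cube()] (`.json` archives or
#' `.tif`/`.tiff` multi-page files with their sidecars). Raw cubes require
#' matching `<file>.dark`/`<file>.ref` frames and are not supported here:
#' cubes must already be calibrated.
#'
#' @inheritParams build_feature_dataset
#' @param dir directory path.
#' @return As [build_feature_dataset()].
#' @export
read_cube_dataset <- function(dir, glcm = glcm_config(),
                              mapping = rgb_mapping(),
                              white_point = default_white_point(),
                              roi_method = "full_frame") {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) {
    stop("cube directory needs a labels manifest: ", mf_path,
         " (columns: file, class)")
  }
  mf <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  if (!all(c("file", "class") %in% names(mf))) {
    stop("manifest.csv must have columns 'file' and 'class'")
  }
  labels <- factor(mf$class)
  feat_rows <- lapply(seq_len(nrow(mf)), function(i) {
    path <- file.path(dir, mf$file[i])
    dialect <- if (grepl("\\.json$", path)) "json" else "tiff"
    cube <- load_cube(path, dialect)
    if (!cube$is_calibrated) stop("cube is not calibrated: ", path)
    roi <- if (roi_method == "full_frame") NULL
           else segment_roi(cube, roi_method)
    extract_features(cube, roi, glcm, mapping, white_point)
  })
  list(blocks = features_to_blocks(feat_rows, labels), labels = labels,
       manifest = mf)
}

#' Pipeline configuration
#'
#' Bundles every sub-configuration of the experiment: input source,
#' GLCM settings, CIELAB mapping and white point, split sizes, classifier
#' grid, feature-set grid and the global seed.
#'
#' @param generator a [generator_config()] for synthetic input, or a
#'   directory path of saved cubes.
#' @param glcm a [glcm_config()].
#' @param mapping an [rgb_mapping()].
#' @param white_point reference white.
#' @param split a [split_spec()].
#' @param classifiers named list of [classifier_spec()]s.
#' @param feature_sets named list of modality combinations.
#' @param cv_folds number of cross-validation folds.
#' @param roi_method ROI selection method.
#' @param seed global seed (propagated to generator, split and
#'   classifiers unless they were configured explicitly).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            glcm = glcm_config(),
                            mapping = rgb_mapping(),
                            white_point = default_white_point(),
                            split = split_spec(),
                            classifiers = NULL,
                            feature_sets = default_feature_sets(),
                            cv_folds = 10L,
                            roi_method = "full_frame",
                            seed = 1L) {
  if (is.null(classifiers)) {
    classifiers <- list(LSVM = classifier_spec("linear_svm", seed = seed),
                        LDA = classifier_spec("lda", seed = seed),
                        RF = classifier_spec("random_forest", seed = seed))
  }
  structure(list(generator = generator, glcm = glcm, mapping = mapping,
                 white_point = white_point, split = split,
                 classifiers = classifiers, feature_sets = feature_sets,
                 cv_folds = as.integer(cv_folds), roi_method = roi_method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys (all optional): `seed`; `generator`
#' (`image_size`, `n_per_class`, `noise_sd`, `separation_scale`, `null`
#' (logical), ...) or `input_dir`; `glcm` (`levels`, `distance`, `angles`,
#' `symmetric`, `average_angles`); `spectral` (`rgb_bands_nm`,
#' `white_point`); `split` (`n_calibration`, `n_prediction`); `svm_c`;
#' `rf_n_trees`; `cv_folds`; `roi_method`; `feature_sets` (names from
#' [default_feature_sets()]).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  gen <- if (!is.null(y$input_dir)) {
    y$input_dir
  } else {
    g <- y$generator %||% list()
    args <- list(seed = as.integer(g$seed %||% seed))
    for (k in c("image_size", "n_per_class", "noise_sd", "separation_scale",
                "illumination_order", "illumination_amplitude",
                "brightness_jitter_sd", "band_jitter_sd",
                "contrast_jitter_sd", "foreground")) {
      if (!is.null(g[[k]])) args[[k]] <- g[[k]]
    }
    if (!is.null(args$image_size)) {
      args$image_size <- as.integer(unlist(args$image_size))
    }
    if (!is.null(args$n_per_class)) {
      args$n_per_class <- unlist(args$n_per_class)
    }
    cfg <- do.call(generator_config, args)
    if (isTRUE(g[["null"]])) cfg <- do.call(null_generator_config, args)
    cfg
  }
  gl <- y$glcm %||% list()
  glcm <- glcm_config(
    n_levels = as.integer(gl$levels %||% 64L),
    distance = as.integer(gl$distance %||% 1L),
    angles_deg = as.numeric(unlist(gl$angles %||% c(0, 45, 90, 135))),
    symmetric = gl$symmetric %||% TRUE,
    average_over_angles = gl$average_angles %||% TRUE)
  sp <- y$spectral %||% list()
  mapping <- if (is.null(sp$rgb_bands_nm)) rgb_mapping()
             else do.call(rgb_mapping, as.list(unlist(sp$rgb_bands_nm)))
  white_point <- if (is.null(sp$white_point)) default_white_point()
                 else as.numeric(unlist(sp$white_point))
  spl <- y$split %||% list()
  split <- split_spec(
    n_calibration = as.integer(spl$n_calibration %||% 445L),
    n_prediction = as.integer(spl$n_prediction %||% 110L),
    seed = as.integer(spl$seed %||% seed))
  classifiers <- list(
    LSVM = classifier_spec("linear_svm", svm_c = y$svm_c %||% 0.6,
                           seed = seed),
    LDA = classifier_spec("lda", seed = seed),
    RF = classifier_spec("random_forest",
                         rf_n_trees = y$rf_n_trees %||% 160L, seed = seed))
  fs <- default_feature_sets()
  if (!is.null(y$feature_sets)) {
    missing <- setdiff(unlist(y$feature_sets), names(fs))
    if (length(missing)) stop("unknown feature set(s): ",
                              paste(missing, collapse = ", "))
    fs <- fs[unlist(y$feature_sets)]
  }
  pipeline_config(generator = gen, glcm = glcm, mapping = mapping,
                  white_point = white_point, split = split,
                  classifiers = classifiers, feature_sets = fs,
                  cv_folds = as.integer(y$cv_folds %||% 10L),
                  roi_method = y$roi_method %||% "full_frame", seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable hash of an arbitrary configuration object
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(config, digits = 15), tmp)
  unname(tools::md5sum(tmp))
}

subset_fm <- function(fm, idx) {
  feature_matrix(fm$x[idx, , drop = FALSE], fm$modality, fm$labels[idx])
}

write_confusion_heatmap <- function(confusion, path, title) {
  grDevices::png(path, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  k <- nrow(confusion)
  m <- confusion[k:1, , drop = FALSE]   # truth top-to-bottom
  graphics::par(mar = c(5, 6, 4, 2))
  graphics::image(seq_len(k), seq_len(k), t(m),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "Predicted", ylab = "True",
                  main = title)
  graphics::axis(1, at = seq_len(k), labels = colnames(m))
  graphics::axis(2, at = seq_len(k), labels = rownames(m), las = 2)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    graphics::text(j, i, m[i, j])
  }
}

#' Run the full feature-set x classifier experiment grid
#'
#' Builds (or loads) the dataset, extracts the three modality blocks,
#' draws the stratified calibration/prediction split once, and for every
#' feature set x classifier cell runs stratified 10-fold cross-validation
#' on the calibration set and a train/predict pass on the prediction set.
#' Writes `summary.csv` (feature-set x classifier grid of CV and
#' prediction accuracies), `report.json` (full metrics, confusion
#' matrices, per-class precision/recall, config hash and seeds),
#' per-cell confusion CSVs, optional heatmap PNGs and `run.log`. A failed
#' cell is logged and skipped; the remaining cells proceed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` for no file
#'   output.
#' @param heatmaps also render confusion-matrix heatmap PNGs.
#' @param dataset optional pre-extracted dataset (list with `blocks` and
#'   `labels`, as returned by [build_feature_dataset()] or
#'   [read_feature_table()]), bypassing generation/loading.
#' @return The report as a list (invisibly if `out_dir` is set): one entry
#'   per grid cell plus `summary` data frame, `config_hash` and `seed`.
#' @export
run_experiment <- function(config = pipeline_config(), out_dir = NULL,
                           heatmaps = FALSE, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%5.1fs] %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    sprintf(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  hash <- config_hash(config)
  say("config hash %s, seed %d", hash, config$seed)

  ds <- if (!is.null(dataset)) {
    say("using %d pre-extracted samples", length(dataset$labels))
    dataset
  } else if (is.character(config$generator)) {
    say("reading cubes from %s", config$generator)
    read_cube_dataset(config$generator, config$glcm, config$mapping,
                      config$white_point, config$roi_method)
  } else {
    say("generating synthetic dataset (%d samples, %dx%d)",
        sum(config$generator$n_per_class), config$generator$image_size[1],
        config$generator$image_size[2])
    build_feature_dataset(config$generator, config$glcm, config$mapping,
                          config$white_point, config$roi_method)
  }
  say("feature blocks ready: %s",
      paste(sprintf("%s(%d)", names(ds$blocks),
                    vapply(ds$blocks, function(b) ncol(b$x), integer(1))),
            collapse = ", "))

  n <- length(ds$labels)
  split <- config$split
  if (split$n_calibration + split$n_prediction != n) {
    # keep the configured prediction fraction if sizes don't match the data
    npred <- round(n * split$n_prediction /
                     (split$n_calibration + split$n_prediction))
    say("adjusting split to data size %d: calibration %d, prediction %d",
        n, n - npred, npred)
    split <- split_spec(n - npred, npred, split$stratified, split$seed)
  }
  idx <- make_split(ds$labels, split)

  cells <- list()
  summary_rows <- list()
  for (fs_name in names(config$feature_sets)) {
    mods <- config$feature_sets[[fs_name]]
    fm <- fuse(ds$blocks[mods])
    cal <- subset_fm(fm, idx$calibration)
    pred <- subset_fm(fm, idx$prediction)
    for (clf_name in names(config$classifiers)) {
      spec <- config$classifiers[[clf_name]]
      cell_id <- sprintf("%s | %s", fs_name, clf_name)
      res <- tryCatch({
        cv <- cross_validate(cal, spec, k = config$cv_folds,
                             seed = config$seed)
        tp <- train_predict(cal, pred, spec)
        per_class <- lapply(rownames(tp$confusion), function(cl) {
          confusion_metrics(tp$confusion, cl)
        })
        names(per_class) <- rownames(tp$confusion)
        say("%-40s cv %6.2f%%  pred %6.2f%%", cell_id,
            cv$mean_accuracy, tp$accuracy)
        list(feature_set = fs_name, classifier = clf_name,
             n_features = ncol(fm$x),
             cv_mean_accuracy = cv$mean_accuracy,
             cv_fold_accuracies = cv$fold_accuracies,
             prediction_accuracy = tp$accuracy,
             confusion = tp$confusion, per_class = per_class,
             seed = config$seed, classifier_config = unclass(spec))
      }, error = function(e) {
        say("%-40s FAILED: %s", cell_id, conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      cells[[cell_id]] <- res
      summary_rows[[cell_id]] <- data.frame(
        feature_set = fs_name, n_features = res$n_features,
        classifier = clf_name,
        cv_mean_accuracy = round(res$cv_mean_accuracy, 2),
        prediction_accuracy = round(res$prediction_accuracy, 2))
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  report <- list(cells = cells, summary = summary, config_hash = hash,
                 seed = config$seed,
                 split = list(n_calibration = split$n_calibration,
                              n_prediction = split$n_prediction))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      report[c("summary", "config_hash", "seed", "split")] |>
        c(list(cells = lapply(cells, function(cl) {
          cl$confusion <- as.data.frame(cl$confusion)
          cl
        }))),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
    for (cell_id in names(cells)) {
      stub <- gsub("[^A-Za-z0-9]+", "_", cell_id)
      utils::write.csv(as.data.frame(cells[[cell_id]]$confusion),
                       file.path(out_dir,
                                 sprintf("confusion_%s.csv", stub)))
      if (heatmaps) {
        write_confusion_heatmap(cells[[cell_id]]$confusion,
                                file.path(out_dir,
                                          sprintf("confusion_%s.png", stub)),
                                cell_id)
      }
    }
    writeLines(log_lines, file.path(out_dir, "run.log"))
    say("reports written to %s", out_dir)
    return(invisible(report))
  }
  report
}
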