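#' Pipeline configuration
#'
#' Collects every tunable parameter of the lesion pipeline in one list that
#' serializes to a single JSON document; missing keys take these defaults.
#'
#' @param c,m,tol,max_iter Fuzzy c-means parameters ([fcm_cluster()]).
#' @param alpha,bandwidth Type-II ambiguity scan ([ambiguity_threshold()]).
#' @param window Defuzzification window ([gradual_focus_defuzzify()]).
#' @param smoothing_scale Mask smoothing passes ([smooth_edges()]).
#' @param lesion Lesion cluster selection, `"darker"` or `"lighter"`.
#' @param sigma Canny Gaussian sigma ([canny_border()]).
#' @param low,high Hysteresis thresholds (`NULL` = percentile rule).
#' @param zernike_order Zernike order for the descriptor.
#' @param input_size,filters,dense_units,lr,epochs,batch_size CNN settings
#'   ([cnn_spec()]).
#' @param seed Master seed for every random component.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(c = 2, m = 2, tol = 1e-5, max_iter = 300,
                            alpha = 2, bandwidth = 127.5, window = 3,
                            smoothing_scale = 1, lesion = "darker",
                            sigma = 1.4, low = NULL, high = NULL,
                            zernike_order = 8,
                            input_size = 128, filters = c(16, 32, 64, 128, 256),
                            dense_units = 64, lr = 0.001, epochs = 1,
                            batch_size = 8, seed = 1) {
  structure(
    list(c = c, m = m, tol = tol, max_iter = max_iter, alpha = alpha,
         bandwidth = bandwidth, window = window,
         smoothing_scale = smoothing_scale, lesion = lesion, sigma = sigma,
         low = low, high = high, zernike_order = zernike_order,
         input_size = input_size, filters = filters,
         dense_units = dense_units, lr = lr, epochs = epochs,
         batch_size = batch_size, seed = seed),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` (for `write_config`).
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

# run segmentation + border + features for one grayscale image
process_lesion <- function(image, config) {
  mask <- extract_lesion_mask(
    image, c = config$c, m = config$m, tol = config$tol,
    max_iter = config$max_iter, alpha = config$alpha,
    bandwidth = config$bandwidth, window = config$window,
    smoothing_scale = config$smoothing_scale, lesion = config$lesion)
  trace <- canny_border(mask, sigma = config$sigma, low = config$low,
                        high = config$high)
  feats <- irregularity_vector(mask, trace, order = config$zernike_order)
  list(mask = mask, trace = trace, features = feats)
}

as_lesion_list <- function(x) {
  if (inherits(x, "synthetic_lesion")) x <- list(x)
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    labels <- NULL
    lab_path <- file.path(x, "labels.csv")
    if (file.exists(lab_path)) {
      labels <- readr::read_csv(lab_path, show_col_types = FALSE)
    }
    paths <- list.files(x, pattern = "\\.(png|tif|tiff)$", full.names = TRUE)
    paths <- paths[!grepl("_(mask|border)\\.", basename(paths))]
    return(purrr::map(paths, function(p) {
      id <- tools::file_path_sans_ext(basename(p))
      lab <- if (!is.null(labels) && id %in% labels$id) {
        labels$label[match(id, labels$id)]
      } else NA_integer_
      list(image = to_grayscale(read_image(p)), label = lab, id = id)
    }))
  }
  if (is.list(x)) {
    return(purrr::map(seq_along(x), function(i) {
      s <- x[[i]]
      list(image = to_grayscale(s$image), label = s$label %||% NA_integer_,
           id = s$id %||% sprintf("img%03d", i))
    }))
  }
  abort("expected a dataset directory, a synthetic_lesion, or a list of lesions")
}

#' Train the full border-irregularity pipeline
#'
#' Segments every training image, extracts its border and 27-value
#' descriptor, fits the Gaussian naive Bayes on the descriptors, and trains
#' the CNN on the (smoothed segmented image, border map) stacks with the
#' descriptor as auxiliary input. A training-batch decision threshold is also
#' stored so single images can be scored outside a test batch.
#'
#' @param x Training data: a dataset directory (images plus `labels.csv`) or a
#'   list of `synthetic_lesion` objects.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory to persist models into (see
#'   [save_models()]).
#' @return A `border_models` list: `gnb`, `cnn`, `features` (tibble),
#'   `threshold` (training-batch fallback), `config`.
#' @export
train_pipeline <- function(x, config = pipeline_config(), out_dir = NULL) {
  samples <- as_lesion_list(x)
  labs <- vapply(samples, function(s) as.integer(s$label), integer(1))
  if (anyNA(labs)) abort("training requires a label for every sample")
  arts <- purrr::map(samples, function(s) process_lesion(s$image, config))
  feat <- do.call(rbind, purrr::map(arts, "features"))
  gnb <- gnb_fit(feat, labs)
  spec <- cnn_spec(input_size = config$input_size, filters = config$filters,
                   dense_units = config$dense_units,
                   n_features = ncol(feat), lr = config$lr,
                   epochs = config$epochs, batch_size = config$batch_size,
                   seed = config$seed)
  images <- purrr::map(arts, function(a) a$mask * 255)
  borders <- purrr::map(arts, function(a) a$trace$edge_map)
  cnn <- cnn_train(images, borders, feat, labs, spec)
  scores <- ensemble_score(cnn_predict(cnn, images, borders, feat),
                           gnb_predict(gnb, feat))
  feat_tbl <- tibble::as_tibble(feat)
  feat_tbl$id <- vapply(samples, `[[`, character(1), "id")
  feat_tbl$label <- labs
  models <- structure(
    list(gnb = gnb, cnn = cnn,
         features = dplyr::relocate(feat_tbl, "id"),
         threshold = decision_threshold(scores), config = config),
    class = "border_models"
  )
  if (!is.null(out_dir)) save_models(models, out_dir)
  models
}

#' @export
print.border_models <- function(x, ...) {
  cat("<border_models>\n")
  print(x$gnb)
  print(x$cnn)
  cat(sprintf("stored decision threshold: %.4f\n", x$threshold))
  invisible(x)
}

#' Persist / restore trained pipeline models
#'
#' The Gaussian naive Bayes parameters, the stored decision threshold, and
#' the pipeline configuration are written as JSON; the CNN weights are stored
#' in an RDS checkpoint.
#'
#' @param models A [train_pipeline()] result.
#' @param dir Model directory.
#' @return `save_models()` the directory, `load_models()` a `border_models`.
#' @export
save_models <- function(models, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gnb <- models$gnb
  jsonlite::write_json(
    list(priors = as.list(gnb$priors),
         mean = unname(gnb$mean),
         var = unname(gnb$var),
         features = gnb$features, n = gnb$n,
         threshold = models$threshold),
    file.path(dir, "gnb.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(models$cnn, file.path(dir, "cnn.rds"))
  write_config(models$config, file.path(dir, "config.json"))
  readr::write_csv(models$features, file.path(dir, "features.csv"))
  invisible(dir)
}

#' @rdname save_models
#' @export
load_models <- function(dir) {
  raw <- jsonlite::read_json(file.path(dir, "gnb.json"), simplifyVector = TRUE)
  gnb <- structure(
    list(priors = unlist(raw$priors),
         mean = as.matrix(raw$mean),
         var = as.matrix(raw$var),
         features = raw$features, n = raw$n),
    class = "gnb_model")
  rownames(gnb$mean) <- rownames(gnb$var) <- c("irregular", "regular")
  structure(
    list(gnb = gnb, cnn = readRDS(file.path(dir, "cnn.rds")),
         features = readr::read_csv(file.path(dir, "features.csv"),
                                    show_col_types = FALSE),
         threshold = raw$threshold,
         config = read_config(file.path(dir, "config.json"))),
    class = "border_models")
}

#' Run the border-irregularity pipeline on a batch of images
#'
#' For each image: grayscale conversion, lesion segmentation, border
#' detection, the 27-value descriptor, CNN and Gaussian naive Bayes
#' probabilities, and the fused ensemble score. The decision threshold is the
#' adaptive batch rule `(max(P) + mean(P))/2` (for a single image the stored
#' training-time threshold is used instead), and each score is then called
#' regular or irregular.
#'
#' Per-image failures (e.g., no lesion found) are logged as warnings and the
#' affected images are skipped; the run aborts only if every image fails.
#'
#' @param x A dataset directory, a `synthetic_lesion`, or a list of lesions.
#' @param models A [train_pipeline()] result (or [load_models()] output).
#' @param config Optional override of `models$config`.
#' @param out_dir Optional directory for artifacts: per-image mask and border
#'   PNGs, `features.csv`, `predictions.csv`.
#' @return A tibble with one row per processed image: `id`, `label`, `FD`,
#'   `C`, `cnn_p_irregular`, `gnb_p_irregular`, `score`, `threshold`,
#'   `decision`.
#' @export
run_pipeline <- function(x, models, config = NULL, out_dir = NULL) {
  config <- config %||% models$config
  samples <- as_lesion_list(x)
  arts <- purrr::map(samples, function(s) {
    tryCatch(process_lesion(s$image, config),
             error = function(e) {
               warn(sprintf("skipping %s: %s", s$id, conditionMessage(e)))
               NULL
             })
  })
  ok <- !vapply(arts, is.null, logical(1))
  if (!any(ok)) abort("pipeline failed on every input image")
  samples <- samples[ok]
  arts <- arts[ok]
  feat <- do.call(rbind, purrr::map(arts, "features"))
  images <- purrr::map(arts, function(a) a$mask * 255)
  borders <- purrr::map(arts, function(a) a$trace$edge_map)
  cnn_p <- cnn_predict(models$cnn, images, borders, feat)
  gnb_p <- gnb_predict(models$gnb, feat)
  scores <- ensemble_score(cnn_p, gnb_p)
  thr <- if (length(scores) > 1L) decision_threshold(scores) else models$threshold
  res <- tibble::tibble(
    id = vapply(samples, `[[`, character(1), "id"),
    label = vapply(samples, function(s) as.integer(s$label), integer(1)),
    FD = feat[, "FD"],
    C = feat[, "C"],
    cnn_p_irregular = cnn_p$p_irregular,
    gnb_p_irregular = gnb_p$p_irregular,
    score = scores,
    threshold = thr,
    decision = decide(scores, thr)
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    purrr::walk2(samples, arts, function(s, a) {
      write_image_png(a$mask * 255L, file.path(out_dir, paste0(s$id, "_mask.png")))
      write_image_png(a$trace$edge_map * 255L,
                      file.path(out_dir, paste0(s$id, "_border.png")))
    })
    feat_tbl <- tibble::as_tibble(feat)
    feat_tbl$id <- res$id
    feat_tbl$label <- res$label
    readr::write_csv(dplyr::relocate(feat_tbl, "id"),
                     file.path(out_dir, "features.csv"))
    readr::write_csv(res, file.path(out_dir, "predictions.csv"))
  }
  res
}
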