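#' Pipeline configuration
#'
#' Bundles the embedding training configuration, the LOF parameters and the
#' backbone choice for the two-stage detector.
#'
#' @param train_config a [train_config()].
#' @param lof_params a [lof_params()].
#' @param backbone a [backbone_spec()].
#' @param seed top-level seed; overrides `train_config$seed` so one seed
#'   drives the whole run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(train_config = octanomaly::train_config(),
                            lof_params = octanomaly::lof_params(),
                            backbone = backbone_spec(), seed = NULL) {
  if (!is.null(seed)) train_config$seed <- as.integer(seed)
  structure(list(train_config = train_config, lof_params = lof_params,
                 backbone = backbone, seed = train_config$seed),
            class = "pipeline_config")
}

#' Fit the two-stage AMD detector
#'
#' Stage 1 trains the embedding network on all training images (both
#' classes). Stage 2 extracts alpha-sphere features from the *normal*
#' images of the embedding's 80% training portion only, which become the
#' LOF reference population. The decision threshold is then calibrated
#' (unless a fixed threshold was configured) as the configured quantile of
#' the novelty-mode LOF scores of the *validation-portion* normals against
#' that reference -- held-out normals give an unbiased picture of where
#' fresh normal scans score; when fewer than five are available the
#' leave-self-out fit-mode quantile of the reference itself is used
#' instead. The class asymmetry is deliberate: the classifier head sees
#' both classes during training, but test images are judged solely by how
#' much they stand out from the normal population.
#'
#' @param train_images an `oct_imageset` containing both classes.
#' @param config a [pipeline_config()].
#' @return an `oct_pipeline`: `model`, `reference` (normal-feature matrix),
#'   `threshold`, `lof_params`, `config`.
#' @export
oct_fit <- function(train_images, config = pipeline_config()) {
  labs <- map_chr(train_images$images, "binary_label")
  if (!any(labs == "NORMAL")) {
    abort("no NORMAL training images: the LOF reference set would be empty")
  }
  if (!any(labs == "AMD")) {
    abort("training requires both classes (AMD and NORMAL) present")
  }
  tc <- config$train_config
  model <- train_embedding(train_images, tc, config$backbone)
  # same seeded stratified split as train_embedding
  y <- binary_labels_of(train_images)
  tr <- stratified_split(y, tc$train_frac, derive_seed(tc$seed, 2L))
  subset_imageset <- function(idx) structure(
    list(images = train_images$images[idx],
         manifest = train_images$manifest[idx, ]),
    class = "oct_imageset")
  ref_idx <- intersect(tr, which(labs == "NORMAL"))
  cal_idx <- setdiff(which(labs == "NORMAL"), tr)
  reference <- extract_features(model, subset_imageset(ref_idx))
  lp <- config$lof_params
  if (lp$k >= nrow(reference)) {
    abort(sprintf(
      "LOF k = %d requires more than k normal training images (have %d)",
      lp$k, nrow(reference)))
  }
  tau <- if (identical(lp$threshold, "auto")) {
    if (length(cal_idx) >= 5) {
      cal <- extract_features(model, subset_imageset(cal_idx))
      lp_fixed <- lp; lp_fixed$threshold <- 1  # decisions unused here
      sc <- score_queries(cal, reference, lp_fixed)$lof_score
      unname(stats::quantile(sc[is.finite(sc)], lp$quantile))
    } else {
      calibrate_threshold(reference, lp$k, lp$quantile, lp$metric)
    }
  } else lp$threshold
  structure(list(model = model, reference = reference, threshold = tau,
                 lof_params = lp, config = config),
            class = "oct_pipeline")
}

#' @export
print.oct_pipeline <- function(x, ...) {
  cat(sprintf("<oct_pipeline> %s embedding (alpha = %g) + LOF (k = %d, tau = %.3f)\n",
              x$model$backbone, x$model$alpha, x$lof_params$k, x$threshold))
  cat(sprintf("  reference set: %d normal features of dimension %d\n",
              nrow(x$reference), ncol(x$reference)))
  invisible(x)
}

#' Score and classify test images
#'
#' Each test image is embedded and scored in novelty mode against the
#' normal reference set; the decision is `AMD` when its LOF score exceeds
#' the calibrated threshold. Output rows follow the input order.
#'
#' @param object an `oct_pipeline`.
#' @param newdata an `oct_imageset` (may be empty).
#' @param ... unused.
#' @return tibble with `id`, `lof_score`, `decision` (and `label`,
#'   `binary_label` columns when the input manifest carries them).
#' @export
predict.oct_pipeline <- function(object, newdata, ...) {
  n <- length(newdata$images)
  if (n == 0) {
    return(tibble(id = character(), lof_score = numeric(),
                  decision = character()))
  }
  feats <- extract_features(object$model, newdata)
  lp <- object$lof_params
  lp$threshold <- object$threshold
  scored <- score_queries(feats, object$reference, lp)
  out <- tibble(id = newdata$manifest$id, lof_score = scored$lof_score,
                decision = scored$decision)
  for (col in c("label", "binary_label")) {
    if (col %in% names(newdata$manifest)) out[[col]] <- newdata$manifest[[col]]
  }
  out
}

#' Evaluate the detector on a labeled test set
#'
#' Predicts every test image, then builds the full metrics report with AMD
#' as the positive class and the LOF score as the ROC ranking score. When
#' the test set contains a single class, metrics whose denominators vanish
#' (weighted averages, AUC) are reported as absent rather than fabricated.
#'
#' @param pipeline an `oct_pipeline`.
#' @param test_images a labeled `oct_imageset`.
#' @return a `metrics_report` with the prediction tibble attached as
#'   `$predictions`.
#' @export
oct_evaluate <- function(pipeline, test_images) {
  preds <- predict(pipeline, test_images)
  if (!"binary_label" %in% names(preds)) {
    abort("test images carry no labels; cannot evaluate")
  }
  rep <- metrics_report(preds$binary_label, preds$decision,
                        scores = preds$lof_score)
  rep$predictions <- preds
  rep
}

#' Glance at a fitted pipeline
#'
#' @param x an `oct_pipeline`.
#' @param ... unused.
#' @return one-row tibble: backbone, alpha, feature dim, reference size, k,
#'   threshold, final validation accuracy.
#' @method glance oct_pipeline
#' @export
glance.oct_pipeline <- function(x, ...) {
  h <- x$model$history
  tibble(backbone = x$model$backbone, alpha = x$model$alpha,
         feature_dim = x$model$feature_dim,
         n_reference = nrow(x$reference), k = x$lof_params$k,
         threshold = x$threshold,
         val_acc = if (nrow(h) > 0) h$val_acc[nrow(h)] else NA_real_)
}

#' Save / load a fitted pipeline
#'
#' Writes the embedding checkpoint, the reference features as CSV, and a
#' JSON with the threshold and configuration into `dir`.
#'
#' @param pipeline an `oct_pipeline`.
#' @param dir run directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_pipeline <- function(pipeline, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_embedding(pipeline$model, file.path(dir, "model"))
  write_features_csv(pipeline$reference,
                     sprintf("ref_%d", seq_len(nrow(pipeline$reference))),
                     file.path(dir, "reference_features.csv"))
  jsonlite::write_json(
    list(threshold = pipeline$threshold,
         lof_params = unclass(pipeline$lof_params),
         seed = pipeline$config$seed),
    file.path(dir, "run.json"), auto_unbox = TRUE, pretty = TRUE)
  saveRDS(pipeline, file.path(dir, "pipeline.rds"))
  invisible(dir)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(dir) {
  readRDS(file.path(dir, "pipeline.rds"))
}
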