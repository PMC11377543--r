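# Segmentation metrics (pixel confusion ratios, Dice, IoU, weighted IoU)
# and the k-fold cross-validation harness that reports fold-wise values and
# mean +/- population standard deviation.

#' Pixelwise confusion counts
#'
#' Polyp (1) is the positive class.
#'
#' @param predicted,truth binary masks of identical shape.
#' @return named list `TP`, `TN`, `FP`, `FN` (pixel counts).
#' @export
confusion_counts <- function(predicted, truth) {
  if (!all(dim(predicted) == dim(truth))) stop_data("mask shape mismatch")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop_data("masks must be binary")
  list(TP = sum(predicted == 1 & truth == 1),
       TN = sum(predicted == 0 & truth == 0),
       FP = sum(predicted == 1 & truth == 0),
       FN = sum(predicted == 0 & truth == 1))
}

safe_ratio <- function(num, den) if (den == 0) 1 else num / den

#' Accuracy, sensitivity, specificity and precision from confusion counts
#'
#' A ratio whose denominator is zero (e.g. sensitivity on a polyp-free
#' image with no false positives) is vacuously perfect: it returns 1 and the
#' metric name is recorded in the `vacuous` attribute.  This keeps fold
#' averages well defined on polyp-free frames.
#'
#' @param counts a [confusion_counts()] result.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, each in `[0,1]`, with attribute `vacuous`.
#' @export
pixel_metrics <- function(counts) {
  with(counts, {
    vac <- character(0)
    if (TP + FN == 0) vac <- c(vac, "sensitivity")
    if (TN + FP == 0) vac <- c(vac, "specificity")
    if (TP + FP == 0) vac <- c(vac, "precision")
    structure(c(accuracy = (TP + TN) / (TP + TN + FP + FN),
                sensitivity = safe_ratio(TP, TP + FN),
                specificity = safe_ratio(TN, TN + FP),
                precision = safe_ratio(TP, TP + FP)),
              vacuous = vac)
  })
}

#' Dice, IoU and weighted IoU between two masks
#'
#' `Dice = 2|M n G| / (|M| + |G|)`, `IoU = |M n G| / |M u G|` for the polyp
#' label; weighted IoU averages the per-label IoU (background and polyp)
#' weighted by the ground-truth pixel count of each label.  Empty-vs-empty
#' overlap is defined as 1.
#'
#' @param predicted,truth binary masks of identical shape.
#' @return named numeric vector `dice`, `iou`, `weighted_iou`.
#' @export
overlap_metrics <- function(predicted, truth) {
  if (!all(dim(predicted) == dim(truth))) stop_data("mask shape mismatch")
  inter <- sum(predicted == 1 & truth == 1)
  m <- sum(predicted == 1); g <- sum(truth == 1)
  dice <- if (m + g == 0) 1 else 2 * inter / (m + g)
  union_ <- m + g - inter
  iou_pos <- if (union_ == 0) 1 else inter / union_
  inter0 <- sum(predicted == 0 & truth == 0)
  union0 <- length(truth) - inter
  iou_neg <- if (union0 == 0) 1 else inter0 / union0
  w_pos <- g / length(truth)
  c(dice = dice, iou = iou_pos,
    weighted_iou = w_pos * iou_pos + (1 - w_pos) * iou_neg)
}

#' Per-image metric record
#'
#' @param predicted,truth binary masks.
#' @return named numeric vector with the six reported metrics, Table-style
#'   column order.
#' @export
metrics_record <- function(predicted, truth) {
  pm <- pixel_metrics(confusion_counts(predicted, truth))
  om <- overlap_metrics(predicted, truth)
  c(accuracy = pm[["accuracy"]], sensitivity = pm[["sensitivity"]],
    specificity = pm[["specificity"]], precision = pm[["precision"]],
    weighted_iou = om[["weighted_iou"]], dice = om[["dice"]])
}

#' Mean and population standard deviation of fold-wise values
#'
#' @param values numeric vector (one value per fold).
#' @return named vector `mean`, `sd` (population sd, dividing by k).
#' @export
summarise_folds <- function(values) {
  m <- mean(values)
  c(mean = m, sd = sqrt(mean((values - m)^2)))
}

#' k-fold cross-validated evaluation
#'
#' Splits the dataset into k balanced folds; for each fold, `model_builder`
#' is fitted on the remaining folds and evaluated on the held-out fold.
#' Per-image metrics are averaged within each fold (image-averaged
#' convention), then summarised as mean +/- population sd across folds.
#'
#' @param model_builder `function(train_data, config)` returning either a
#'   `polypvit_model` (used with [predict_mask()]) or a `function(image)`
#'   returning a binary mask.
#' @param dataset list of [labeled_image()] (>= k items).
#' @param k fold count (>= 2).
#' @param config passed through to `model_builder`.
#' @param seed fold-assignment seed.
#' @return object of class `crossval_result`: list with `folds`
#'   (data.frame, one row per fold), `summary` (data.frame with mean and sd
#'   rows), `assignments`.
#' @export
crossval_evaluate <- function(model_builder, dataset, k = 5L, config = NULL,
                              seed = 1L) {
  assert_that(k >= 2, "k must be >= 2")
  if (length(dataset) < k)
    stop_data("dataset (%d items) smaller than k = %d", length(dataset), k)
  splits <- make_splits(length(dataset), k = k, seed = seed)
  fold_rows <- NULL
  for (f in seq_len(k)) {
    test_idx <- splits$folds[[f]]
    train_idx <- setdiff(seq_along(dataset), test_idx)
    fitted <- model_builder(dataset[train_idx], config)
    predict_fun <- if (inherits(fitted, "polypvit_model"))
      function(img) predict_mask(fitted, img) else fitted
    per_image <- vapply(dataset[test_idx], function(item) {
      metrics_record(predict_fun(item$image), item$mask)
    }, numeric(6))
    fold_rows <- rbind(fold_rows, rowMeans(per_image))
  }
  folds_df <- data.frame(fold = seq_len(k), fold_rows, row.names = NULL)
  sums <- apply(fold_rows, 2, summarise_folds)
  summary_df <- data.frame(statistic = c("mean", "sd"), sums, row.names = NULL)
  structure(list(folds = folds_df, summary = summary_df,
                 assignments = splits$folds),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("k-fold cross-validation (mean +/- population sd):\n")
  s <- x$summary
  for (col in setdiff(names(s), "statistic"))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", col, s[[col]][1], s[[col]][2]))
  invisible(x)
}

#' Write a metrics report as CSV and JSON
#'
#' One row per fold plus a mean and an sd row; columns in the order
#' accuracy, sensitivity, specificity, precision, weighted_iou, dice.
#'
#' @param result a [crossval_evaluate()] result.
#' @param path_csv,path_json output paths (skipped when `NULL`).
#' @return invisibly, the combined data.frame.
#' @export
write_metrics_report <- function(result, path_csv = NULL, path_json = NULL) {
  folds <- result$folds
  folds$statistic <- paste0("fold", folds$fold)
  s <- result$summary
  cols <- c("accuracy", "sensitivity", "specificity", "precision",
            "weighted_iou", "dice")
  combined <- rbind(folds[, c("statistic", cols)], s[, c("statistic", cols)])
  if (!is.null(path_csv)) write.csv(combined, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(combined, path_json, dataframe = "rows", digits = NA)
  invisible(combined)
}
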