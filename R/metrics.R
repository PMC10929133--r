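#' Pixelwise confusion counts between two binary masks
#'
#' @param pred,truth Logical (or 0/1) matrices of the same shape.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`; the four
#'   counts sum to the number of evaluated pixels.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    rlang::abort("`pred` and `truth` must have identical dimensions.")
  }
  p <- as.logical(pred)
  t <- as.logical(truth)
  tibble::tibble(
    tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t)
  )
}

metric_counts <- function(c) {
  if (is.data.frame(c) || is.list(c)) {
    need <- c("tp", "fp", "fn", "tn")
    if (!all(need %in% names(c))) {
      rlang::abort("Counts must provide tp, fp, fn, tn.")
    }
    lapply(c[need], as.numeric)
  } else {
    rlang::abort("Counts must be a data frame or named list with tp, fp, fn, tn.")
  }
}

# Zero-denominator metrics return NA_real_ (the explicit "undefined" marker)
# rather than NaN, so they can be excluded from macro averages deliberately.
safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Segmentation evaluation metrics from confusion counts
#'
#' The five standard metrics: `f1_score` = 2TP / (2TP + FP + FN) (Dice),
#' `iou` = TP / (TP + FP + FN) (Jaccard), `pixel_accuracy` =
#' (TP + TN) / total, `sensitivity` = TP / (TP + FN) (recall),
#' `specificity` = TN / (TN + FP). For any single confusion matrix the
#' identity `f1 = 2 * iou / (1 + iou)` holds. A zero denominator yields the
#' explicit undefined marker `NA` (never `NaN`).
#'
#' @param c Confusion counts: a tibble/list with `tp`, `fp`, `fn`, `tn`
#'   (vectorized over rows).
#' @return Numeric vector of metric values in `[0, 1]` (or `NA`).
#' @examples
#' f1_score(list(tp = 1, fp = 1, fn = 1, tn = 0)) # 0.5
#' @export
f1_score <- function(c) {
  cc <- metric_counts(c)
  safe_ratio(2 * cc$tp, 2 * cc$tp + cc$fp + cc$fn)
}

#' @rdname f1_score
#' @export
iou <- function(c) {
  cc <- metric_counts(c)
  safe_ratio(cc$tp, cc$tp + cc$fp + cc$fn)
}

#' @rdname f1_score
#' @export
pixel_accuracy <- function(c) {
  cc <- metric_counts(c)
  safe_ratio(cc$tp + cc$tn, cc$tp + cc$fp + cc$fn + cc$tn)
}

#' @rdname f1_score
#' @export
sensitivity <- function(c) {
  cc <- metric_counts(c)
  safe_ratio(cc$tp, cc$tp + cc$fn)
}

#' @rdname f1_score
#' @export
specificity <- function(c) {
  cc <- metric_counts(c)
  safe_ratio(cc$tn, cc$tn + cc$fp)
}

#' @rdname f1_score
#' @export
precision <- function(c) {
  cc <- metric_counts(c)
  safe_ratio(cc$tp, cc$tp + cc$fp)
}

#' F1 score as the harmonic mean of precision and recall
#'
#' @param precision,recall Numeric vectors in `[0, 1]`, not both zero.
#' @return `2 * precision * recall / (precision + recall)`.
#' @examples
#' f1_from_precision_recall(0.7651, 0.6196) # 0.6847
#' @export
f1_from_precision_recall <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1, na.rm = TRUE)) {
    rlang::abort("`precision` and `recall` must lie in [0, 1].")
  }
  if (any(precision + recall == 0, na.rm = TRUE)) {
    rlang::abort("F1 is undefined when precision and recall are both zero.")
  }
  2 * precision * recall / (precision + recall)
}

#' Per-pixel multi-label binary cross-entropy loss
#'
#' Reference implementation of the multi-label segmentation loss: the mean
#' over every (pixel, class) cell of
#' `-(y * log(p) + (1 - y) * log(1 - p))`, with probabilities clamped to
#' `[eps, 1 - eps]`. Because each class has its own independent (sigmoid)
#' probability, a pixel may belong to several classes at once — the property
#' needed for overlapping tooth-position masks.
#'
#' @param pred Numeric array of predicted probabilities in `[0, 1]`, any
#'   shape (typically `H x W x C`).
#' @param labels Binary array of the same shape.
#' @param eps Clamp bound, default `1e-7`.
#' @return Non-negative scalar loss; 0 only at (clamped) perfect prediction.
#' @examples
#' multilabel_loss(array(0.5, c(2, 2, 3)), array(1, c(2, 2, 3))) # log(2)
#' @export
multilabel_loss <- function(pred, labels, eps = 1e-7) {
  if (!identical(dim(pred) %||% length(pred), dim(labels) %||% length(labels))) {
    rlang::abort("`pred` and `labels` must have identical shape.")
  }
  if (any(pred < 0 | pred > 1)) rlang::abort("`pred` must lie in [0, 1].")
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) rlang::abort("`labels` must be binary.")
  p <- pmin(pmax(as.numeric(pred), eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Per-pixel softmax cross-entropy loss
#'
#' Reference implementation of the single-label segmentation loss: logits are
#' turned into class probabilities with a per-pixel softmax (exponentiate,
#' then normalize across classes so each pixel's probabilities sum to 1), and
#' the loss is the mean over pixels of the negative log probability of the
#' true class. Computed via log-sum-exp for numerical stability.
#'
#' @param logits Numeric `H x W x C` array of unnormalized scores, `C >= 2`.
#' @param labels Binary `H x W x C` array with exactly one 1 per pixel.
#' @return Non-negative scalar loss.
#' @examples
#' cross_entropy_loss(array(0, c(2, 2, 4)),
#'                    array(rep(c(1, 0, 0, 0), each = 4), c(2, 2, 4))) # log(4)
#' @export
cross_entropy_loss <- function(logits, labels) {
  if (length(dim(logits)) != 3L || !identical(dim(logits), dim(labels))) {
    rlang::abort("`logits` and `labels` must be H x W x C arrays of identical shape.")
  }
  d <- dim(logits)
  if (d[3] < 2L) rlang::abort("Need at least 2 classes.")
  L <- matrix(logits, nrow = d[1] * d[2], ncol = d[3])
  Y <- matrix(labels, nrow = d[1] * d[2], ncol = d[3])
  if (!all(Y %in% c(0, 1))) rlang::abort("`labels` must be binary.")
  ones <- rowSums(Y)
  if (any(ones != 1)) {
    rlang::abort(sprintf(
      "Single-label mode requires exactly one set class per pixel; %d pixel(s) violate this.",
      sum(ones != 1)))
  }
  rowmax <- apply(L, 1, max)
  lse <- rowmax + log(rowSums(exp(L - rowmax)))
  mean(lse - rowSums(Y * L))
}

#' Per-class segmentation report over paired predictions and truths
#'
#' Pools confusion counts per class across all image pairs (micro within
#' class), computes per-class IoU and F1, then appends two summary rows:
#' `macro` — the unweighted mean of the per-class metrics over classes that
#' are defined — and `micro` — metrics of the counts pooled over classes as
#' well. A class absent from every prediction and truth has no defined
#' metric; it is reported as `NA` and excluded from the macro mean with a
#' message.
#'
#' Pairs may be [region_map()]s (classes: intrabony, suprabony, crown,
#' one-vs-rest on the label value) or [tooth_position_stack()]s (classes:
#' tooth positions 1-32, each mask evaluated as a binary task).
#'
#' @param preds,truths Lists (of equal length) of region maps or position
#'   stacks.
#' @return A tibble: `class`, `tp`, `fp`, `fn`, `tn`, `iou`, `f1`.
#' @export
segmentation_report <- function(preds, truths) {
  if (length(preds) == 0L || length(preds) != length(truths)) {
    rlang::abort("`preds` and `truths` must be non-empty lists of equal length.")
  }
  pair_counts <- function(pred, truth) {
    if (inherits(pred, "region_map")) {
      if (!inherits(truth, "region_map")) rlang::abort("Mismatched pair types.")
      classes <- c(intrabony = 1L, suprabony = 2L, crown = 3L)
      purrr::imap_dfr(classes, function(lab, nm) {
        dplyr::mutate(confusion_counts(unclass(pred) == lab, unclass(truth) == lab),
                      class = nm, .before = 1)
      })
    } else if (inherits(pred, "tooth_position_stack")) {
      if (!inherits(truth, "tooth_position_stack")) rlang::abort("Mismatched pair types.")
      teeth <- sort(union(stack_teeth(pred), stack_teeth(truth)))
      empty <- matrix(FALSE, truth$height, truth$width)
      purrr::map_dfr(teeth, function(t) {
        key <- as.character(t)
        dplyr::mutate(
          confusion_counts(pred$masks[[key]] %||% empty, truth$masks[[key]] %||% empty),
          class = sprintf("tooth_%02d", t), .before = 1)
      })
    } else {
      rlang::abort("Pairs must be region maps or tooth position stacks.")
    }
  }
  counts <- purrr::map2_dfr(preds, truths, pair_counts) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(c("tp", "fp", "fn", "tn"), sum), .groups = "drop")
  per_class <- dplyr::mutate(counts, iou = iou(counts), f1 = f1_score(counts))
  undefined <- per_class$class[is.na(per_class$iou)]
  if (length(undefined) > 0L) {
    message("Class(es) with no positives anywhere excluded from the macro mean: ",
            paste(undefined, collapse = ", "))
  }
  pooled <- dplyr::summarise(counts, dplyr::across(c("tp", "fp", "fn", "tn"), sum))
  summary_rows <- tibble::tibble(
    class = c("macro", "micro"),
    tp = c(NA_real_, pooled$tp), fp = c(NA_real_, pooled$fp),
    fn = c(NA_real_, pooled$fn), tn = c(NA_real_, pooled$tn),
    iou = c(mean(per_class$iou, na.rm = TRUE), iou(pooled)),
    f1 = c(mean(per_class$f1, na.rm = TRUE), f1_score(pooled))
  )
  dplyr::bind_rows(per_class, summary_rows)
}

#' Per-stage staging report (one-vs-rest over teeth)
#'
#' Compares predicted against reference bone-loss stages tooth by tooth.
#' Each stage is scored one-vs-rest: precision, sensitivity, F1, specificity
#' and support (number of reference teeth in that stage). A final `macro`
#' row holds the unweighted means of the per-stage values (undefined values
#' excluded with a message) and the total support.
#'
#' @param pred_stages,ref_stages Vectors (character or factor) of stages
#'   `I`/`II`/`III`, equal length, one entry per tooth or dentition.
#' @param method_label Label naming the reference method (e.g. the landmark
#'   formula the reference stages came from).
#' @return A tibble of class `stage_report`: `method`, `stage`, `precision`,
#'   `sensitivity`, `f1`, `specificity`, `support`.
#' @export
stage_report <- function(pred_stages, ref_stages, method_label = "reference") {
  pred <- as.character(pred_stages)
  ref <- as.character(ref_stages)
  if (length(pred) != length(ref)) {
    rlang::abort("`pred_stages` and `ref_stages` must have equal length.")
  }
  if (length(pred) == 0L) rlang::abort("Stage lists must be non-empty.")
  stages <- c("I", "II", "III")
  bad <- setdiff(unique(c(pred, ref)), stages)
  if (length(bad) > 0L) {
    rlang::abort(paste0("Unknown stage value(s): ", paste(bad, collapse = ", "), "."))
  }
  rows <- purrr::map_dfr(stages, function(s) {
    cc <- tibble::tibble(
      tp = sum(pred == s & ref == s), fp = sum(pred == s & ref != s),
      fn = sum(pred != s & ref == s), tn = sum(pred != s & ref != s)
    )
    tibble::tibble(
      method = method_label, stage = s,
      precision = precision(cc), sensitivity = sensitivity(cc),
      f1 = f1_score(cc), specificity = specificity(cc),
      support = sum(ref == s)
    )
  })
  nas <- vapply(rows[c("precision", "sensitivity", "f1", "specificity")],
                function(x) any(is.na(x)), logical(1))
  if (any(nas)) {
    message("Undefined per-stage value(s) excluded from the macro mean: ",
            paste(names(nas)[nas], collapse = ", "))
  }
  macro <- tibble::tibble(
    method = method_label, stage = "macro",
    precision = mean(rows$precision, na.rm = TRUE),
    sensitivity = mean(rows$sensitivity, na.rm = TRUE),
    f1 = mean(rows$f1, na.rm = TRUE),
    specificity = mean(rows$specificity, na.rm = TRUE),
    support = length(ref)
  )
  out <- dplyr::bind_rows(rows, macro)
  class(out) <- c("stage_report", class(out))
  out
}

#' Write a report tibble as CSV or an aligned text table
#'
#' @param report A tibble (e.g. from [segmentation_report()] or
#'   [stage_report()]).
#' @param path Output path.
#' @param format `"csv"` or `"text"` (fixed-width columns).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "text")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(as.data.frame(report), path)
  } else {
    df <- as.data.frame(report)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) ifelse(is.na(x), "-", sprintf("%.4f", x)))
    widths <- pmax(nchar(names(df)), vapply(df, function(x) max(nchar(as.character(x)), 0L), integer(1)))
    fmt_row <- function(cells) paste(mapply(formatC, as.character(cells), width = widths), collapse = "  ")
    writeLines(c(fmt_row(names(df)), apply(df, 1, fmt_row)), path)
  }
  invisible(path)
}
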