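test_that("confusion counts match an exhaustive per-pixel loop oracle", {
  all1 <- matrix(TRUE, 4, 4)
  cc <- confusion_counts(all1, all1)
  expect_equal(unlist(cc), c(tp = 16, fp = 0, fn = 0, tn = 0))

  cc2 <- confusion_counts(matrix(TRUE, 3, 3), matrix(FALSE, 3, 3))
  expect_equal(cc2$fp, 9)
  expect_equal(cc2$tp + cc2$fn + cc2$tn, 0)

  set.seed(29)
  p <- matrix(runif(64) > 0.5, 8, 8)
  t <- matrix(runif(64) > 0.5, 8, 8)
  cc3 <- confusion_counts(p, t)
  tp <- fp <- fn <- tn <- 0
  for (i in 1:8) for (j in 1:8) {
    if (p[i, j] && t[i, j]) tp <- tp + 1
    else if (p[i, j]) fp <- fp + 1
    else if (t[i, j]) fn <- fn + 1
    else tn <- tn + 1
  }
  expect_equal(unlist(cc3), c(tp = tp, fp = fp, fn = fn, tn = tn))
  expect_equal(sum(unlist(cc3)), 64)
  expect_error(confusion_counts(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "dimensions")
})

test_that("the five metrics follow their formulas and the F1/IoU identity", {
  c1 <- list(tp = 1, fp = 1, fn = 1, tn = 0)
  expect_equal(f1_score(c1), 0.5)
  expect_equal(iou(c1), 1 / 3)

  perfect <- list(tp = 10, fp = 0, fn = 0, tn = 5)
  expect_equal(f1_score(perfect), 1)
  expect_equal(iou(perfect), 1)
  expect_equal(pixel_accuracy(perfect), 1)
  expect_equal(sensitivity(perfect), 1)
  expect_equal(specificity(perfect), 1)

  # undefined markers, never NaN
  none <- list(tp = 0, fp = 0, fn = 0, tn = 4)
  expect_true(is.na(f1_score(none)) && !is.nan(f1_score(none)))
  expect_true(is.na(sensitivity(none)))
  expect_equal(specificity(none), 1)

  # F1 = 2 IoU / (1 + IoU) across random confusion counts
  set.seed(31)
  counts <- tibble::tibble(
    tp = sample(0:500, 200, TRUE), fp = sample(0:500, 200, TRUE),
    fn = sample(0:500, 200, TRUE), tn = sample(0:500, 200, TRUE)
  )
  f1 <- f1_score(counts)
  jac <- iou(counts)
  ok <- !is.na(f1)
  expect_true(any(ok))
  expect_equal(f1[ok], 2 * jac[ok] / (1 + jac[ok]), tolerance = 1e-12)
  expect_true(all(jac[ok] <= f1[ok] + 1e-12))
  expect_true(all(f1[ok] <= 1))
})

test_that("harmonic-mean F1 reproduces precision/recall pairs", {
  expect_equal(round(f1_from_precision_recall(0.7651, 0.6196), 4), 0.6847)
  expect_lt(abs(f1_from_precision_recall(0.8149, 0.7752) - 0.7945), 1e-4)
  x <- c(0.3, 0.72, 0.9999)
  expect_equal(f1_from_precision_recall(x, x), x)
  expect_error(f1_from_precision_recall(0, 0), "undefined")
  expect_error(f1_from_precision_recall(1.2, 0.5), "0, 1")
})

test_that("multi-label loss matches analytic values and an independent oracle", {
  labels <- array(rep(c(1, 0), each = 6), c(3, 2, 2))
  expect_equal(multilabel_loss(array(0.5, c(3, 2, 2)), labels), log(2), tolerance = 1e-12)

  expect_lte(multilabel_loss(labels, labels), 2e-7)

  # single pixel, two classes, y = (1, 0), p = (0.8, 0.3)
  y <- array(c(1, 0), c(1, 1, 2))
  p <- array(c(0.8, 0.3), c(1, 1, 2))
  expect_equal(multilabel_loss(p, y), -(log(0.8) + log(0.7)) / 2, tolerance = 1e-4)

  # element-wise loop oracle on a random instance
  set.seed(37)
  pr <- array(runif(24), c(2, 3, 4))
  yr <- array(rbinom(24, 1, 0.4), c(2, 3, 4))
  acc <- 0
  for (i in 1:2) for (j in 1:3) for (k in 1:4) {
    pc <- min(max(pr[i, j, k], 1e-7), 1 - 1e-7)
    acc <- acc - (yr[i, j, k] * log(pc) + (1 - yr[i, j, k]) * log(1 - pc))
  }
  expect_equal(multilabel_loss(pr, yr), acc / 24, tolerance = 1e-12)
  expect_error(multilabel_loss(array(0.5, c(2, 2, 2)), array(1, c(2, 2))), "shape")
  expect_error(multilabel_loss(array(2, c(2, 2, 2)), array(1, c(2, 2, 2))), "0, 1")
})

test_that("cross-entropy loss softmaxes per pixel and matches a direct oracle", {
  onehot <- function(idx, C) {
    y <- array(0, c(dim(idx), C))
    for (i in seq_len(nrow(idx))) for (j in seq_len(ncol(idx))) y[i, j, idx[i, j]] <- 1
    y
  }
  idx <- matrix(1L, 2, 2)
  expect_equal(cross_entropy_loss(array(0, c(2, 2, 4)), onehot(idx, 4)),
               log(4), tolerance = 1e-12)

  # strongly separated logits drive the loss toward zero
  logits <- array(0, c(2, 2, 4))
  logits[, , 1] <- 50
  expect_lt(cross_entropy_loss(logits, onehot(idx, 4)), 1e-20)

  # direct per-pixel oracle on a random 3 x 3 x 4 instance
  set.seed(41)
  L <- array(rnorm(36, sd = 3), c(3, 3, 4))
  ridx <- matrix(sample(1:4, 9, TRUE), 3, 3)
  Y <- onehot(ridx, 4)
  acc <- 0
  for (i in 1:3) for (j in 1:3) {
    pvec <- exp(L[i, j, ]) / sum(exp(L[i, j, ]))
    acc <- acc - log(pvec[ridx[i, j]])
  }
  expect_equal(cross_entropy_loss(L, Y), acc / 9, tolerance = 1e-10)

  bad <- onehot(idx, 4)
  bad[1, 1, ] <- 0
  expect_error(cross_entropy_loss(array(0, c(2, 2, 4)), bad), "exactly one")
})

test_that("segmentation reports pool counts per class and average correctly", {
  set.seed(43)
  g1 <- region_map(matrix(sample(0:3, 100, TRUE), 10, 10))
  g2 <- region_map(matrix(sample(0:3, 100, TRUE), 10, 10))

  ident <- segmentation_report(list(g1, g2), list(g1, g2))
  per_class <- dplyr::filter(ident, !.data$class %in% c("macro", "micro"))
  expect_true(all(per_class$iou == 1 & per_class$f1 == 1))

  # duplicated identical images equal the single-image report
  single <- segmentation_report(list(g1), list(g2))
  doubled <- segmentation_report(list(g1, g1), list(g2, g2))
  expect_equal(doubled$iou, single$iou)
  expect_equal(doubled$f1, single$f1)
  expect_equal(doubled$tp[doubled$class == "micro"],
               2 * single$tp[single$class == "micro"])

  # macro equals the unweighted mean of the per-class rows
  rep1 <- segmentation_report(list(g1), list(g2))
  pc <- dplyr::filter(rep1, !.data$class %in% c("macro", "micro"))
  expect_equal(rep1$iou[rep1$class == "macro"], mean(pc$iou, na.rm = TRUE), tolerance = 1e-12)

  # a class absent everywhere is excluded from the macro with a message
  no_crown_a <- region_map(matrix(sample(0:2, 100, TRUE), 10, 10))
  no_crown_b <- region_map(matrix(sample(0:2, 100, TRUE), 10, 10))
  expect_message(rep2 <- segmentation_report(list(no_crown_a), list(no_crown_b)), "crown")
  expect_true(is.na(rep2$iou[rep2$class == "crown"]))
  expect_false(is.na(rep2$iou[rep2$class == "macro"]))

  # position stacks are scored per tooth
  m1 <- matrix(FALSE, 6, 6); m1[2:4, 2:4] <- TRUE
  m2 <- matrix(FALSE, 6, 6); m2[3:5, 3:5] <- TRUE
  sp <- tooth_position_stack(list(`3` = m1))
  st <- tooth_position_stack(list(`3` = m2))
  rep3 <- segmentation_report(list(sp), list(st))
  expect_equal(rep3$iou[rep3$class == "tooth_03"], 4 / 14, tolerance = 1e-12)
  expect_error(segmentation_report(list(), list()), "non-empty")
})

test_that("stage reports score each stage one-vs-rest with macro means", {
  ref <- c("I", "I", "II", "II", "II", "III")
  perfect <- stage_report(ref, ref, "self")
  per <- dplyr::filter(perfect, .data$stage != "macro")
  expect_equal(per$precision, rep(1, 3))
  expect_equal(per$sensitivity, rep(1, 3))
  expect_equal(per$support, c(2, 3, 1))
  expect_equal(sum(per$support), length(ref))

  # toy confusion: stages I..III with one II predicted as III
  pred <- c("I", "I", "II", "II", "III", "III")
  rep1 <- stage_report(pred, ref, "toy")
  # hand-computed one-vs-rest: II -> tp 2 fp 0 fn 1 tn 3; III -> tp 1 fp 1 fn 0 tn 4
  expect_equal(rep1$precision[rep1$stage == "II"], 1)
  expect_equal(rep1$sensitivity[rep1$stage == "II"], 2 / 3)
  expect_equal(rep1$precision[rep1$stage == "III"], 1 / 2)
  expect_equal(rep1$sensitivity[rep1$stage == "III"], 1)
  expect_equal(rep1$specificity[rep1$stage == "III"], 4 / 5)
  macro <- dplyr::filter(rep1, .data$stage == "macro")
  per1 <- dplyr::filter(rep1, .data$stage != "macro")
  expect_equal(macro$precision, mean(per1$precision), tolerance = 1e-12)
  expect_equal(macro$sensitivity, mean(per1$sensitivity), tolerance = 1e-12)
  expect_equal(macro$support, length(ref))

  expect_error(stage_report(c("I", "II"), c("I")), "equal length")
  expect_error(stage_report(c("I", "IV"), c("I", "II")), "IV")
  p <- autoplot(rep1)
  expect_s3_class(p, "ggplot")
})

test_that("reports write to CSV and aligned text", {
  rep1 <- stage_report(c("I", "II", "III"), c("I", "II", "III"), "m")
  csv <- tempfile(fileext = ".csv")
  txt <- tempfile(fileext = ".txt")
  write_report(rep1, csv, "csv")
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), 4)
  write_report(rep1, txt, "text")
  lines <- readLines(txt)
  expect_length(lines, 5)
  expect_match(lines[1], "precision")
})
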