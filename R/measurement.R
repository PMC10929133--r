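#' Measure radiographic bone loss for one tooth
#'
#' Implements the axis-and-hull RBL measurement. The tooth's longitudinal
#' axis is estimated by [principal_axis()] of the pixel coordinates (by
#' default over the whole tooth — crown plus both root regions, matching the
#' enclosing-ellipse view of the full tooth body; `axis_source = "root"`
#' restricts PCA to the root pixels). The infinite line through the centroid
#' along that axis is clipped against two convex hulls:
#' \itemize{
#'   \item `a` — length inside the hull of the suprabony root region (the
#'     part of the root exposed by bone loss);
#'   \item `b` — length inside the hull of the whole root
#'     (suprabony plus intrabony together).
#' }
#' The bone-loss percentage is `rbl_percent = 100 * a / b`, clamped to
#' `[0, 100]` (hull inclusion guarantees `a <= b` mathematically; the clamp
#' guards float noise only), and a stage is assigned with [assign_stage()].
#'
#' Quality flags: `DEGENERATE_AXIS` (near-equal eigenvalues, axis direction
#' unreliable), `NO_INTRABONY` (whole root is suprabony, RBL = 100),
#' `NO_SUPRABONY` (no exposed root, RBL = 0). A tooth with no root pixels at
#' all is unmeasurable and raises an error (`EMPTY_ROOT`).
#'
#' @param tooth A [tooth_region_mask()].
#' @param axis_source `"tooth"` (default) to run PCA on crown + roots, or
#'   `"root"` for roots only.
#' @param thresholds Stage cut-offs passed to [assign_stage()].
#' @return A one-row tibble: `tooth_number`, `a`, `b` (pixels),
#'   `rbl_percent`, `stage`, `flags` (`;`-separated).
#' @seealso [measure_dentition()] for many teeth at once,
#'   [rbl_geometry()] for the underlying axis and hulls.
#' @export
measure_rbl <- function(tooth, axis_source = c("tooth", "root"),
                        thresholds = c(15, 33)) {
  geom <- rbl_geometry(tooth, axis_source = axis_source)
  rbl <- if (geom$b > 0) min(100, 100 * min(geom$a, geom$b) / geom$b) else 0
  tibble::tibble(
    tooth_number = tooth$tooth_number,
    a = geom$a, b = geom$b,
    rbl_percent = rbl,
    stage = assign_stage(rbl, thresholds = thresholds),
    flags = paste(geom$flags, collapse = ";")
  )
}

#' Axis and hull geometry behind an RBL measurement
#'
#' @inheritParams measure_rbl
#' @return A list: `axis` ([principal_axis()]), `hull_supra`, `hull_root`
#'   ([convex_hull()] polygons or `NULL` when the region is empty), lengths
#'   `a` and `b`, and `flags` (character vector).
#' @export
rbl_geometry <- function(tooth, axis_source = c("tooth", "root")) {
  stopifnot(inherits(tooth, "tooth_region_mask"))
  axis_source <- match.arg(axis_source)
  root <- tooth$suprabony | tooth$intrabony
  if (!any(root)) {
    rlang::abort(sprintf(
      "EMPTY_ROOT: tooth %d has no root pixels (crown-only teeth are unmeasurable).",
      tooth$tooth_number))
  }
  axis_mask <- if (axis_source == "tooth") tooth_union(tooth) else root
  axis <- principal_axis(axis_mask)
  flags <- character()
  if (axis$degenerate) flags <- c(flags, "DEGENERATE_AXIS")
  hull_root <- convex_hull(root)
  b <- axis_length_in_hull(axis, hull_root)
  if (any(tooth$suprabony)) {
    hull_supra <- convex_hull(tooth$suprabony)
    a <- axis_length_in_hull(axis, hull_supra)
  } else {
    hull_supra <- NULL
    a <- 0
    flags <- c(flags, "NO_SUPRABONY")
  }
  if (!any(tooth$intrabony)) flags <- c(flags, "NO_INTRABONY")
  if (b <= 0 && !("DEGENERATE_AXIS" %in% flags)) flags <- c(flags, "DEGENERATE_AXIS")
  list(axis = axis, hull_supra = hull_supra, hull_root = hull_root,
       a = a, b = b, flags = flags)
}

#' Assign a periodontitis bone-loss stage from RBL%
#'
#' Severity staging of radiographic bone loss per the 2018 periodontitis
#' classification: stage I for RBL below `thresholds[1]` (coronal third,
#' default < 15%), stage II from `thresholds[1]` up to but excluding
#' `thresholds[2]` (default 15-33%), stage III at or above `thresholds[2]`
#' (middle/apical third, default >= 33%).
#'
#' @param rbl_percent Numeric vector of RBL percentages in `[0, 100]`.
#' @param thresholds Length-2 increasing cut-offs, default `c(15, 33)`.
#' @return Factor with levels `I`, `II`, `III`, same length as the input.
#' @examples
#' assign_stage(c(10, 15, 40))
#' @export
assign_stage <- function(rbl_percent, thresholds = c(15, 33)) {
  if (length(thresholds) != 2L || !all(is.finite(thresholds)) ||
      thresholds[1] >= thresholds[2]) {
    rlang::abort("`thresholds` must be two increasing finite cut-offs.")
  }
  if (any(!is.finite(rbl_percent)) || any(rbl_percent < 0 | rbl_percent > 100)) {
    rlang::abort("`rbl_percent` must be finite and within [0, 100].")
  }
  out <- ifelse(rbl_percent < thresholds[1], "I",
                ifelse(rbl_percent < thresholds[2], "II", "III"))
  factor(out, levels = c("I", "II", "III"))
}

#' Measure radiographic bone loss for a whole dentition
#'
#' Runs [measure_rbl()] over a list of per-tooth masks (as produced by
#' [merge_positions_with_regions()]) and bundles the per-tooth table with the
#' dentition-level summary into an `rbl_analysis` object with
#' [tidy()][tidy.rbl_analysis], [glance()][glance.rbl_analysis] and
#' [autoplot()][autoplot.rbl_analysis] methods.
#'
#' @param teeth List of [tooth_region_mask()] objects.
#' @param axis_source,thresholds Passed to [measure_rbl()].
#' @param exclude_third_molars Should third molars (teeth 1, 16, 17, 32) be
#'   excluded from the dentition-maximum summary? Default `TRUE`.
#' @return An object of class `rbl_analysis`.
#' @export
measure_dentition <- function(teeth, axis_source = c("tooth", "root"),
                              thresholds = c(15, 33),
                              exclude_third_molars = TRUE) {
  if (length(teeth) == 0L) rlang::abort("`teeth` must be a non-empty list of tooth masks.")
  axis_source <- match.arg(axis_source)
  results <- purrr::map_dfr(teeth, measure_rbl,
                            axis_source = axis_source, thresholds = thresholds)
  results <- dplyr::arrange(results, .data$tooth_number)
  structure(
    list(results = results, axis_source = axis_source, thresholds = thresholds,
         exclude_third_molars = exclude_third_molars),
    class = "rbl_analysis"
  )
}

#' @export
print.rbl_analysis <- function(x, ...) {
  cat(sprintf("<rbl_analysis> %d teeth (axis over %s pixels, stage cut-offs %g/%g)\n",
              nrow(x$results), x$axis_source, x$thresholds[1], x$thresholds[2]))
  print(x$results)
  smry <- tryCatch(
    max_rbl_dentition(x$results, exclude_third_molars = x$exclude_third_molars),
    error = function(e) NULL
  )
  if (!is.null(smry)) {
    cat(sprintf("Dentition maximum RBL %.1f%% (tooth %d) -> stage %s%s\n",
                smry$rbl_percent, smry$tooth_number, smry$stage,
                if (x$exclude_third_molars) " [third molars excluded]" else ""))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-tooth results of an RBL analysis
#' @param x An `rbl_analysis` object.
#' @param ... Unused.
#' @return A tibble with one row per tooth.
#' @export
tidy.rbl_analysis <- function(x, ...) x$results

#' One-row summary of an RBL analysis
#'
#' Reports the number of teeth measured and the dentition-level maximum used
#' for staging (third molars excluded when the analysis says so).
#'
#' @param x An `rbl_analysis` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_teeth`, `max_rbl_percent`, `max_rbl_tooth`,
#'   `stage`, `n_flagged`.
#' @export
glance.rbl_analysis <- function(x, ...) {
  smry <- max_rbl_dentition(x$results, exclude_third_molars = x$exclude_third_molars)
  tibble::tibble(
    n_teeth = nrow(x$results),
    max_rbl_percent = smry$rbl_percent,
    max_rbl_tooth = smry$tooth_number,
    stage = smry$stage,
    n_flagged = sum(x$results$flags != "")
  )
}

#' Dentition-level maximum RBL and stage
#'
#' The dentition is staged by the maximum RBL over the permanent teeth,
#' excluding third molars (universal numbers 1, 16, 17, 32) by default.
#'
#' @param results A tibble with `tooth_number`, `rbl_percent` columns (e.g.
#'   from [measure_dentition()] via `tidy()`).
#' @param exclude_third_molars Drop teeth 1, 16, 17, 32 first? Default `TRUE`.
#' @param thresholds Stage cut-offs for [assign_stage()].
#' @return One-row tibble: `tooth_number` (arg-max), `rbl_percent`, `stage`.
#' @export
max_rbl_dentition <- function(results, exclude_third_molars = TRUE,
                              thresholds = c(15, 33)) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    rlang::abort("`results` must be a non-empty data frame.")
  }
  keep <- results
  if (exclude_third_molars) {
    keep <- dplyr::filter(keep, !.data$tooth_number %in% c(1L, 16L, 17L, 32L))
  }
  if (nrow(keep) == 0L) {
    rlang::abort("No teeth left after excluding third molars.")
  }
  top <- keep[which.max(keep$rbl_percent), ]
  tibble::tibble(
    tooth_number = top$tooth_number,
    rbl_percent = top$rbl_percent,
    stage = assign_stage(top$rbl_percent, thresholds = thresholds)
  )
}

#' Manual RBL by landmark line lengths
#'
#' The first clinical reference method: on each side of the tooth, the length
#' of the CEJ-to-ABC line as a fraction of the CEJ-to-AP line, taking the
#' worse (larger) of the proximal and distal sides —
#' `100 * max(L1/L2, R1/R2)` with `L1 = |CEJ_prox - ABC_prox|`,
#' `L2 = |CEJ_prox - AP|` and likewise `R` for the distal side.
#'
#' @param landmarks A landmark tibble (see [validate_landmarks()]).
#' @return The input with columns `l1`, `l2`, `r1`, `r2` (pixels) and
#'   `rbl_length_percent` appended.
#' @export
manual_rbl_length <- function(landmarks) {
  lm <- validate_landmarks(landmarks)
  dist2d <- function(r1, c1, r2, c2) sqrt((r1 - r2)^2 + (c1 - c2)^2)
  out <- dplyr::mutate(
    lm,
    l1 = dist2d(.data$cej_prox_row, .data$cej_prox_col, .data$abc_prox_row, .data$abc_prox_col),
    l2 = dist2d(.data$cej_prox_row, .data$cej_prox_col, .data$ap_row, .data$ap_col),
    r1 = dist2d(.data$cej_dist_row, .data$cej_dist_col, .data$abc_dist_row, .data$abc_dist_col),
    r2 = dist2d(.data$cej_dist_row, .data$cej_dist_col, .data$ap_row, .data$ap_col)
  )
  check_denominators(out, "l2", "r2")
  dplyr::mutate(out, rbl_length_percent = 100 * pmax(.data$l1 / .data$l2, .data$r1 / .data$r2))
}

#' Manual RBL by axial landmark distances
#'
#' The second clinical reference method: distances are measured along the
#' tooth's long axis (signed displacements projected onto `axis_direction`,
#' absolute value taken), not as raw line lengths —
#' `100 * max(L3/L4, R3/R4)` with `L3 = |(ABC_prox - CEJ_prox) . axis|`,
#' `L4 = |(AP - CEJ_prox) . axis|` and likewise `R`. Lateral displacement of
#' a landmark (perpendicular to the axis) therefore does not change the
#' result. With `axis_direction = c(0, 1)`-style image-vertical conventions
#' see `mode`.
#'
#' @param landmarks A landmark tibble (see [validate_landmarks()]).
#' @param axis_direction Unit 2-vector `(row, col)` of the tooth's long axis,
#'   recycled across rows, or an n x 2 matrix with one direction per tooth.
#'   Ignored when `mode = "image_vertical"`.
#' @param mode `"axial"` (default) projects onto `axis_direction`;
#'   `"image_vertical"` uses the image row axis `(1, 0)` instead.
#' @return The input with `l3`, `l4`, `r3`, `r4` and `rbl_distance_percent`
#'   appended.
#' @export
manual_rbl_distance <- function(landmarks, axis_direction = c(1, 0),
                                mode = c("axial", "image_vertical")) {
  lm <- validate_landmarks(landmarks)
  mode <- match.arg(mode)
  n <- nrow(lm)
  if (mode == "image_vertical") {
    dirs <- matrix(c(1, 0), n, 2, byrow = TRUE)
  } else if (is.matrix(axis_direction)) {
    if (nrow(axis_direction) != n || ncol(axis_direction) != 2L) {
      rlang::abort("`axis_direction` matrix must be n x 2.")
    }
    dirs <- axis_direction
  } else {
    if (length(axis_direction) != 2L) rlang::abort("`axis_direction` must be a 2-vector.")
    dirs <- matrix(axis_direction, n, 2, byrow = TRUE)
  }
  norms <- sqrt(rowSums(dirs^2))
  if (any(abs(norms - 1) > 1e-6)) {
    rlang::abort("`axis_direction` must be unit length.")
  }
  proj <- function(dr, dc) abs(dr * dirs[, 1] + dc * dirs[, 2])
  out <- dplyr::mutate(
    lm,
    l3 = proj(.data$abc_prox_row - .data$cej_prox_row, .data$abc_prox_col - .data$cej_prox_col),
    l4 = proj(.data$ap_row - .data$cej_prox_row, .data$ap_col - .data$cej_prox_col),
    r3 = proj(.data$abc_dist_row - .data$cej_dist_row, .data$abc_dist_col - .data$cej_dist_col),
    r4 = proj(.data$ap_row - .data$cej_dist_row, .data$ap_col - .data$cej_dist_col)
  )
  check_denominators(out, "l4", "r4")
  dplyr::mutate(out, rbl_distance_percent = 100 * pmax(.data$l3 / .data$l4, .data$r3 / .data$r4))
}

check_denominators <- function(df, prox_col, dist_col) {
  bad_p <- which(df[[prox_col]] <= 0)
  bad_d <- which(df[[dist_col]] <= 0)
  if (length(bad_p) > 0L) {
    rlang::abort(sprintf(
      "Zero CEJ-AP denominator on the proximal side for tooth %s.",
      paste(df$tooth_number[bad_p], collapse = ", ")))
  }
  if (length(bad_d) > 0L) {
    rlang::abort(sprintf(
      "Zero CEJ-AP denominator on the distal side for tooth %s.",
      paste(df$tooth_number[bad_d], collapse = ", ")))
  }
  invisible(df)
}
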