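#' Crop the dental region from a tooth position stack
#'
#' Computes the tight bounding box of the union of all set pixels across the
#' per-tooth masks, expands it by `padding` on every side, clips it to the
#' image bounds, and returns both the box and the cropped stack. The box is
#' half-open, `[row0, row1) x [col0, col1)` in 1-based pixel coordinates, and
#' the cropped stack records its origin in the parent frame via `offset`.
#'
#' @param positions A [tooth_position_stack()].
#' @param padding Margin in pixels added around the tight box (default 10);
#'   a small margin keeps hull geometry clear of the crop border.
#' @return A list with elements `bbox` (`c(row0, col0, row1, col1)`) and
#'   `positions` (the cropped stack).
#' @export
crop_dental_region <- function(positions, padding = 10L) {
  stopifnot(inherits(positions, "tooth_position_stack"))
  if (padding < 0L) rlang::abort("`padding` must be non-negative.")
  if (length(positions$masks) == 0L) rlang::abort("No teeth detected: the position stack is empty.")
  union <- Reduce(`|`, positions$masks)
  if (!any(union)) rlang::abort("No teeth detected: all position masks are empty.")
  idx <- which(union, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - padding)
  r1 <- min(positions$height, max(idx[, 1]) + padding)
  c0 <- max(1L, min(idx[, 2]) - padding)
  c1 <- min(positions$width, max(idx[, 2]) + padding)
  cropped <- lapply(positions$masks, function(m) m[r0:r1, c0:c1, drop = FALSE])
  list(
    bbox = c(r0, c0, r1 + 1L, c1 + 1L),
    positions = tooth_position_stack(cropped, offset = c(r0, c0))
  )
}

#' Merge tooth positions with region segmentation into per-tooth masks
#'
#' For each tooth `t` in the stack, intersects its position mask with the
#' three foreground classes of the region map: crown = positions\[t\] AND
#' (regions == 3), suprabony = positions\[t\] AND (regions == 2), intrabony =
#' positions\[t\] AND (regions == 1). Pixels claimed by several overlapping
#' teeth appear in every claiming tooth's output (multi-label). Teeth whose
#' merged masks fall below `min_pixels` total are omitted with a message;
#' teeth with roots but no crown are kept, since measurement needs roots.
#'
#' @param positions A [tooth_position_stack()].
#' @param regions A [region_map()] of the same shape. If shapes differ and
#'   the stack carries a crop `offset`, the region map is cropped to the
#'   stack's window first.
#' @param min_pixels Minimum total pixels for a tooth to be kept (default 1).
#' @return A list of [tooth_region_mask()] objects, ordered by tooth number.
#' @export
merge_positions_with_regions <- function(positions, regions, min_pixels = 1L) {
  stopifnot(inherits(positions, "tooth_position_stack"))
  regions <- region_map(unclass(regions))
  pd <- c(positions$height, positions$width)
  if (!identical(dim(regions), pd)) {
    off <- positions$offset
    if (identical(off, c(1L, 1L))) {
      rlang::abort(sprintf(
        "Shape mismatch: positions are %d x %d but regions are %d x %d (no crop offset to align by).",
        pd[1], pd[2], nrow(regions), ncol(regions)))
    }
    fits <- off[1] >= 1L && off[2] >= 1L &&
      off[1] + pd[1] - 1L <= nrow(regions) && off[2] + pd[2] - 1L <= ncol(regions)
    if (!fits) {
      rlang::abort(sprintf(
        "Shape mismatch: positions are %d x %d (offset %d,%d) but regions are %d x %d.",
        pd[1], pd[2], off[1], off[2], nrow(regions), ncol(regions)))
    }
    regions <- region_map(unclass(regions)[off[1]:(off[1] + pd[1] - 1L),
                                           off[2]:(off[2] + pd[2] - 1L), drop = FALSE])
  }
  crown_all <- unclass(regions) == 3L
  supra_all <- unclass(regions) == 2L
  intra_all <- unclass(regions) == 1L
  out <- list()
  for (nm in names(positions$masks)) {
    pos <- positions$masks[[nm]]
    tooth <- tooth_region_mask(
      tooth_number = as.integer(nm),
      crown = pos & crown_all,
      suprabony = pos & supra_all,
      intrabony = pos & intra_all,
      frame_offset = positions$offset
    )
    total <- sum(tooth$crown) + sum(tooth$suprabony) + sum(tooth$intrabony)
    if (total < min_pixels) {
      message(sprintf("Tooth %s omitted: %d labelled pixels (min %d).", nm, total, min_pixels))
      next
    }
    out[[length(out) + 1L]] <- tooth
  }
  out
}
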