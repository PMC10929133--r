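#' Construct a four-class region label map
#'
#' A region map is an integer matrix whose cells take values in
#' `{0, 1, 2, 3}`: 0 = background, 1 = intrabony root (root still within
#' alveolar bone), 2 = suprabony root (root exposed coronal to the bone
#' crest), 3 = tooth crown. Rows index image rows (top to bottom), columns
#' index image columns (left to right); pixel centers sit at integer
#' (row, col) coordinates.
#'
#' @param labels An integer matrix (or something coercible to one) with all
#'   values in `{0, 1, 2, 3}`.
#' @return An integer matrix of class `region_map`.
#' @examples
#' region_map(matrix(c(0L, 1L, 2L, 3L), 2, 2))
#' @export
region_map <- function(labels) {
  if (is.data.frame(labels)) labels <- as.matrix(labels)
  if (!is.matrix(labels) || !is.numeric(labels)) {
    rlang::abort("`labels` must be a numeric matrix.")
  }
  if (any(dim(labels) < 1L)) rlang::abort("`labels` must have positive dimensions.")
  if (anyNA(labels)) rlang::abort("`labels` must not contain NA.")
  vals <- as.vector(labels)
  if (any(vals != as.integer(vals))) {
    rlang::abort("Region labels must be integers in {0, 1, 2, 3}.")
  }
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(vals), 0:3)
  if (length(bad) > 0L) {
    rlang::abort(paste0(
      "Region labels must be in {0, 1, 2, 3}; found out-of-range label",
      if (length(bad) > 1L) "s " else " ", paste(sort(bad), collapse = ", "), "."
    ))
  }
  class(labels) <- c("region_map", "matrix", "array")
  labels
}

#' @export
print.region_map <- function(x, ...) {
  counts <- tabulate(as.vector(x) + 1L, nbins = 4L)
  cat(sprintf(
    "<region_map> %d x %d pixels (background %d, intrabony %d, suprabony %d, crown %d)\n",
    nrow(x), ncol(x), counts[1], counts[2], counts[3], counts[4]
  ))
  invisible(x)
}

#' Construct a stack of per-tooth position masks
#'
#' Holds one binary mask per tooth position under the universal numbering
#' system (1-32). Masks may overlap: a pixel can belong to several teeth at
#' once, as happens where neighbouring teeth project onto the same region of
#' a panoramic radiograph.
#'
#' @param masks Named list of logical matrices; names are tooth numbers
#'   (`"1"`-`"32"`, or integers). All masks must share dimensions.
#' @param height,width Image dimensions in pixels. Required when `masks` is
#'   empty; otherwise inferred (and checked) from the masks.
#' @param offset Length-2 integer `(row, col)` of this stack's origin in its
#'   parent image frame; `c(1, 1)` for an uncropped stack.
#' @return An object of class `tooth_position_stack`.
#' @export
tooth_position_stack <- function(masks = list(), height = NULL, width = NULL,
                                 offset = c(1L, 1L)) {
  if (length(masks) > 0L) {
    nums <- suppressWarnings(as.integer(names(masks)))
    if (anyNA(nums) || any(nums < 1L | nums > 32L)) {
      rlang::abort("Mask names must be tooth numbers 1-32 (universal numbering).")
    }
    if (anyDuplicated(nums)) rlang::abort("Duplicate tooth numbers in `masks`.")
    masks <- lapply(masks, function(m) {
      if (!is.matrix(m)) rlang::abort("Each mask must be a matrix.")
      storage.mode(m) <- "logical"
      m
    })
    dims <- vapply(masks, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      rlang::abort("All position masks must share the same dimensions.")
    }
    if (is.null(height)) height <- dims[1, 1]
    if (is.null(width)) width <- dims[2, 1]
    if (height != dims[1, 1] || width != dims[2, 1]) {
      rlang::abort("`height`/`width` disagree with mask dimensions.")
    }
    masks <- masks[order(nums)]
    names(masks) <- as.character(sort(nums))
  } else {
    if (is.null(height) || is.null(width)) {
      rlang::abort("`height` and `width` are required when `masks` is empty.")
    }
  }
  if (height < 1L || width < 1L) rlang::abort("Dimensions must be positive.")
  structure(
    list(height = as.integer(height), width = as.integer(width),
         masks = masks, offset = as.integer(offset)),
    class = "tooth_position_stack"
  )
}

#' @export
print.tooth_position_stack <- function(x, ...) {
  cat(sprintf(
    "<tooth_position_stack> %d x %d pixels, %d teeth (%s)\n",
    x$height, x$width, length(x$masks),
    if (length(x$masks)) paste(names(x$masks), collapse = ", ") else "none"
  ))
  invisible(x)
}

#' Tooth numbers present in a position stack
#' @param stack A [tooth_position_stack()].
#' @return Integer vector of tooth numbers.
#' @export
stack_teeth <- function(stack) {
  stopifnot(inherits(stack, "tooth_position_stack"))
  as.integer(names(stack$masks))
}

#' Construct one tooth's three-region mask
#'
#' Binary crown / suprabony-root / intrabony-root masks for a single tooth,
#' all in the same pixel frame. Within one tooth the three regions are
#' pairwise disjoint: a pixel has at most one region label.
#'
#' @param tooth_number Universal tooth number, 1-32.
#' @param crown,suprabony,intrabony Logical matrices of identical dimensions.
#' @param frame_offset `(row, col)` of this crop's origin in the parent image.
#' @return An object of class `tooth_region_mask`.
#' @export
tooth_region_mask <- function(tooth_number, crown, suprabony, intrabony,
                              frame_offset = c(1L, 1L)) {
  tooth_number <- as.integer(tooth_number)
  if (is.na(tooth_number) || tooth_number < 1L || tooth_number > 32L) {
    rlang::abort("`tooth_number` must be in 1-32.")
  }
  grids <- list(crown = crown, suprabony = suprabony, intrabony = intrabony)
  grids <- lapply(grids, function(m) {
    if (!is.matrix(m)) rlang::abort("Region grids must be matrices.")
    storage.mode(m) <- "logical"
    m
  })
  d <- dim(grids$crown)
  if (!identical(d, dim(grids$suprabony)) || !identical(d, dim(grids$intrabony))) {
    rlang::abort("crown, suprabony and intrabony grids must share dimensions.")
  }
  overlap <- grids$crown + grids$suprabony + grids$intrabony
  if (any(overlap > 1L)) {
    rlang::abort("Region grids must be pairwise disjoint within a tooth.")
  }
  structure(
    list(tooth_number = tooth_number, crown = grids$crown,
         suprabony = grids$suprabony, intrabony = grids$intrabony,
         frame_offset = as.integer(frame_offset)),
    class = "tooth_region_mask"
  )
}

#' @export
print.tooth_region_mask <- function(x, ...) {
  cat(sprintf(
    "<tooth_region_mask> tooth %d: crown %d px, suprabony %d px, intrabony %d px (%d x %d frame)\n",
    x$tooth_number, sum(x$crown), sum(x$suprabony), sum(x$intrabony),
    nrow(x$crown), ncol(x$crown)
  ))
  invisible(x)
}

#' Whole-tooth mask (crown plus both root regions)
#' @param tooth A [tooth_region_mask()].
#' @return Logical matrix.
#' @export
tooth_union <- function(tooth) {
  stopifnot(inherits(tooth, "tooth_region_mask"))
  tooth$crown | tooth$suprabony | tooth$intrabony
}

# Validate a landmark table: one row per tooth with sub-pixel (row, col)
# coordinates for the proximal/distal cemento-enamel junction (CEJ), the
# proximal/distal alveolar bone crest (ABC), and the root apex (AP).
landmark_columns <- c(
  "tooth_number",
  "cej_prox_row", "cej_prox_col", "cej_dist_row", "cej_dist_col",
  "abc_prox_row", "abc_prox_col", "abc_dist_row", "abc_dist_col",
  "ap_row", "ap_col"
)

#' Validate a landmark table
#'
#' Landmark tables are plain tibbles with one row per tooth and columns
#' `tooth_number`, `cej_prox_row`/`_col`, `cej_dist_row`/`_col`,
#' `abc_prox_row`/`_col`, `abc_dist_row`/`_col`, `ap_row`/`_col` — the
#' cemento-enamel junction (CEJ), alveolar bone crest (ABC) and apical point
#' (AP) used by the manual reference measurements.
#'
#' @param landmarks A data frame.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_landmarks <- function(landmarks) {
  if (!is.data.frame(landmarks)) rlang::abort("`landmarks` must be a data frame.")
  missing_cols <- setdiff(landmark_columns, names(landmarks))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("Landmark table is missing columns: ",
                        paste(missing_cols, collapse = ", "), "."))
  }
  tibble::as_tibble(landmarks)
}
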