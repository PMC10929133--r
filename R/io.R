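#' Read a region label map from an indexed PNG
#'
#' The file must be a single-channel (grayscale) PNG whose 8-bit pixel values
#' are the region labels themselves: 0 background, 1 intrabony root,
#' 2 suprabony root, 3 crown. Any other value is rejected with an error that
#' names the offending label.
#'
#' @param path Path to a PNG file.
#' @return A [region_map()].
#' @export
read_region_map <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("Cannot read region map: no such file '", path, "'."))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L && !all(img[, , 1] == img[, , min(2L, dim(img)[3])])) {
      rlang::abort("Region map PNG must be single-channel.")
    }
    img <- img[, , 1]
  }
  labels <- round(img * 255)
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad) > 0L) {
    rlang::abort(paste0("Region map '", path, "' contains out-of-range label",
                        if (length(bad) > 1L) "s " else " ",
                        paste(sort(bad), collapse = ", "),
                        "; allowed labels are 0-3."))
  }
  region_map(labels)
}

#' Write a region label map as an indexed PNG
#'
#' Inverse of [read_region_map()]: labels are stored verbatim as 8-bit gray
#' levels, so a write/read round trip is bit-exact.
#'
#' @param regions A [region_map()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_region_map <- function(regions, path) {
  regions <- region_map(unclass(regions))
  png::writePNG(matrix(as.vector(regions) / 255, nrow(regions), ncol(regions)), path)
  invisible(path)
}

#' Write / read a tooth position stack as per-tooth PNG masks
#'
#' Each tooth's binary mask is stored as `tooth_<nn>.png` (gray levels 0/1)
#' in `dir`; overlap between teeth is preserved because every tooth has its
#' own file.
#'
#' @param stack A [tooth_position_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_position_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "tooth_position_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(stack$masks)) {
    m <- stack$masks[[nm]]
    png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)),
                  file.path(dir, sprintf("tooth_%02d.png", as.integer(nm))))
  }
  invisible(dir)
}

#' @rdname write_position_stack
#' @export
read_position_stack <- function(dir) {
  if (!dir.exists(dir)) rlang::abort(paste0("No such directory '", dir, "'."))
  files <- list.files(dir, pattern = "^tooth_[0-9]+\\.png$", full.names = TRUE)
  masks <- list()
  for (f in files) {
    n <- as.integer(sub("^tooth_0*([0-9]+)\\.png$", "\\1", basename(f)))
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    masks[[as.character(n)]] <- img > 0.5
  }
  if (length(masks) == 0L) rlang::abort(paste0("No tooth_<nn>.png masks found in '", dir, "'."))
  tooth_position_stack(masks)
}

#' Read LabelMe polygon annotations into a tooth position stack
#'
#' Parses a LabelMe-style JSON document: a `shapes` array whose entries carry
#' a `label` string of the form `"tooth_<n>"` (n in 1-32) and a `points`
#' list of `(x, y)` vertices. Each polygon is rasterized onto an
#' `height x width` grid with the center-inclusive rule: a pixel is set when
#' its center lies strictly inside the polygon or exactly on its boundary.
#' LabelMe `(x, y)` maps to `(col, row)`; coordinates are taken as 1-based
#' pixel-center positions. Two polygons with the same label are unioned;
#' polygons with different labels may overlap freely.
#'
#' @param path Path to a LabelMe JSON file.
#' @param height,width Dimensions of the target mask grid, in pixels.
#' @return A [tooth_position_stack()].
#' @export
read_labelme_positions <- function(path, height, width) {
  if (!file.exists(path)) rlang::abort(paste0("Cannot read annotations: no such file '", path, "'."))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  shapes <- doc$shapes %||% list()
  masks <- list()
  for (shape in shapes) {
    label <- shape$label
    m <- regmatches(label, regexec("^tooth_([0-9]+)$", label))[[1]]
    if (length(m) != 2L) {
      rlang::abort(paste0("Unknown label '", label, "'; expected 'tooth_<n>' with n in 1-32."))
    }
    n <- as.integer(m[2])
    if (n < 1L || n > 32L) {
      rlang::abort(paste0("Label '", label, "' is outside the universal numbering range 1-32."))
    }
    pts <- shape$points
    if (length(pts) < 3L) {
      rlang::abort(paste0("Polygon for '", label, "' has fewer than 3 vertices."))
    }
    xy <- do.call(rbind, lapply(pts, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    mask <- rasterize_polygon(row = xy[, 2], col = xy[, 1], height = height, width = width)
    key <- as.character(n)
    masks[[key]] <- if (is.null(masks[[key]])) mask else masks[[key]] | mask
  }
  tooth_position_stack(masks, height = height, width = width)
}

# Center-inclusive polygon rasterization: even-odd ray crossing for strict
# interior plus an explicit on-boundary test, evaluated at integer pixel
# centers within the polygon's bounding box.
rasterize_polygon <- function(row, col, height, width, tol = 1e-9) {
  n <- length(row)
  mask <- matrix(FALSE, height, width)
  r0 <- max(1L, floor(min(row))); r1 <- min(height, ceiling(max(row)))
  c0 <- max(1L, floor(min(col))); c1 <- min(width, ceiling(max(col)))
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- rep(r0:r1, times = c1 - c0 + 1L)
  cols <- rep(c0:c1, each = r1 - r0 + 1L)
  inside <- rep(FALSE, length(rows))
  on_edge <- rep(FALSE, length(rows))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ry <- row[i]; cy <- col[i]; rz <- row[j]; cz <- col[j]
    # on-segment: zero cross product and within the segment's bounding box
    cross <- (cz - cy) * (rows - ry) - (rz - ry) * (cols - cy)
    seg_len2 <- (cz - cy)^2 + (rz - ry)^2
    on_seg <- abs(cross) <= tol * max(1, sqrt(seg_len2)) &
      cols >= pmin(cy, cz) - tol & cols <= pmax(cy, cz) + tol &
      rows >= pmin(ry, rz) - tol & rows <= pmax(ry, rz) + tol
    on_edge <- on_edge | on_seg
    # even-odd crossing of a horizontal ray in +col direction (rays cast in
    # row space: edge straddles the pixel's row)
    straddle <- (ry > rows) != (rz > rows)
    xint <- cy + (rows - ry) * (cz - cy) / ifelse(rz == ry, Inf, rz - ry)
    inside <- xor(inside, straddle & (cols < xint))
  }
  mask[cbind(rows, cols)] <- inside | on_edge
  mask
}

#' Write per-tooth RBL results to CSV
#'
#' One row per tooth, ordered by tooth number, with columns `tooth_number`,
#' `a` (axis length in the suprabony hull, px), `b` (axis length in the
#' whole-root hull, px), `rbl_percent`, `stage`, `flags` (`;`-separated
#' quality flags, empty when clean).
#'
#' @param results A tibble as returned by [measure_rbl()] /
#'   [tidy()][tidy.rbl_analysis] on an analysis object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rbl_report <- function(results, path) {
  cols <- c("tooth_number", "a", "b", "rbl_percent", "stage", "flags")
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("`results` is missing columns: ",
                        paste(missing_cols, collapse = ", "), "."))
  }
  out <- dplyr::arrange(dplyr::select(tibble::as_tibble(results),
                                      dplyr::all_of(cols)), .data$tooth_number)
  out$stage <- as.character(out$stage)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_rbl_report
#' @export
read_rbl_report <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("No such file '", path, "'."))
  readr::read_csv(path, col_types = readr::cols(
    tooth_number = readr::col_integer(), a = readr::col_double(),
    b = readr::col_double(), rbl_percent = readr::col_double(),
    stage = readr::col_character(), flags = readr::col_character()
  )) |>
    dplyr::mutate(
      stage = factor(.data$stage, levels = c("I", "II", "III")),
      flags = dplyr::coalesce(.data$flags, "")
    )
}
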