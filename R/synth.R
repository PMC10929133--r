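#' Specification for one synthetic tooth phantom
#'
#' Describes a stylized tooth: a rounded crown block atop 1-3 tapered roots,
#' with a bone crest line perpendicular to the tooth axis placed
#' `bone_loss_fraction` of the way down the root. The coronal
#' `bone_loss_fraction` of the root is labelled suprabony (exposed), the
#' remainder intrabony, so the ground-truth RBL is exactly
#' `100 * bone_loss_fraction`. Default dimensions approximate a molar-sized
#' tooth on a panoramic radiograph at ordinary resolution.
#'
#' @param tooth_number Universal tooth number (1-32).
#' @param root_count 1, 2 or 3 roots, placed symmetrically about the axis
#'   with an inter-root gap.
#' @param crown_height,crown_width,root_length,root_width Dimensions in
#'   pixels (`root_width` is the combined width across all roots at the CEJ).
#' @param bone_loss_fraction Fraction of the root length coronal to the bone
#'   crest, in `[0, 1]`.
#' @param tilt Rotation of the whole tooth about its center, radians
#'   (positive tilts the apex toward increasing column).
#' @param center Optional `(row, col)` center on the canvas; `NULL` centers
#'   the tooth on an auto-sized canvas.
#' @return A one-row tibble; rows from several calls can be
#'   `dplyr::bind_rows()`-ed into a dentition specification.
#' @export
tooth_spec <- function(tooth_number = 3L, root_count = 1L,
                       crown_height = 40, crown_width = 44,
                       root_length = 120, root_width = 36,
                       bone_loss_fraction = 0.2, tilt = 0,
                       center = NULL) {
  if (any(c(crown_height, crown_width, root_length, root_width) <= 0)) {
    rlang::abort("Tooth dimensions must be positive.")
  }
  if (bone_loss_fraction < 0 || bone_loss_fraction > 1) {
    rlang::abort("`bone_loss_fraction` must lie in [0, 1].")
  }
  if (!root_count %in% 1:3) rlang::abort("`root_count` must be 1, 2 or 3.")
  tibble::tibble(
    tooth_number = as.integer(tooth_number), root_count = as.integer(root_count),
    crown_height = crown_height, crown_width = crown_width,
    root_length = root_length, root_width = root_width,
    bone_loss_fraction = bone_loss_fraction, tilt = tilt,
    center_row = if (is.null(center)) NA_real_ else center[1],
    center_col = if (is.null(center)) NA_real_ else center[2]
  )
}

# Taper: each root narrows linearly to 45% of its CEJ width at the apex.
ROOT_TAPER <- 0.55

root_centers <- function(spec) {
  k <- spec$root_count
  (seq_len(k) - (k + 1) / 2) * (spec$root_width / k) * 1.2
}

root_half_width <- function(spec, u) {
  (spec$root_width / (2 * spec$root_count)) * (1 - ROOT_TAPER * u / spec$root_length)
}

# Tooth-local classification of displacement (du, dv) from the tooth center:
# u axial (0 at CEJ, positive apically), v lateral. Returns 0/1/2/3 labels.
classify_local <- function(spec, u, v) {
  lab <- integer(length(u))
  in_crown <- u >= -spec$crown_height & u < 0 & abs(v) <= spec$crown_width / 2
  lab[in_crown] <- 3L
  in_root <- rep(FALSE, length(u))
  for (vc in root_centers(spec)) {
    in_root <- in_root | (u >= 0 & u < spec$root_length &
                            abs(v - vc) <= root_half_width(spec, pmax(u, 0)))
  }
  u_crest <- spec$bone_loss_fraction * spec$root_length
  lab[in_root & u < u_crest] <- 2L
  lab[in_root & u >= u_crest] <- 1L
  lab
}

# Evaluate with a temporary RNG seed, restoring global RNG state afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Rasterize one tooth into an (H, W) window. Boundary jitter perturbs the
# local coordinates of each pixel with seeded Gaussian noise, roughening the
# mask edges without moving the analytic landmarks, so ground truth stays
# exact.
rasterize_tooth <- function(spec, height, width, center, seed, jitter_sd = 0) {
  rows <- rep(seq_len(height), times = width)
  cols <- rep(seq_len(width), each = height)
  ax <- c(cos(spec$tilt), sin(spec$tilt))
  pe <- c(-sin(spec$tilt), cos(spec$tilt))
  u_mid <- (spec$root_length - spec$crown_height) / 2
  dr <- rows - center[1]
  dc <- cols - center[2]
  u <- u_mid + dr * ax[1] + dc * ax[2]
  v <- dr * pe[1] + dc * pe[2]
  if (jitter_sd > 0) {
    with_local_seed(seed, {
      u <- u + stats::rnorm(length(u), sd = jitter_sd)
      v <- v + stats::rnorm(length(v), sd = jitter_sd)
    })
  }
  matrix(classify_local(spec, u, v), height, width)
}

tooth_landmarks_local <- function(spec) {
  v0 <- max(root_centers(spec)) + root_half_width(spec, 0)
  u_crest <- spec$bone_loss_fraction * spec$root_length
  v_crest <- max(root_centers(spec)) + root_half_width(spec, u_crest)
  list(
    cej_prox = c(0, -v0), cej_dist = c(0, v0),
    abc_prox = c(u_crest, -v_crest), abc_dist = c(u_crest, v_crest),
    ap = c(spec$root_length, 0)
  )
}

local_to_image <- function(spec, center, p) {
  ax <- c(cos(spec$tilt), sin(spec$tilt))
  pe <- c(-sin(spec$tilt), cos(spec$tilt))
  u_mid <- (spec$root_length - spec$crown_height) / 2
  center + (p[1] - u_mid) * ax + p[2] * pe
}

default_canvas <- function(spec, margin = 6) {
  len <- spec$crown_height + spec$root_length
  half <- len / 2 + max(spec$crown_width, spec$root_width) / 2 + margin
  size <- 2 * ceiling(half) + 1
  c(size, size)
}

#' Generate one synthetic tooth with exact ground truth
#'
#' Rasterizes the tooth described by `spec` (see [tooth_spec()]) onto a
#' canvas: crown labelled 3, the coronal `bone_loss_fraction` of the root(s)
#' labelled suprabony (2), the remainder intrabony (1); the whole shape is
#' rotated by `tilt` about its center. Landmarks (CEJ, ABC on the outer root
#' edges, apex) are placed analytically and rotated identically. Output is
#' deterministic for a fixed `(spec, seed)`.
#'
#' @param spec A one-row tibble from [tooth_spec()].
#' @param seed Integer seed (used by boundary jitter only).
#' @param jitter_sd Standard deviation in pixels of seeded boundary
#'   roughening; 0 (default) gives clean analytic boundaries. Landmarks and
#'   ground truth are never jittered.
#' @param canvas Optional `(height, width)`; `NULL` auto-sizes.
#' @return A list: `tooth` ([tooth_region_mask()]), `landmarks` (one-row
#'   landmark tibble), `true_rbl` (`100 * bone_loss_fraction`), `regions`
#'   (the tooth's own [region_map()]).
#' @export
generate_tooth <- function(spec, seed = 1L, jitter_sd = 0, canvas = NULL) {
  stopifnot(is.data.frame(spec), nrow(spec) == 1L)
  if (is.null(canvas)) canvas <- default_canvas(spec)
  center <- if (is.na(spec$center_row)) (canvas + 1) / 2 else c(spec$center_row, spec$center_col)
  len <- spec$crown_height + spec$root_length
  half_diag <- sqrt(len^2 + max(spec$crown_width, spec$root_width)^2) / 2
  if (center[1] - half_diag < 0 || center[1] + half_diag > canvas[1] + 1 ||
      center[2] - half_diag < 0 || center[2] + half_diag > canvas[2] + 1) {
    rlang::abort("Tooth does not fit the canvas.")
  }
  lab <- rasterize_tooth(spec, canvas[1], canvas[2], center, seed, jitter_sd)
  lmk <- tooth_landmarks_local(spec)
  pts <- lapply(lmk, function(p) local_to_image(spec, center, p))
  landmarks <- tibble::tibble(
    tooth_number = spec$tooth_number,
    cej_prox_row = pts$cej_prox[1], cej_prox_col = pts$cej_prox[2],
    cej_dist_row = pts$cej_dist[1], cej_dist_col = pts$cej_dist[2],
    abc_prox_row = pts$abc_prox[1], abc_prox_col = pts$abc_prox[2],
    abc_dist_row = pts$abc_dist[1], abc_dist_col = pts$abc_dist[2],
    ap_row = pts$ap[1], ap_col = pts$ap[2]
  )
  list(
    tooth = tooth_region_mask(spec$tooth_number,
                              crown = lab == 3L, suprabony = lab == 2L,
                              intrabony = lab == 1L),
    landmarks = landmarks,
    true_rbl = 100 * spec$bone_loss_fraction,
    regions = region_map(lab)
  )
}

#' Generate a multi-tooth panorama phantom with exact ground truth
#'
#' Places the specified teeth left-to-right on a shared canvas. A positive
#' `overlap_shift` pulls neighbours together so adjacent crowns overlap and
#' the tooth-position stack becomes genuinely multi-label, emulating the
#' overlapping projections of a panoramic radiograph. The region map
#' resolves contested pixels deterministically (later tooth wins) while the
#' position stack keeps every membership.
#'
#' @param specs Tibble of tooth specifications (rows from [tooth_spec()]).
#' @param canvas Optional `(height, width)`; `NULL` auto-sizes.
#' @param overlap_shift Pixels by which each tooth is shifted toward its left
#'   neighbour (default 0).
#' @param jitter_sd Seeded boundary roughening in pixels (default 0).
#' @param seed Integer seed.
#' @return An object of class `phantom_truth`: list with `regions`
#'   ([region_map()]), `positions` ([tooth_position_stack()]), `landmarks`
#'   (tibble, one row per tooth), and `truth` (tibble: `tooth_number`,
#'   `true_rbl`, `stage`).
#' @export
generate_panorama <- function(specs, canvas = NULL, overlap_shift = 0,
                              jitter_sd = 0, seed = 1L) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1L)
  if (anyDuplicated(specs$tooth_number)) {
    rlang::abort("Duplicate tooth numbers in `specs`.")
  }
  margin <- 6
  n <- nrow(specs)
  lens <- specs$crown_height + specs$root_length
  wids <- pmax(specs$crown_width, specs$root_width)
  # tight half-extents place the teeth (crowns touch at overlap_shift = 0 and
  # overlap by overlap_shift pixels); the margin only pads windows and canvas
  half_w <- wids / 2 * abs(cos(specs$tilt)) + lens / 2 * abs(sin(specs$tilt))
  half_h <- lens / 2 * abs(cos(specs$tilt)) + wids / 2 * abs(sin(specs$tilt))
  cols <- numeric(n)
  cols[1] <- half_w[1] + margin + 1
  if (n > 1L) {
    for (i in 2:n) cols[i] <- cols[i - 1] + half_w[i - 1] + half_w[i] - overlap_shift
  }
  half_w <- half_w + margin
  half_h <- half_h + margin
  if (is.null(canvas)) {
    canvas <- c(2 * ceiling(max(half_h)) + 1, ceiling(cols[n] + half_w[n]) + 1)
  }
  H <- canvas[1]; W <- canvas[2]
  if (cols[n] + half_w[n] > W + 1 || 2 * max(half_h) > H + 2) {
    rlang::abort("Teeth do not fit the canvas after shifts.")
  }
  regions <- matrix(0L, H, W)
  masks <- list()
  landmarks <- list()
  for (i in seq_len(n)) {
    spec <- specs[i, ]
    center <- c(H / 2 + 0.5, cols[i])
    # rasterize within the tooth's own window, then embed
    r0 <- max(1L, floor(center[1] - half_h[i])); r1 <- min(H, ceiling(center[1] + half_h[i]))
    c0 <- max(1L, floor(center[2] - half_w[i])); c1 <- min(W, ceiling(center[2] + half_w[i]))
    lab <- rasterize_tooth(spec, r1 - r0 + 1L, c1 - c0 + 1L,
                           center - c(r0 - 1, c0 - 1),
                           seed = seed + i, jitter_sd = jitter_sd)
    full <- matrix(FALSE, H, W)
    full[r0:r1, c0:c1] <- lab > 0L
    masks[[as.character(spec$tooth_number)]] <- full
    win <- regions[r0:r1, c0:c1]
    win[lab > 0L] <- lab[lab > 0L] # later tooth wins contested pixels
    regions[r0:r1, c0:c1] <- win
    lmk <- tooth_landmarks_local(spec)
    pts <- lapply(lmk, function(p) local_to_image(spec, center, p))
    landmarks[[i]] <- tibble::tibble(
      tooth_number = spec$tooth_number,
      cej_prox_row = pts$cej_prox[1], cej_prox_col = pts$cej_prox[2],
      cej_dist_row = pts$cej_dist[1], cej_dist_col = pts$cej_dist[2],
      abc_prox_row = pts$abc_prox[1], abc_prox_col = pts$abc_prox[2],
      abc_dist_row = pts$abc_dist[1], abc_dist_col = pts$abc_dist[2],
      ap_row = pts$ap[1], ap_col = pts$ap[2]
    )
  }
  truth <- tibble::tibble(
    tooth_number = specs$tooth_number,
    true_rbl = 100 * specs$bone_loss_fraction,
    stage = assign_stage(100 * specs$bone_loss_fraction)
  )
  structure(
    list(regions = region_map(regions),
         positions = tooth_position_stack(masks),
         landmarks = dplyr::bind_rows(landmarks),
         truth = truth),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d teeth on a %d x %d canvas; stages: %s\n",
              nrow(x$truth), nrow(x$regions), ncol(x$regions),
              paste(sprintf("%s=%d", levels(x$truth$stage),
                            tabulate(x$truth$stage, 3L)), collapse = " ")))
  invisible(x)
}

#' Draw a random dentition specification
#'
#' Convenience sampler for validation studies: tooth numbers are sampled
#' without replacement, bone-loss fractions uniformly from `fraction_range`,
#' tilts uniformly from `tilt_range`, and sizes jittered around the
#' [tooth_spec()] defaults.
#'
#' @param n Number of teeth (<= 32).
#' @param seed Integer seed.
#' @param fraction_range Range of bone-loss fractions (default 0.05-0.8,
#'   which spans all three stages).
#' @param tilt_range Tilt range in radians (default +/- 30 degrees).
#' @param root_counts Candidate root counts to sample from.
#' @return A tibble of tooth specifications.
#' @export
sample_tooth_specs <- function(n, seed = 1L,
                               fraction_range = c(0.05, 0.8),
                               tilt_range = c(-pi / 6, pi / 6),
                               root_counts = 1L) {
  if (n > 32L) rlang::abort("A dentition has at most 32 teeth.")
  with_local_seed(seed, {
    purrr::map_dfr(seq_len(n), function(i) tooth_spec(
      tooth_number = i,
      root_count = sample(root_counts, 1),
      crown_height = stats::runif(1, 32, 46),
      crown_width = stats::runif(1, 38, 50),
      root_length = stats::runif(1, 100, 150),
      root_width = stats::runif(1, 30, 42),
      bone_loss_fraction = stats::runif(1, fraction_range[1], fraction_range[2]),
      tilt = stats::runif(1, tilt_range[1], tilt_range[2])
    ))
  })
}
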