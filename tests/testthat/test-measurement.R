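band_tooth <- function(fraction, height = 160, width = 60,
                       crown_rows = 1:30, root_rows = 31:150, cols = 21:40) {
  # vertical rectangular tooth: crown block atop a root band split at
  # `fraction` of the root rows
  crown <- matrix(FALSE, height, width)
  supra <- matrix(FALSE, height, width)
  intra <- matrix(FALSE, height, width)
  crown[crown_rows, cols] <- TRUE
  n_sup <- round(length(root_rows) * fraction)
  if (n_sup > 0) supra[root_rows[seq_len(n_sup)], cols] <- TRUE
  if (n_sup < length(root_rows)) intra[root_rows[(n_sup + 1):length(root_rows)], cols] <- TRUE
  tooth_region_mask(3, crown = crown, suprabony = supra, intrabony = intra)
}

test_that("RBL degenerates correctly when one root region is empty", {
  all_supra <- band_tooth(1)
  r1 <- measure_rbl(all_supra)
  expect_equal(r1$a, r1$b)
  expect_equal(r1$rbl_percent, 100)
  expect_match(r1$flags, "NO_INTRABONY")

  no_supra <- band_tooth(0)
  r2 <- measure_rbl(no_supra)
  expect_equal(r2$a, 0)
  expect_equal(r2$rbl_percent, 0)
  expect_match(r2$flags, "NO_SUPRABONY")

  crown_only <- band_tooth(0)
  crown_only <- tooth_region_mask(3, crown = crown_only$crown,
                                  suprabony = crown_only$crown & FALSE,
                                  intrabony = crown_only$crown & FALSE)
  expect_error(measure_rbl(crown_only), "EMPTY_ROOT")
})

test_that("a coronal 25% suprabony band measures close to 25% RBL", {
  r <- measure_rbl(band_tooth(0.25))
  expect_equal(r$rbl_percent, 25, tolerance = 2 / 25) # within 2 points
  expect_equal(as.character(r$stage), "II")
  expect_true(r$a <= r$b)
})

test_that("stage assignment follows the 15/33 cut-offs and is monotone", {
  expect_equal(as.character(assign_stage(c(0, 10, 14.999))), rep("I", 3))
  expect_equal(as.character(assign_stage(c(15, 20, 32.999))), rep("II", 3))
  expect_equal(as.character(assign_stage(c(33, 40, 100))), rep("III", 3))

  grid <- seq(0, 100, by = 0.25)
  stages <- as.integer(assign_stage(grid))
  expect_true(all(diff(stages) >= 0))

  # overridable thresholds
  expect_equal(as.character(assign_stage(c(12, 27), thresholds = c(10, 25))),
               c("II", "III"))
  expect_error(assign_stage(NaN), "finite")
  expect_error(assign_stage(120), "100")
  expect_error(assign_stage(50, thresholds = c(33, 15)), "increasing")
})

random_landmarks <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    tooth_number = seq_len(n),
    cej_prox_row = runif(n, 10, 20), cej_prox_col = runif(n, 10, 20),
    cej_dist_row = runif(n, 10, 20), cej_dist_col = runif(n, 30, 40),
    abc_prox_row = runif(n, 30, 60), abc_prox_col = runif(n, 10, 20),
    abc_dist_row = runif(n, 30, 60), abc_dist_col = runif(n, 30, 40),
    ap_row = runif(n, 100, 140), ap_col = runif(n, 20, 30)
  )
}

test_that("manual length-based RBL takes the worse side of the CEJ-ABC / CEJ-AP ratio", {
  collinear <- tibble::tibble(
    tooth_number = 1L,
    cej_prox_row = 0, cej_prox_col = 0, cej_dist_row = 0, cej_dist_col = 0,
    abc_prox_row = 20, abc_prox_col = 0, abc_dist_row = 20, abc_dist_col = 0,
    ap_row = 100, ap_col = 0
  )
  expect_equal(manual_rbl_length(collinear)$rbl_length_percent, 20)

  # proximal ratio 0.2, distal ratio 0.3 -> max rule picks 30
  two_sided <- collinear
  two_sided$abc_dist_row <- 30
  expect_equal(manual_rbl_length(two_sided)$rbl_length_percent, 30)

  # duplicate-formula oracle on random landmark tables
  lm <- random_landmarks(25, seed = 91)
  got <- manual_rbl_length(lm)$rbl_length_percent
  oracle <- vapply(seq_len(nrow(lm)), function(i) {
    d <- function(p, q) sqrt(sum((p - q)^2))
    cejp <- c(lm$cej_prox_row[i], lm$cej_prox_col[i])
    cejd <- c(lm$cej_dist_row[i], lm$cej_dist_col[i])
    abcp <- c(lm$abc_prox_row[i], lm$abc_prox_col[i])
    abcd <- c(lm$abc_dist_row[i], lm$abc_dist_col[i])
    ap <- c(lm$ap_row[i], lm$ap_col[i])
    100 * max(d(cejp, abcp) / d(cejp, ap), d(cejd, abcd) / d(cejd, ap))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)

  degenerate <- collinear
  degenerate$ap_row <- 0
  expect_error(manual_rbl_length(degenerate), "proximal")
})

test_that("manual axial-distance RBL projects onto the tooth axis", {
  collinear <- tibble::tibble(
    tooth_number = 1L,
    cej_prox_row = 0, cej_prox_col = 5, cej_dist_row = 0, cej_dist_col = 5,
    abc_prox_row = 20, abc_prox_col = 5, abc_dist_row = 20, abc_dist_col = 5,
    ap_row = 100, ap_col = 5
  )
  axis_dir <- c(1, 0)
  on_axis <- manual_rbl_distance(collinear, axis_dir)$rbl_distance_percent
  expect_equal(on_axis, manual_rbl_length(collinear)$rbl_length_percent)

  # lateral (perpendicular) displacement of the ABC leaves the result unchanged
  shifted <- collinear
  shifted$abc_prox_col <- 19
  shifted$abc_dist_col <- -4
  expect_equal(manual_rbl_distance(shifted, axis_dir)$rbl_distance_percent, on_axis)

  # duplicate projection oracle on random landmarks and a random unit axis
  lm <- random_landmarks(25, seed = 17)
  ang <- 0.35
  dir <- c(cos(ang), sin(ang))
  got <- manual_rbl_distance(lm, dir)$rbl_distance_percent
  oracle <- vapply(seq_len(nrow(lm)), function(i) {
    pr <- function(p, q) abs(sum((q - p) * dir))
    cejp <- c(lm$cej_prox_row[i], lm$cej_prox_col[i])
    cejd <- c(lm$cej_dist_row[i], lm$cej_dist_col[i])
    abcp <- c(lm$abc_prox_row[i], lm$abc_prox_col[i])
    abcd <- c(lm$abc_dist_row[i], lm$abc_dist_col[i])
    ap <- c(lm$ap_row[i], lm$ap_col[i])
    100 * max(pr(cejp, abcp) / pr(cejp, ap), pr(cejd, abcd) / pr(cejd, ap))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)

  # image-vertical mode matches an explicit row-axis projection
  got_iv <- manual_rbl_distance(lm, mode = "image_vertical")$rbl_distance_percent
  got_row <- manual_rbl_distance(lm, c(1, 0))$rbl_distance_percent
  expect_equal(got_iv, got_row)
  expect_error(manual_rbl_distance(lm, c(1, 1)), "unit")
})

test_that("dentition maximum excludes third molars on request", {
  res <- tibble::tibble(tooth_number = c(3L, 9L, 30L),
                        rbl_percent = c(10, 20, 50))
  top <- max_rbl_dentition(res)
  expect_equal(top$rbl_percent, 50)
  expect_equal(as.character(top$stage), "III")

  molar <- tibble::tibble(tooth_number = c(1L, 9L),
                          rbl_percent = c(90, 20))
  with_molar <- max_rbl_dentition(molar, exclude_third_molars = FALSE)
  without <- max_rbl_dentition(molar, exclude_third_molars = TRUE)
  expect_equal(with_molar$rbl_percent, 90)
  expect_equal(as.character(with_molar$stage), "III")
  expect_equal(without$rbl_percent, 20)
  expect_equal(as.character(without$stage), "II")

  only_molar <- tibble::tibble(tooth_number = 17L, rbl_percent = 44)
  expect_error(max_rbl_dentition(only_molar), "third molars")
})

test_that("RBL is invariant to rigid rotation and uniform scaling", {
  for (theta_deg in c(15, 30, 60, 90)) {
    g <- generate_tooth(tooth_spec(bone_loss_fraction = 0.35,
                                   tilt = theta_deg * pi / 180))
    g0 <- generate_tooth(tooth_spec(bone_loss_fraction = 0.35, tilt = 0))
    r <- measure_rbl(g$tooth)$rbl_percent
    r0 <- measure_rbl(g0$tooth)$rbl_percent
    expect_lt(abs(r - r0), 2)
  }

  # scaling all mask dimensions by 2 changes RBL by < 1 point (a pure ratio)
  small <- tooth_spec(bone_loss_fraction = 0.42, crown_height = 30,
                      crown_width = 30, root_length = 90, root_width = 26)
  big <- tooth_spec(bone_loss_fraction = 0.42, crown_height = 60,
                    crown_width = 60, root_length = 180, root_width = 52)
  r_small <- measure_rbl(generate_tooth(small)$tooth)$rbl_percent
  r_big <- measure_rbl(generate_tooth(big)$tooth)$rbl_percent
  expect_lt(abs(r_small - r_big), 1)
})

test_that("measured RBL tracks ground truth monotonically as bone loss deepens", {
  fracs <- seq(0.1, 0.7, by = 0.1)
  measured <- vapply(fracs, function(f) {
    measure_rbl(generate_tooth(tooth_spec(bone_loss_fraction = f))$tooth)$rbl_percent
  }, numeric(1))
  expect_true(all(diff(measured) > -1))
})

test_that("dentition analysis tidies, glances and reports consistently", {
  teeth <- lapply(c(0.1, 0.25, 0.5), function(f) {
    g <- generate_tooth(tooth_spec(tooth_number = round(f * 20) + 2,
                                   bone_loss_fraction = f))
    g$tooth
  })
  an <- measure_dentition(teeth)
  td <- tidy(an)
  expect_equal(nrow(td), 3)
  expect_true(all(td$a <= td$b))
  expect_true(all(td$rbl_percent >= 0 & td$rbl_percent <= 100))
  gl <- glance(an)
  expect_equal(gl$n_teeth, 3)
  expect_equal(gl$max_rbl_percent, max(td$rbl_percent))
  p <- autoplot(an)
  expect_s3_class(p, "ggplot")
})
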