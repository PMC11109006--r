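make_texture <- function(ny = 40, nx = 40, seed = 1) {
  set.seed(seed)
  # smooth random texture with structure for registration
  base <- matrix(rnorm(ny * nx), ny, nx)
  k <- 5
  sm <- base
  for (i in seq_len(ny)) sm[i, ] <- stats::filter(base[i, ], rep(1 / k, k),
                                                  circular = TRUE)
  for (j in seq_len(nx)) sm[, j] <- stats::filter(sm[, j], rep(1 / k, k),
                                                  circular = TRUE)
  sm
}

test_that("registration recovers injected integer shifts", {
  img <- make_texture()
  stack <- array(0, dim = c(6, 40, 40))
  for (f in 1:6) stack[f, , ] <- img
  # inject a shift on frame 5: content moves by (dy, dx) = (3, -2)
  shifted <- matrix(0, 40, 40)
  shifted[4:40, 1:38] <- img[1:37, 3:40]
  stack[5, , ] <- shifted
  res <- align_stack(stack, radius = 5)
  expect_true(all(res$shifts$dy[-5] == 0))
  expect_true(all(res$shifts$dx[-5] == 0))
  expect_equal(res$shifts$dy[5], -3)
  expect_equal(res$shifts$dx[5], 2)
  # aligned frame matches the reference on the valid region
  ok <- !is.na(res$stack[5, , ])
  expect_lt(max(abs(res$stack[5, , ][ok] - img[ok])), 1e-10)
})

test_that("drift-free stacks report zero shifts; noise is flagged", {
  img <- make_texture(seed = 2)
  stack <- array(rep(img, each = 1), dim = c(4, 40, 40))
  for (f in 1:4) stack[f, , ] <- img
  res <- align_stack(stack)
  expect_true(all(res$shifts$dy == 0 & res$shifts$dx == 0))
  expect_false(any(res$shifts$low_confidence))
  # pure independent noise: no reliable peak -> zero shift, low confidence
  set.seed(3)
  noise <- array(rnorm(4 * 40 * 40), dim = c(4, 40, 40))
  resn <- align_stack(noise, radius = 3)
  expect_true(all(resn$shifts$dy == 0 & resn$shifts$dx == 0))
  expect_true(all(resn$shifts$low_confidence[-1]))
})

test_that("denoise_and_bin subtracts background, rejects impulses, conserves flux", {
  # constant stack: identically zero after initial-background subtraction
  const <- array(5, dim = c(7, 10, 10))
  out <- denoise_and_bin(const, median_window = 5, bin_factor = 5)
  expect_true(all(out$stack == 0))
  expect_equal(out$pixel_size, 5)
  expect_equal(dim(out$stack), c(7, 2, 2))
  # single-frame impulse removed by the 5-frame median
  imp <- array(0, dim = c(7, 10, 10))
  imp[4, 3, 3] <- 100
  outi <- denoise_and_bin(imp, median_window = 5, bin_factor = 1)
  expect_true(all(outi$stack == 0))
  # mean binning preserves the spot integral (sum of bin means x bin area
  # equals the pixel sum)
  spot <- simulate_spot_image(c(20, 20), 1, center = c(10, 10), sigma = 3,
                              height = 2)
  st <- array(0, dim = c(3, 20, 20))
  st[2, , ] <- spot
  st[3, , ] <- spot                      # frame 1 (background) stays zero
  outs <- denoise_and_bin(st, median_window = 1, bin_factor = 5)
  binned <- outs$stack[3, , ]
  expect_equal(sum(binned) * 25, sum(spot), tolerance = 1e-6)
  expect_error(denoise_and_bin(const, median_window = 9), "exceeds")
  expect_error(denoise_and_bin(const, median_window = 4), "odd")
})

test_that("empty-well coefficients remove stratified multiplicative drift", {
  wells <- make_test_wells(n_per_stratum = 4, n_frames = 5)
  # uniform data: all coefficients are exactly 1
  coefs <- empty_well_coefficients(wells)
  expect_true(all(abs(coefs$coefficient - 1) < 1e-12))
  # chamber 2 twice as bright: its coefficients are 2 and correction
  # restores equality with chamber 1
  bright <- dplyr::mutate(wells, mean_intensity = ifelse(chamber == 2,
                                                         2 * mean_intensity,
                                                         mean_intensity))
  # grand mean over empties = (100 + 200)/2 = 150 -> coefficients 2/3, 4/3
  c2 <- empty_well_coefficients(bright)
  expect_true(all(abs(c2$coefficient[c2$chamber == 2] -
                        2 * c2$coefficient[c2$chamber == 1]) < 1e-12))
  corrected <- apply_coefficients(bright, c2)
  per_ch <- corrected |>
    dplyr::group_by(chamber) |>
    dplyr::summarise(m = mean(mean_intensity))
  expect_equal(per_ch$m[1], per_ch$m[2], tolerance = 1e-12)
})

test_that("coefficient normalization is idempotent", {
  wells <- make_test_wells(n_per_stratum = 3, n_frames = 4)
  set.seed(8)
  wells$mean_intensity <- wells$mean_intensity *
    runif(nrow(wells), 0.5, 2)[as.integer(factor(paste(wells$quadrant,
                                                       wells$chamber,
                                                       wells$frame)))]
  once <- apply_coefficients(wells, empty_well_coefficients(wells))
  twice <- apply_coefficients(once, empty_well_coefficients(once))
  expect_equal(twice$mean_intensity, once$mean_intensity, tolerance = 1e-10)
})

test_that("random stratified drift is removed to sub-percent residual", {
  wells <- make_test_wells(n_per_stratum = 6, n_frames = 8)
  set.seed(12)
  strata <- wells |> dplyr::distinct(quadrant, chamber, frame) |>
    dplyr::mutate(factor = runif(dplyr::n(), 0.5, 2))
  drifted <- wells |>
    dplyr::left_join(strata, by = c("quadrant", "chamber", "frame")) |>
    dplyr::mutate(mean_intensity = mean_intensity * factor +
                    rnorm(dplyr::n(), sd = 0.1)) |>
    dplyr::select(-factor)
  corrected <- apply_coefficients(drifted, empty_well_coefficients(drifted))
  empties <- corrected |>
    dplyr::group_by(well_id) |>
    dplyr::filter(all(cell_count == 0)) |>
    dplyr::ungroup()
  grand <- mean(empties$mean_intensity)
  resid <- empties |>
    dplyr::group_by(quadrant, chamber, frame) |>
    dplyr::summarise(m = mean(mean_intensity), .groups = "drop")
  expect_lt(max(abs(resid$m / grand - 1)), 0.01)
})

test_that("a missing stratum falls back to the chamber coefficient", {
  wells <- make_test_wells(n_per_stratum = 2, n_frames = 3)
  # remove the empty well of one stratum (make it occupied)
  wells$cell_count[wells$quadrant == "upper_left" & wells$chamber == 1] <- 1L
  expect_warning(coefs <- empty_well_coefficients(wells), "chamber-level")
  expect_false(anyNA(coefs$coefficient))
})

test_that("baseline subtraction follows the IQR outlier rule", {
  wells <- make_test_wells(n_per_stratum = 8, n_frames = 5)
  # give wells distinct initial intensities; one contaminated well far out
  set.seed(4)
  inits <- setNames(100 + rnorm(length(unique(wells$well_id))),
                    unique(wells$well_id))
  contaminated <- names(inits)[5]
  inits[contaminated] <- inits[contaminated] +
    10 * stats::IQR(inits) + 50        # far beyond Q3 + 1.5 IQR
  wells$mean_intensity <- unname(inits[wells$well_id]) + wells$frame  # common growth
  css <- subtract_baseline(wells)
  expect_identical(unique(css$baseline_mode[css$well_id == contaminated]),
                   "empty_mean")
  normal <- setdiff(unique(wells$well_id), contaminated)
  expect_true(all(css$baseline_mode[css$well_id %in% normal] == "initial"))
  # own-initial wells start at exactly zero
  w1 <- css[css$well_id == normal[1], ]
  expect_equal(w1$css[w1$frame == 0], 0)
  expect_equal(w1$css[w1$frame == 4], 4)
  # degenerate IQR (identical initials): nobody is an outlier
  flat <- make_test_wells(n_per_stratum = 3, n_frames = 3)
  cf <- subtract_baseline(flat)
  expect_true(all(cf$baseline_mode == "initial"))
})

test_that("well tables round-trip through CSV", {
  wells <- make_test_wells(n_per_stratum = 2, n_frames = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_well_table(wells, path)
  back <- read_well_table(path)
  expect_equal(nrow(back), nrow(wells))
  expect_equal(back$mean_intensity, wells$mean_intensity)
  expect_identical(back$well_id, wells$well_id)
})

test_that("image stacks round-trip through multi-page float TIFF", {
  skip_if_not_installed("tiff")
  stack <- array(runif(3 * 8 * 8, 0, 50), dim = c(3, 8, 8))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(stack, path, scale = 50)
  back <- read_stack_tiff(path, scale = 50)
  expect_equal(dim(back), dim(stack))
  expect_equal(back, stack, tolerance = 1e-6)
})
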