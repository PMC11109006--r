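#' Register a time-lapse stack by integer pixel shifts
#'
#' Each frame is translated by the integer `(dy, dx)` that maximizes its
#' Pearson correlation with the reference frame over the overlapping region,
#' searched exhaustively within `radius` pixels. Pixels shifted in from
#' outside the frame are marked `NA` (invalid), never zero-filled. When the
#' best correlation falls below `min_confidence` (featureless or pure-noise
#' frames) the frame is left unshifted and flagged low-confidence.
#'
#' @param stack 3D numeric array `[frame, y, x]`.
#' @param reference Index of the reference frame (default 1).
#' @param radius Maximum shift searched in each direction, pixels (default 10).
#' @param min_confidence Minimum peak correlation to accept a shift
#'   (default 0.3).
#' @return A list: `stack` (aligned array with `NA` margins), `shifts`
#'   (tibble `frame`, `dy`, `dx`, `confidence`, `low_confidence`).
#' @export
align_stack <- function(stack, reference = 1, radius = 10, min_confidence = 0.3) {
  d <- dim(stack)
  if (length(d) != 3 || d[1] < 2) abort("stack must be [frame, y, x] with >= 2 frames")
  ref <- stack[reference, , ]
  shifts <- vector("list", d[1])
  out <- stack
  for (f in seq_len(d[1])) {
    if (f == reference) {
      shifts[[f]] <- c(0L, 0L, 1)
      next
    }
    best <- c(0L, 0L, -Inf)
    img <- stack[f, , ]
    for (dy in -radius:radius) {
      for (dx in -radius:radius) {
        r <- shifted_correlation(ref, img, dy, dx)
        if (is.finite(r) && r > best[3]) best <- c(dy, dx, r)
      }
    }
    if (!is.finite(best[3]) || best[3] < min_confidence) {
      shifts[[f]] <- c(0L, 0L, if (is.finite(best[3])) best[3] else 0)
    } else {
      shifts[[f]] <- best
      out[f, , ] <- translate_na(img, best[1], best[2])
    }
  }
  sh <- do.call(rbind, shifts)
  tbl <- tibble::tibble(frame = seq_len(d[1]), dy = as.integer(sh[, 1]),
                        dx = as.integer(sh[, 2]), confidence = sh[, 3])
  tbl$low_confidence <- tbl$confidence < min_confidence & tbl$frame != reference
  list(stack = out, shifts = tbl)
}

# correlation between ref and img translated by (dy, dx), overlap only
shifted_correlation <- function(ref, img, dy, dx) {
  ny <- nrow(ref); nx <- ncol(ref)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  if (length(ys) < 4 || length(xs) < 4) return(NA_real_)
  a <- ref[ys, xs]
  b <- img[ys - dy, xs - dx]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  stats::cor(as.vector(a), as.vector(b))
}

# translate with NA fill for out-of-frame pixels
translate_na <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(NA_real_, ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  out[ys, xs] <- img[ys - dy, xs - dx]
  out
}

#' Background-subtract, denoise and bin a stack
#'
#' The initial frame is subtracted as the static background, a temporal
#' rolling median (window shrinking symmetrically at the edges) removes
#' impulsive noise per pixel, and the result is spatially binned by averaging
#' `bin_factor x bin_factor` blocks (mean, not sum, so intensities stay on
#' the calibration scale). Trailing rows/columns that do not fill a block are
#' cropped.
#'
#' @param stack 3D numeric array `[frame, y, x]`.
#' @param median_window Odd temporal window in frames (default 5).
#' @param bin_factor Spatial binning factor in pixels (default 5).
#' @param pixel_size Input pixel size in micrometres (default 1).
#' @return A list: `stack` (binned array), `pixel_size` (scaled).
#' @export
denoise_and_bin <- function(stack, median_window = 5, bin_factor = 5,
                            pixel_size = 1) {
  d <- dim(stack)
  if (length(d) != 3) abort("stack must be [frame, y, x]")
  if (median_window %% 2 != 1) abort("median_window must be odd")
  if (median_window > d[1]) abort("median window exceeds frame count")
  nt <- d[1]
  # initial background
  bg <- stack[1, , ]
  for (f in seq_len(nt)) stack[f, , ] <- stack[f, , ] - bg
  # temporal rolling median per pixel (shrinking window at edges)
  flat <- matrix(stack, nrow = nt)  # frames x pixels
  half <- (median_window - 1) / 2
  sm <- flat
  if (half > 0) {
    for (f in seq_len(nt)) {
      h <- min(half, f - 1, nt - f)
      if (h == 0) next
      win <- flat[(f - h):(f + h), , drop = FALSE]
      sm[f, ] <- apply(win, 2, median)
    }
  }
  stack <- array(sm, dim = d)
  # spatial mean binning
  ny <- (d[2] %/% bin_factor) * bin_factor
  nx <- (d[3] %/% bin_factor) * bin_factor
  nyb <- ny %/% bin_factor
  nxb <- nx %/% bin_factor
  out <- array(0, dim = c(nt, nyb, nxb))
  for (f in seq_len(nt)) {
    img <- stack[f, seq_len(ny), seq_len(nx)]
    dim(img) <- c(bin_factor, nyb, bin_factor, nxb)
    out[f, , ] <- apply(img, c(2, 4), mean)
  }
  list(stack = out, pixel_size = pixel_size * bin_factor)
}

#' Illumination-drift coefficients from empty wells
#'
#' Empty wells (no cell at any frame) report the local illumination and
#' background level. Their mean intensity is summarized per stratum --
#' field-of-view quadrant x chamber x frame (x channel) -- and divided by
#' the grand mean over all empty wells and frames of that channel, giving a
#' multiplicative coefficient per stratum. Dividing every well's intensity by
#' its stratum coefficient removes the spatial/temporal illumination drift.
#' A stratum with no empty wells falls back to the chamber-level coefficient
#' with a warning.
#'
#' @param wells Tidy well table with columns `well_id`, `chamber`,
#'   `quadrant`, `frame`, `channel`, `mean_intensity`, `cell_count`.
#' @return A tibble `channel`, `quadrant`, `chamber`, `frame`, `coefficient`.
#' @export
empty_well_coefficients <- function(wells) {
  need <- c("well_id", "chamber", "quadrant", "frame", "channel",
            "mean_intensity", "cell_count")
  stopifnot(all(need %in% names(wells)))
  empties <- wells |>
    dplyr::group_by(.data$well_id) |>
    dplyr::filter(all(.data$cell_count == 0)) |>
    dplyr::ungroup()
  if (!nrow(empties)) abort("no empty wells available for normalization")
  grand <- empties |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(grand_mean = mean(.data$mean_intensity), .groups = "drop")
  strat <- empties |>
    dplyr::group_by(.data$channel, .data$quadrant, .data$chamber, .data$frame) |>
    dplyr::summarise(stratum_mean = mean(.data$mean_intensity), .groups = "drop")
  # full grid: strata never seen in the empty set fall back to chamber level
  grid <- wells |>
    dplyr::distinct(.data$channel, .data$quadrant, .data$chamber, .data$frame)
  chamber_level <- empties |>
    dplyr::group_by(.data$channel, .data$chamber, .data$frame) |>
    dplyr::summarise(chamber_mean = mean(.data$mean_intensity), .groups = "drop")
  out <- grid |>
    dplyr::left_join(strat, by = c("channel", "quadrant", "chamber", "frame")) |>
    dplyr::left_join(chamber_level, by = c("channel", "chamber", "frame")) |>
    dplyr::left_join(grand, by = "channel")
  if (anyNA(out$stratum_mean)) {
    warn(sprintf("%d strata had no empty wells; using chamber-level coefficients",
                 sum(is.na(out$stratum_mean))))
  }
  out |>
    dplyr::mutate(coefficient = dplyr::coalesce(.data$stratum_mean,
                                                .data$chamber_mean) /
                                .data$grand_mean) |>
    dplyr::select("channel", "quadrant", "chamber", "frame", "coefficient")
}

#' Apply drift coefficients to a well table
#'
#' @param wells Tidy well table (see [empty_well_coefficients()]).
#' @param coefficients Coefficient table from [empty_well_coefficients()].
#' @return The well table with `mean_intensity` divided by the stratum
#'   coefficient.
#' @export
apply_coefficients <- function(wells, coefficients) {
  wells |>
    dplyr::left_join(coefficients,
                     by = c("channel", "quadrant", "chamber", "frame")) |>
    dplyr::mutate(mean_intensity = .data$mean_intensity / .data$coefficient) |>
    dplyr::select(-"coefficient")
}

#' Subtract per-well baselines to form cumulative secretion signals
#'
#' For each well and channel the default baseline is the well's own initial
#' intensity, removing static autofluorescence. Wells whose initial intensity
#' is an outlier above `Q3 + iqr_mult x IQR` of the population of initial
#' intensities (infrequent autofluorescent contaminants, well-wall signal)
#' instead have the per-frame mean empty-well intensity subtracted. The
#' result is the cumulative secretion signal (CSS) trace.
#'
#' @param wells Drift-corrected well table (see [apply_coefficients()]).
#' @param iqr_mult Outlier multiplier on the interquartile range (default 1.5).
#' @return Tibble `well_id`, `chamber`, `quadrant`, `channel`, `frame`,
#'   `time` (if present), `css`, `cell_count`, `baseline_mode`
#'   (`"initial"` or `"empty_mean"`).
#' @export
subtract_baseline <- function(wells, iqr_mult = 1.5) {
  first_frame <- min(wells$frame)
  initials <- wells |>
    dplyr::filter(.data$frame == first_frame) |>
    dplyr::select("well_id", "channel", initial = "mean_intensity")
  cutoffs <- initials |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      cutoff = unname(quantile(.data$initial, 0.75)) +
               iqr_mult * stats::IQR(.data$initial),
      .groups = "drop"
    )
  empty_trace <- wells |>
    dplyr::group_by(.data$well_id) |>
    dplyr::filter(all(.data$cell_count == 0)) |>
    dplyr::group_by(.data$channel, .data$frame) |>
    dplyr::summarise(empty_mean = mean(.data$mean_intensity), .groups = "drop")
  out <- wells |>
    dplyr::left_join(initials, by = c("well_id", "channel")) |>
    dplyr::left_join(cutoffs, by = "channel") |>
    dplyr::left_join(empty_trace, by = c("channel", "frame")) |>
    dplyr::mutate(
      baseline_mode = ifelse(.data$initial > .data$cutoff, "empty_mean", "initial"),
      css = ifelse(.data$baseline_mode == "empty_mean",
                   .data$mean_intensity - .data$empty_mean,
                   .data$mean_intensity - .data$initial)
    )
  keep <- intersect(c("well_id", "chamber", "quadrant", "channel", "frame",
                      "time", "css", "cell_count", "baseline_mode"),
                    names(out))
  dplyr::select(out, dplyr::all_of(keep))
}

#' Read / write a tidy well table
#'
#' Standard per-well CSV: columns `well_id`, `chamber`, `quadrant`, `frame`,
#' `time`, `channel`, `mean_intensity`, `cell_count`.
#'
#' @param path File path.
#' @param wells Well table to write.
#' @return `read_well_table()` returns a tibble.
#' @export
read_well_table <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_well_table
#' @export
write_well_table <- function(wells, path) {
  write.csv(wells, path, row.names = FALSE)
  invisible(path)
}

#' Read / write an image stack as TIFF
#'
#' Thin wrappers over the tiff package storing a `[frame, y, x]` array as a
#' multi-page 32-bit float TIFF.
#'
#' @param path File path.
#' @param stack 3D numeric array `[frame, y, x]`.
#' @param scale Intensities are divided by `scale` on write and multiplied
#'   back on read (TIFF float pages are stored in `[0, 1]`).
#' @return `read_stack_tiff()` returns the array.
#' @export
read_stack_tiff <- function(path, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) abort("package 'tiff' required")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) arr[f, , ] <- pages[[f]] * scale
  arr
}

#' @rdname read_stack_tiff
#' @export
write_stack_tiff <- function(stack, path, scale = max(abs(stack), 1)) {
  if (!requireNamespace("tiff", quietly = TRUE)) abort("package 'tiff' required")
  pages <- lapply(seq_len(dim(stack)[1]),
                  function(f) pmin(pmax(stack[f, , ] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  invisible(path)
}
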