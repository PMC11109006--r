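#' Nanoliter-well dish layout
#'
#' Deterministic well grid for a multi-chamber TIRF dish. Each chamber holds
#' `wells_per_chamber` cubic wells (80 um side, 115 um centre-to-centre
#' pitch by default) filled row-major on a near-square grid; each well is
#' assigned to a field-of-view quadrant (upper/lower x left/right) by its
#' position within the chamber.
#'
#' @param chambers Number of chambers (default 4).
#' @param wells_per_chamber Wells per chamber (default 996).
#' @param well_um Well side length, micrometres (default 80).
#' @param pitch_um Centre-to-centre pitch, micrometres (default 115); must
#'   exceed the well side.
#' @return Tibble `well_id`, `chamber`, `row`, `col`, `x_um`, `y_um`,
#'   `quadrant`.
#' @examples
#' nrow(make_dish_layout()) # 3984 wells
#' @export
make_dish_layout <- function(chambers = 4, wells_per_chamber = 996,
                             well_um = 80, pitch_um = 115) {
  if (pitch_um <= well_um) abort("pitch must exceed the well side length")
  if (chambers < 1 || wells_per_chamber < 1) abort("invalid layout dimensions")
  ncol_grid <- ceiling(sqrt(wells_per_chamber))
  nrow_grid <- ceiling(wells_per_chamber / ncol_grid)
  per_chamber <- purrr::map_dfr(seq_len(chambers), function(ch) {
    idx <- seq_len(wells_per_chamber)
    row <- (idx - 1) %/% ncol_grid + 1
    col <- (idx - 1) %% ncol_grid + 1
    tibble::tibble(
      well_id = sprintf("c%d_w%04d", ch, idx),
      chamber = ch,
      row = row,
      col = col,
      x_um = (col - 1) * pitch_um,
      y_um = (row - 1) * pitch_um,
      quadrant = paste0(
        ifelse(row <= nrow_grid / 2, "upper_", "lower_"),
        ifelse(col <= ncol_grid / 2, "left", "right")
      )
    )
  })
  per_chamber
}

#' Specification of a synthetic secretion population
#'
#' Defines the study conditions the generator emulates: the mix of secretory
#' phenotypes, their onset-time distribution, release scales and durations,
#' acquisition cadence and noise/drift levels.
#'
#' Defaults: onsets are log-normal over roughly 1-12 h after stimulation;
#' slightly active cells release transiently and cease within 10-30 h while
#' hyperactive cells sustain release to the horizon; class signal scales are
#' 0x / 10x / 100x the empty-well noise SD; about a quarter of wells are
#' empty and roughly two thirds of occupied wells are active.
#'
#' @param fractions Named class fractions
#'   (`silent`, `slightly_active`, `hyperactive`), summing to 1.
#' @param empty_fraction Fraction of wells left empty (no cell).
#' @param onset_meanlog,onset_sdlog Log-normal onset-time parameters (hours);
#'   draws are truncated to `onset_range`.
#' @param onset_range Truncation range for onsets, hours.
#' @param slight_duration Range of active duration for slightly active
#'   cells, hours.
#' @param css_scales Named per-class plateau CSS, in multiples of the
#'   empty-well robust SD.
#' @param burst_fraction Fraction of a cell's total release emitted as an
#'   onset burst (the remainder is spread over the active window); bursts
#'   make onsets sharp at the acquisition cadence.
#' @param noise_sd Additive Gaussian detection noise SD, intensity units.
#' @param baseline_mean Static per-well background intensity.
#' @param outlier_fraction Fraction of occupied wells given an
#'   autofluorescent baseline outlier.
#' @param outlier_mult Baseline multiplier for outlier wells.
#' @param drift_range Range of the multiplicative illumination drift drawn
#'   independently per (quadrant, chamber, frame).
#' @param frame_interval Acquisition interval, hours.
#' @param horizon Observation horizon, hours.
#' @param channels Channel labels to simulate.
#' @param crosstalk Logical: add the IL-13-channel cross-signal from IL-5
#'   release (requires both `"IL5"` and `"IL13"` channels).
#' @param seed Integer seed fixing all randomness.
#' @return A `population_spec` list.
#' @export
population_spec <- function(fractions = c(silent = 0.33, slightly_active = 0.50,
                                          hyperactive = 0.17),
                            empty_fraction = 0.25,
                            onset_meanlog = log(4), onset_sdlog = 0.5,
                            onset_range = c(1, 12),
                            slight_duration = c(10, 30),
                            css_scales = c(silent = 0, slightly_active = 10,
                                           hyperactive = 100),
                            burst_fraction = 0.5,
                            noise_sd = 1,
                            baseline_mean = 100,
                            outlier_fraction = 0,
                            outlier_mult = 5,
                            drift_range = c(0.7, 1.4),
                            frame_interval = 1,
                            horizon = 72,
                            channels = "IL5",
                            crosstalk = FALSE,
                            seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) abort("class fractions must sum to 1")
  if (any(fractions < 0)) abort("class fractions must be non-negative")
  if (any(css_scales < 0)) abort("signal scales must be >= 0")
  structure(as.list(environment()), class = "population_spec")
}

#' Simulate a heterogeneous secretion population
#'
#' Draws a ground-truth table for every well of a layout: occupancy, class,
#' onset, and the per-bin release train per channel. Silent cells release
#' nothing; slightly active cells emit an onset burst plus a transient tail
#' that ceases within their duration window; hyperactive cells sustain
#' release to the horizon at a ten-fold larger scale. Release amounts are
#' expressed in multiples of the empty-well noise SD of the rendered
#' observations, so downstream thresholds (3x, 50x robust SD) have a known
#' relation to the truth.
#'
#' @param layout Well table from [make_dish_layout()].
#' @param spec A [population_spec()].
#' @return A list with `wells` (tibble `well_id`, `occupied`, `class`,
#'   `onset_time`) and `release` (tibble `well_id`, `channel`, `bin`, `time`,
#'   `release`; active wells only, zero bins omitted). Fully deterministic
#'   under `spec$seed`.
#' @export
simulate_population <- function(layout, spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- nrow(layout)
  nbins <- floor(spec$horizon / spec$frame_interval)
  occupied <- runif(n) >= spec$empty_fraction
  classes <- rep("empty", n)
  classes[occupied] <- sample(names(spec$fractions), sum(occupied),
                              replace = TRUE, prob = spec$fractions)
  onset <- rep(NA_real_, n)
  active <- classes %in% c("slightly_active", "hyperactive")
  if (any(active)) {
    draw <- rlnorm(sum(active), spec$onset_meanlog, spec$onset_sdlog)
    onset[active] <- pmin(pmax(draw, spec$onset_range[1]), spec$onset_range[2])
  }
  duration <- rep(NA_real_, n)
  duration[classes == "slightly_active"] <-
    runif(sum(classes == "slightly_active"),
          spec$slight_duration[1], spec$slight_duration[2])
  duration[classes == "hyperactive"] <- spec$horizon

  # reference noise scale of the rendered empty-well CSS: baseline subtraction
  # differences two independent noise draws, so its SD is sqrt(2) * noise_sd
  sigma_ref <- sqrt(2) * spec$noise_sd

  release_rows <- purrr::map_dfr(which(active), function(i) {
    scale <- spec$css_scales[[classes[i]]] * sigma_ref
    onset_bin <- max(1L, min(nbins, as.integer(round(onset[i] / spec$frame_interval))))
    end_bin <- min(nbins, as.integer(ceiling((onset[i] + duration[i]) / spec$frame_interval)))
    train <- numeric(nbins)
    train[onset_bin] <- spec$burst_fraction * scale
    tail_bins <- seq.int(min(onset_bin + 1L, end_bin), end_bin)
    train[tail_bins] <- train[tail_bins] +
      (1 - spec$burst_fraction) * scale / length(tail_bins)
    nz <- which(train > 0)
    purrr::map_dfr(spec$channels, function(ch) {
      tibble::tibble(well_id = layout$well_id[i], channel = ch,
                     bin = nz, time = nz * spec$frame_interval,
                     release = train[nz])
    })
  })
  if (!nrow(release_rows)) {
    release_rows <- tibble::tibble(well_id = character(), channel = character(),
                                   bin = integer(), time = numeric(),
                                   release = numeric())
  }
  list(
    wells = tibble::tibble(well_id = layout$well_id, occupied = occupied,
                           class = classes, onset_time = onset),
    release = release_rows
  )
}

#' Render observed well traces from a ground truth
#'
#' Forward model for the whole measurement: each well's release train is
#' convolved with the channel's staining kinetics to its cumulative secretion
#' signal, the IL-13 channel optionally receives the cross-signal from the
#' well's IL-5 release, a static per-well baseline and a multiplicative
#' illumination drift per (quadrant, chamber, frame) are applied, and
#' additive Gaussian detection noise is drawn. Empty wells carry baseline,
#' drift and noise only, so the preprocessing chain can estimate and remove
#' exactly what was imposed.
#'
#' @param truth Output of [simulate_population()].
#' @param layout The layout used to generate `truth`.
#' @param kinetics Named list of [ab_kinetics] per channel; time units must
#'   be hours (the generator's clock).
#' @param spec The same [population_spec()].
#' @param crosstalk_kernel_obj Optional [crosstalk_kernel] used when
#'   `spec$crosstalk` is `TRUE`.
#' @return A tidy well table (`well_id`, `chamber`, `quadrant`, `frame`,
#'   `time`, `channel`, `mean_intensity`, `cell_count`) ready for
#'   [empty_well_coefficients()]. Attributes: `drift` (the imposed drift
#'   field), `true_css` (noise- and drift-free CSS per well/channel/frame).
#' @export
render_observations <- function(truth, layout, kinetics, spec,
                                crosstalk_kernel_obj = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  missing_k <- setdiff(spec$channels, names(kinetics))
  if (length(missing_k)) {
    abort(sprintf("no kinetics for channel(s): %s", paste(missing_k, collapse = ", ")))
  }
  for (ch in spec$channels) {
    if (kinetics[[ch]]$time_unit != "h") {
      abort("generator clock is hours; kinetics must use time_unit = 'h'")
    }
  }
  set.seed(spec$seed + 1L)
  nbins <- floor(spec$horizon / spec$frame_interval)
  frames <- 0:nbins
  n <- nrow(layout)

  # per-well release matrices -> true CSS per channel
  css_list <- list()
  il5_dss <- list()
  for (ch in spec$channels) {
    rel <- dplyr::filter(truth$release, .data$channel == ch)
    css_mat <- matrix(0, n, nbins + 1)
    rel_by_well <- split(rel, rel$well_id)
    for (wid in names(rel_by_well)) {
      i <- match(wid, layout$well_id)
      train <- numeric(nbins)
      train[rel_by_well[[wid]]$bin] <- rel_by_well[[wid]]$release
      css_mat[i, -1] <- forward_convolve(train, kinetics[[ch]],
                                         dt_time = spec$frame_interval)
      if (ch == "IL5") il5_dss[[wid]] <- train
    }
    css_list[[ch]] <- css_mat
  }
  if (spec$crosstalk) {
    if (is.null(crosstalk_kernel_obj) || !"IL13" %in% spec$channels) {
      abort("crosstalk requested: supply a crosstalk kernel and an IL13 channel")
    }
    chi <- eval_crosstalk(crosstalk_kernel_obj, (1:nbins) * spec$frame_interval)
    for (wid in names(il5_dss)) {
      i <- match(wid, layout$well_id)
      train <- il5_dss[[wid]]
      X <- numeric(nbins)
      for (k in seq_len(nbins)) X[k] <- sum(train[1:k] * chi[k:1])
      css_list[["IL13"]][i, -1] <- css_list[["IL13"]][i, -1] + X
    }
  }

  # baseline per well (optional autofluorescent outliers among occupied wells)
  baseline <- rep(spec$baseline_mean, n)
  occ_idx <- which(truth$wells$occupied)
  n_out <- round(spec$outlier_fraction * length(occ_idx))
  if (n_out > 0) {
    out_idx <- sample(occ_idx, n_out)
    baseline[out_idx] <- baseline[out_idx] * spec$outlier_mult
  }

  # multiplicative drift per (channel, quadrant, chamber, frame)
  drift <- tidyr::expand_grid(
    channel = spec$channels,
    quadrant = unique(layout$quadrant),
    chamber = unique(layout$chamber),
    frame = frames
  )
  drift$factor <- runif(nrow(drift), spec$drift_range[1], spec$drift_range[2])

  cell_count <- as.integer(truth$wells$occupied)
  obs <- purrr::map_dfr(spec$channels, function(ch) {
    css_mat <- css_list[[ch]]
    tab <- tidyr::expand_grid(idx = seq_len(n), frame = frames)
    tab$well_id <- layout$well_id[tab$idx]
    tab$chamber <- layout$chamber[tab$idx]
    tab$quadrant <- layout$quadrant[tab$idx]
    tab$channel <- ch
    tab$time <- tab$frame * spec$frame_interval
    tab$cell_count <- cell_count[tab$idx]
    tab$true_css <- css_mat[cbind(tab$idx, tab$frame + 1)]
    tab$baseline <- baseline[tab$idx]
    tab
  })
  obs <- obs |>
    dplyr::left_join(drift, by = c("channel", "quadrant", "chamber", "frame")) |>
    dplyr::mutate(
      mean_intensity = .data$factor * (.data$baseline + .data$true_css) +
        rnorm(dplyr::n(), sd = spec$noise_sd)
    )
  out <- obs |>
    dplyr::select("well_id", "chamber", "quadrant", "frame", "time",
                  "channel", "mean_intensity", "cell_count")
  attr(out, "drift") <- drift
  attr(out, "true_css") <- dplyr::select(obs, "well_id", "channel", "frame",
                                         "true_css")
  out
}

#' Simulate a microinjection standard curve
#'
#' Calibration time course produced by an instantaneous release of a known
#' amount `Q` of recombinant protein: `intensity = Q * A(t)` with optional
#' multiplicative Gaussian noise.
#'
#' @param model An [ab_kinetics].
#' @param Q Released amount (signal units).
#' @param times Strictly increasing sample times in the model's unit.
#' @param noise_frac SD of the multiplicative noise (e.g. 0.01 for 1%).
#' @param seed Optional seed.
#' @return A `standard_curve` tibble with columns `time`, `intensity` and
#'   attributes `time_unit`, `release_amount`, `analyte`.
#' @export
simulate_microinjection <- function(model, Q = 1, times, noise_frac = 0,
                                    seed = NULL) {
  stopifnot(inherits(model, "ab_kinetics"))
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  clean <- Q * eval_kinetics(model, times)
  noisy <- clean * (1 + if (noise_frac > 0) rnorm(length(times), sd = noise_frac) else 0)
  out <- tibble::tibble(time = times, intensity = noisy)
  attr(out, "time_unit") <- model$time_unit
  attr(out, "release_amount") <- Q
  attr(out, "analyte") <- model$analyte
  class(out) <- c("standard_curve", class(out))
  out
}

#' Render a secretion spot image or stack
#'
#' Phenomenological image model for the localization module: a 2D Gaussian
#' secretion spot near a (possibly random-walking) cell centroid, plus a
#' constant offset and Gaussian noise. `simulate_spot_image()` renders one
#' frame; `simulate_secretion_stack()` renders a time series together with
#' the ground-truth cell track.
#'
#' @param size `c(ny, nx)` image size in (binned) pixels.
#' @param pixel_size Pixel size, micrometres.
#' @param center `c(x, y)` spot centre, micrometres.
#' @param sigma Spot width (isotropic SD), micrometres.
#' @param height Peak amplitude, signal units.
#' @param offset Constant background.
#' @param noise_sd Additive Gaussian noise SD.
#' @return `simulate_spot_image()`: a matrix. `simulate_secretion_stack()`:
#'   a list with `stack` (`[frame, y, x]`), `track` (tibble `frame`, `x`,
#'   `y`) and `spot_centers`.
#' @export
simulate_spot_image <- function(size = c(16, 16), pixel_size = 5,
                                center = size * pixel_size / 2, sigma = 5,
                                height = 1, offset = 0, noise_sd = 0) {
  ny <- size[1]; nx <- size[2]
  xs <- (seq_len(nx) - 0.5) * pixel_size
  ys <- (seq_len(ny) - 0.5) * pixel_size
  img <- offset + height * outer(ys, xs, function(y, x) {
    exp(-((x - center[1])^2 + (y - center[2])^2) / (2 * sigma^2))
  })
  if (noise_sd > 0) img <- img + matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)
  img
}

#' @rdname simulate_spot_image
#' @param n_frames Number of frames.
#' @param cell_start `c(x, y)` initial cell position, micrometres.
#' @param step_sd Per-frame random-walk step SD of the cell, micrometres.
#' @param spot_offset `c(dx, dy)` displacement of the secretion spot from the
#'   cell, micrometres.
#' @param heights Per-frame spot amplitudes (recycled).
#' @param seed Optional seed.
#' @export
simulate_secretion_stack <- function(n_frames = 10, size = c(16, 16),
                                     pixel_size = 5,
                                     cell_start = size * pixel_size / 2,
                                     step_sd = 1, spot_offset = c(0, 0),
                                     heights = 1, sigma = 5, offset = 0,
                                     noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  heights <- rep_len(heights, n_frames)
  pos <- matrix(0, n_frames, 2)
  pos[1, ] <- cell_start
  if (n_frames > 1) {
    steps <- matrix(rnorm(2 * (n_frames - 1), sd = step_sd), ncol = 2)
    pos[-1, ] <- cell_start + apply(steps, 2, cumsum)
  }
  extent <- rev(size) * pixel_size  # (x, y)
  pos[, 1] <- pmin(pmax(pos[, 1], 2 * pixel_size), extent[1] - 2 * pixel_size)
  pos[, 2] <- pmin(pmax(pos[, 2], 2 * pixel_size), extent[2] - 2 * pixel_size)
  centers <- sweep(pos, 2, spot_offset, `+`)
  stack <- array(0, dim = c(n_frames, size[1], size[2]))
  for (f in seq_len(n_frames)) {
    stack[f, , ] <- simulate_spot_image(size, pixel_size, centers[f, ],
                                        sigma, heights[f], offset, noise_sd)
  }
  list(
    stack = stack,
    track = tibble::tibble(frame = seq_len(n_frames), x = pos[, 1], y = pos[, 2]),
    spot_centers = tibble::tibble(frame = seq_len(n_frames),
                                  x = centers[, 1], y = centers[, 2])
  )
}
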