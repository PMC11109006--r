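# Independent oracles used to cross-check the package implementations.
# These are deliberately written with a different algorithmic structure than
# the functions they validate.

# Positivity/episode oracle over a logical supra-threshold pattern, built on
# rle segments instead of a frame-by-frame state machine: an episode must
# begin with a supra segment of length >= min_run; subsequent supra segments
# of any length are absorbed while the separating sub-threshold segment is
# <= max_gap.
oracle_episodes <- function(supra, min_run = 2, max_gap = 3) {
  if (!length(supra)) return(data.frame(start = integer(), end = integer()))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  eps <- list()
  cur <- NULL
  prev_gap <- Inf
  for (s in seq_along(r$lengths)) {
    if (r$values[s]) {
      if (!is.null(cur) && prev_gap <= max_gap) {
        cur[2] <- ends[s]
      } else {
        if (!is.null(cur)) eps[[length(eps) + 1]] <- cur
        cur <- if (r$lengths[s] >= min_run) c(starts[s], ends[s]) else NULL
      }
    } else {
      prev_gap <- r$lengths[s]
    }
  }
  if (!is.null(cur)) eps[[length(eps) + 1]] <- cur
  if (!length(eps)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, eps)
  data.frame(start = m[, 1], end = m[, 2])
}

# Brute-force forward model: accumulate each release bin's contribution
# outward over all later observation bins (outer loop over sources, not
# observations as in the package implementation).
oracle_forward <- function(dss, A) {
  n <- length(dss)
  css <- numeric(n)
  for (i in seq_len(n)) {
    for (k in i:n) {
      css[k] <- css[k] + dss[i] * A[k - i + 1]
    }
  }
  css
}

# small standard well table used across preprocessing tests
make_test_wells <- function(n_per_stratum = 3, n_frames = 6, chambers = 2,
                            base = 100, channel = "IL5") {
  quadrants <- c("upper_left", "upper_right", "lower_left", "lower_right")
  grid <- expand.grid(q = quadrants, ch = seq_len(chambers),
                      w = seq_len(n_per_stratum), stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    tibble::tibble(
      well_id = sprintf("c%d_%s_w%d", grid$ch[i], grid$q[i], grid$w[i]),
      chamber = grid$ch[i],
      quadrant = grid$q[i],
      frame = 0:(n_frames - 1),
      time = 0:(n_frames - 1),
      channel = channel,
      mean_intensity = base,
      cell_count = ifelse(grid$w[i] == 1, 0L, 1L)  # first well per stratum empty
    )
  })
}
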