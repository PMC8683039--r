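#' @useDynLib ppcons, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic sub-seed derivation: one master seed, per-purpose streams.
# Kept below 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  s <- ((as.double(seed) %% 2147483647) * 48271 + stream * 7919) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Homogeneous Poisson spike trains
#'
#' Generates `n` mutually independent homogeneous Poisson spike trains by
#' drawing exponential inter-spike intervals (exact, no binning).
#'
#' @param n number of afferents.
#' @param rate mean firing rate in spikes/s (>= 0).
#' @param duration train duration in ms.
#' @param seed integer seed.
#' @return a `spike_input_set`: list with `trains` (per-afferent numeric
#'   vectors of spike times in ms, strictly increasing), `n`, `duration`,
#'   and generator metadata.
#' @export
poisson_trains <- function(n, rate, duration, seed = 1) {
  stopifnot(n >= 1, rate >= 0, duration > 0)
  trains <- with_seed(derive_seed(seed, 1L), {
    lapply(seq_len(n), function(i) {
      if (rate == 0) return(numeric(0))
      # expected count + slack; top up if the tail was undershot
      t <- cumsum(stats::rexp(ceiling(rate * duration / 1000 * 1.5) + 25,
                              rate = rate / 1000))
      while (length(t) && t[length(t)] < duration) {
        t <- c(t, t[length(t)] +
                 cumsum(stats::rexp(25, rate = rate / 1000)))
      }
      t[t <= duration]
    })
  })
  structure(list(trains = trains, n = n, duration = duration,
                 meta = list(kind = "poisson", rate = rate, seed = seed)),
            class = "spike_input_set")
}

#' @exportS3Method base::print
print.spike_input_set <- function(x, ...) {
  cat(sprintf("spike input set: %d afferents, %.6g ms, %d spikes (%s)\n",
              x$n, x$duration, sum(lengths(x$trains)),
              x$meta$kind %||% "unknown"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Delayed copy of a spike input set
#'
#' Shifts every spike time by `+delay` ms, preserving afferent identity
#' and spike counts.  Models a multisynaptic pathway carrying the same
#' activity with a fixed transmission delay.
#'
#' @param x a `spike_input_set`.
#' @param delay delay in ms (>= 0).
#' @export
delayed_copy <- function(x, delay) {
  stopifnot(inherits(x, "spike_input_set"), delay >= 0)
  x$trains <- lapply(x$trains, function(t) t + delay)
  x$duration <- x$duration + delay
  x$meta$delay <- (x$meta$delay %||% 0) + delay
  x
}

#' Spatial tuning of afferents on a linear track
#'
#' Builds the afferent population of the spatial-replay experiment:
#' `n_grid` grid-like afferents with periodic fields
#' \eqn{G_i(x) = r\,H(\cos(2\pi k_i x + \xi_i))} whose periodicity spans
#' 2 to 6 fields along the track with uniform random phases, and
#' `n_place` place afferents with single fields of width `field_width`
#' whose centers are uniform random, each field lying fully on the track.
#' Afferents fire as independent Poisson processes at `rate` inside their
#' fields and are silent outside.
#'
#' @param track_length track length in m (default 2.5).
#' @param n_grid,n_place afferent counts.
#' @param rate in-field rate, spikes/s.
#' @param field_width place-field length in m (default 0.25).
#' @param seed integer seed.
#' @return object of class `track_tuning`.
#' @export
track_tuning <- function(track_length = 2.5, n_grid = 500, n_place = 2500,
                         rate = 10, field_width = 0.25, seed = 1) {
  stopifnot(track_length > 0, field_width < track_length)
  with_seed(derive_seed(seed, 2L), {
    periods <- stats::runif(n_grid, 2, 6)       # fields along the track
    phases <- stats::runif(n_grid, 0, 2 * pi)
    centers <- stats::runif(n_place, field_width / 2,
                            track_length - field_width / 2)
  })
  structure(list(track_length = track_length, rate = rate,
                 field_width = field_width,
                 n_grid = n_grid, periods = periods, phases = phases,
                 n_place = n_place, centers = centers, seed = seed),
            class = "track_tuning")
}

#' Evaluate grid-afferent tuning curves
#'
#' @param tuning a [track_tuning()].
#' @param x positions in m (vector).
#' @param which_grid indices of grid afferents (default all).
#' @return matrix `length(x) x length(which_grid)` of rates.
#' @export
grid_tuning_curve <- function(tuning, x, which_grid = seq_len(tuning$n_grid)) {
  sapply(which_grid, function(i) {
    tuning$rate * (cos(2 * pi * tuning$periods[i] * x /
                         tuning$track_length + tuning$phases[i]) >= 0)
  })
}

place_field_active <- function(tuning, x) {
  # logical matrix length(x) x n_place
  outer(x, tuning$centers, function(p, c) abs(p - c) <= tuning$field_width / 2)
}

#' Theory reference tuning for the replay experiment
#'
#' Sums the tuning functions of every grid afferent whose field is active
#' at the target position, normalized to unit peak.  This is the best
#' constructive superposition the direct pathway can reach and serves as
#' the reference for tuning-correlation readouts.
#'
#' @param tuning a [track_tuning()].
#' @param target_position position on the track in m.
#' @param x evaluation grid (default 512 points spanning the track).
#' @return data.frame with columns `x`, `tuning`.
#' @export
theory_tuning <- function(tuning, target_position,
                          x = seq(0, tuning$track_length,
                                  length.out = 512)) {
  stopifnot(target_position >= 0, target_position <= tuning$track_length)
  at_target <- drop(grid_tuning_curve(tuning, target_position)) > 0
  if (!any(at_target))
    stop("no grid afferent has an active field at the target position")
  curve <- rowSums(grid_tuning_curve(tuning, x, which(at_target)))
  data.frame(x = x, tuning = curve / max(curve))
}

# Positions for an alternating back-and-forth sweep: x(t) piecewise linear.
# Returns, for one afferent's set of active x-intervals, the active time
# intervals over n_passes passes at the given speed.
sweep_time_intervals <- function(x_intervals, track_length, speed, n_passes) {
  pass_dur <- track_length / speed
  out <- vector("list", n_passes)
  for (p in seq_len(n_passes)) {
    forward <- (p %% 2L) == 1L
    t0 <- (p - 1) * pass_dur
    if (nrow(x_intervals) == 0L) { out[[p]] <- x_intervals; next }
    if (forward) {
      lo <- t0 + x_intervals[, 1] / speed
      hi <- t0 + x_intervals[, 2] / speed
    } else {
      lo <- t0 + (track_length - x_intervals[, 2]) / speed
      hi <- t0 + (track_length - x_intervals[, 1]) / speed
    }
    out[[p]] <- cbind(lo, hi)
  }
  do.call(rbind, out)
}

grid_field_intervals <- function(tuning, i) {
  # x-intervals (m) where cos(2 pi k x / L + xi) >= 0, intersected with track
  L <- tuning$track_length
  k <- tuning$periods[i] / L                 # cycles per m
  xi <- tuning$phases[i]
  # cos(theta) >= 0 on [-pi/2 + 2 pi m, pi/2 + 2 pi m]
  m_lo <- ceiling((2 * pi * k * 0 + xi - pi / 2) / (2 * pi)) - 2
  m_hi <- floor((2 * pi * k * L + xi + pi / 2) / (2 * pi)) + 2
  lo <- ((-pi / 2 + 2 * pi * (m_lo:m_hi)) - xi) / (2 * pi * k)
  hi <- ((pi / 2 + 2 * pi * (m_lo:m_hi)) - xi) / (2 * pi * k)
  keep <- hi > 0 & lo < L
  cbind(pmax(lo[keep], 0), pmin(hi[keep], L))
}

#' Track-replay session: spike trains from a simulated sweep
#'
#' A virtual animal sweeps the linear track back and forth at
#' `0.25 * speed_factor` m/s.  Each afferent fires as a homogeneous
#' Poisson process at the in-field rate while the animal is inside one of
#' its fields and is silent otherwise.  The place pathway is returned as
#' a delayed copy convention-wise: its spikes are shifted by `place_delay`
#' ms relative to the grid pathway, modelling the extra synaptic stages of
#' the indirect route.
#'
#' @param tuning a [track_tuning()].
#' @param speed_factor multiple of the 0.25 m/s base speed (20 for replay).
#' @param n_passes number of single-direction traversals (alternating).
#' @param seed integer seed.
#' @param place_delay delay of the place pathway in ms (default 5).
#' @return list with `grid` and `place` spike input sets (times in ms),
#'   `duration` (ms), `speed` (m/s) and the tuning used.
#' @export
track_replay_session <- function(tuning, speed_factor = 20, n_passes = 10,
                                 seed = 1, place_delay = 5) {
  stopifnot(inherits(tuning, "track_tuning"), speed_factor > 0, n_passes >= 1)
  speed <- 0.25 * speed_factor
  pass_dur <- tuning$track_length / speed      # seconds
  duration_ms <- n_passes * pass_dur * 1000
  rate_ms <- tuning$rate / 1000

  draw_on_intervals <- function(iv_s) {
    if (is.null(iv_s) || nrow(iv_s) == 0L) return(numeric(0))
    ts <- lapply(seq_len(nrow(iv_s)), function(r) {
      len_ms <- (iv_s[r, 2] - iv_s[r, 1]) * 1000
      k <- stats::rpois(1, rate_ms * len_ms)
      if (k == 0) return(numeric(0))
      sort(stats::runif(k, iv_s[r, 1] * 1000, iv_s[r, 2] * 1000))
    })
    sort(unlist(ts))
  }

  with_seed(derive_seed(seed, 3L), {
    grid_trains <- lapply(seq_len(tuning$n_grid), function(i) {
      iv_x <- grid_field_intervals(tuning, i)
      draw_on_intervals(sweep_time_intervals(iv_x, tuning$track_length,
                                             speed, n_passes))
    })
    place_trains <- lapply(seq_len(tuning$n_place), function(i) {
      iv_x <- cbind(tuning$centers[i] - tuning$field_width / 2,
                    tuning$centers[i] + tuning$field_width / 2)
      draw_on_intervals(sweep_time_intervals(iv_x, tuning$track_length,
                                             speed, n_passes))
    })
  })
  grid <- structure(list(trains = grid_trains, n = tuning$n_grid,
                         duration = duration_ms,
                         meta = list(kind = "track-replay-grid", seed = seed,
                                     speed = speed)),
                    class = "spike_input_set")
  place <- structure(list(trains = place_trains, n = tuning$n_place,
                          duration = duration_ms,
                          meta = list(kind = "track-replay-place",
                                      seed = seed, speed = speed)),
                     class = "spike_input_set")
  list(grid = grid, place = delayed_copy(place, place_delay),
       duration = duration_ms + place_delay, speed = speed, tuning = tuning)
}

#' Random row-normalized binary memory matrix
#'
#' Entries are Bernoulli(1/2) draws; each row is rescaled to sum to 1
#' (L1 row normalization).  All-zero rows are redrawn, since the
#' normalization is undefined there.
#'
#' @param N matrix dimension (>= 2).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return `N x N` matrix with unit row sums.
#' @export
random_memory_matrix <- function(N, seed = NULL) {
  stopifnot(N >= 2)
  draw <- function() {
    m <- matrix(stats::rbinom(N * N, 1, 0.5), N, N)
    bad <- rowSums(m) == 0
    while (any(bad)) {
      m[bad, ] <- stats::rbinom(sum(bad) * N, 1, 0.5)
      bad <- rowSums(m) == 0
    }
    m / rowSums(m)
  }
  if (is.null(seed)) draw() else with_seed(derive_seed(seed, 4L), draw())
}

#' Uniform random 2-D positions in the unit square
#'
#' @param n number of positions.
#' @param seed integer seed.
#' @return `n x 2` matrix.
#' @export
sample_positions_2d <- function(n, seed = 1) {
  with_seed(derive_seed(seed, 5L), matrix(stats::runif(2 * n), n, 2))
}

#' Write / read spike trains as two-column CSV
#'
#' Columns: `afferent` (1-based id), `time_ms`.
#'
#' @param x a `spike_input_set`.
#' @param path file path.
#' @export
write_spike_csv <- function(x, path) {
  stopifnot(inherits(x, "spike_input_set"))
  df <- data.frame(
    afferent = rep.int(seq_along(x$trains), lengths(x$trains)),
    time_ms = unlist(x$trains) %||% numeric(0)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @param n number of afferents (defaults to the largest id present).
#' @param duration horizon in ms (defaults to the last spike time).
#' @export
read_spike_csv <- function(path, n = NULL, duration = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("afferent", "time_ms") %in% names(df)))
  if (is.null(n)) n <- max(df$afferent, 1L)
  trains <- lapply(seq_len(n),
                   function(i) sort(df$time_ms[df$afferent == i]))
  structure(list(trains = trains, n = n,
                 duration = duration %||% max(c(df$time_ms, 0)),
                 meta = list(kind = "csv", path = path)),
            class = "spike_input_set")
}
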