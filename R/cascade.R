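#' Configuration of the hierarchical neocortical cascade
#'
#' A single hippocampal (HPC) weight matrix surrounded by `L` neocortical
#' shortcut matrices whose STDP amplitudes shrink geometrically with the
#' level index (`A_i = 0.4 w_max q^{i-1}`, `q = 0.5`).  The `"paper"`
#' profile is the published 1000-cycle, N = 256, L = 8 world; the
#' `"test"` profile is the desk-scale world (N = 64, L = 5, 15 s nights,
#' 200 cycles, 50 equilibration cycles).  STDP amplitudes keep their
#' published values in both profiles; a shorter night transfers
#' proportionally less per cycle.
#'
#' @param profile `"test"` or `"paper"`.
#' @param ... field overrides.
#' @export
cascade_config <- function(profile = c("test", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- list(N_cycle = 1000, T_c = 150, dT = 0.005, N = 256, L = 8,
              r = 10, D = 0.005, lambda = 0.5, q = 0.5,
              tau_stdp = 0.020, N_equi = 1000)
  if (profile == "test") {
    cfg$N <- 64; cfg$L <- 5; cfg$T_c <- 15
    cfg$N_equi <- 50; cfg$N_cycle <- 200
  }
  cfg <- utils::modifyList(cfg, list(...))
  cfg$w_max <- 2 / cfg$N
  # published amplitudes at every scale: the per-step weight kick is
  # dT * A * (activity)^2 ~ 0.25 * w_max * q^(i-1) already, so raising A
  # to compensate for shorter nights rails the bounds and replaces the
  # memory signal with churn (shorter nights simply transfer less)
  cfg$a_plus <- 0.4 * cfg$w_max * cfg$q^(seq_len(cfg$L) - 1)
  cfg$a_minus <- -1.00008 * cfg$a_plus
  cfg$profile <- profile
  structure(cfg, class = "cascade_config")
}

#' Rectified-Gaussian input sample
#'
#' Activity of the outermost neocortical population: Gaussian with mean
#' `r` and standard deviation `r/2`, rectified at zero.
#'
#' @param N number of neurons.
#' @param r mean rate (spikes/s).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @export
sample_input <- function(N, r, seed = NULL) {
  draw <- function() pmax(stats::rnorm(N, mean = r, sd = r / 2), 0)
  if (is.null(seed)) draw() else with_seed(derive_seed(seed, 61L), draw())
}

#' Initial cascade state
#'
#' @param config a [cascade_config()].
#' @param seed integer seed.
#' @return object of class `cascade_state`: row-normalized random binary
#'   `V_hpc` and `L` shortcut matrices uniform in `[0, w_max]`.
#' @export
cascade_state <- function(config, seed = 1) {
  V_hpc <- random_memory_matrix(config$N, seed = derive_seed(seed, 62L))
  W <- with_seed(derive_seed(seed, 63L),
                 lapply(seq_len(config$L), function(i)
                   matrix(stats::runif(config$N^2, 0, config$w_max),
                          config$N, config$N)))
  structure(list(config = config, V_hpc = V_hpc, W = W),
            class = "cascade_state")
}

#' Propagate one input through the cascade (steady activities)
#'
#' Reference implementation of the layered activity equations with all
#' delays unrolled (each connection delays by one step; for a constant
#' input the delayed activities equal the steady-state ones):
#' `y_HPC = V_hpc' x_1`, `y_1 = 1/2 W_1' x_1 + 1/2 y_HPC`,
#' `y_i = 1/2 W_i' x_i + 1/2 y_{i-1}`, with `x_i = x_{i+1}` delayed.
#'
#' @param state a [cascade_state()].
#' @param x_L input activity at the outermost layer.
#' @return list with `x` (N x L matrix of inward activities), `y_hpc`,
#'   and `y` (N x L matrix of outward activities).
#' @export
propagate <- function(state, x_L) {
  L <- state$config$L; N <- state$config$N
  stopifnot(length(x_L) == N)
  x <- matrix(rep(x_L, L), N, L)   # identical copies, delayed in time
  y <- matrix(0, N, L)
  y_hpc <- drop(t(state$V_hpc) %*% x[, 1])
  y[, 1] <- 0.5 * drop(t(state$W[[1]]) %*% x[, 1]) + 0.5 * y_hpc
  if (L > 1) for (i in 2:L)
    y[, i] <- 0.5 * drop(t(state$W[[i]]) %*% x[, i]) + 0.5 * y[, i - 1]
  list(x = x, y_hpc = y_hpc, y = y)
}

#' Imprint a new memory into the HPC matrix
#'
#' `V_hpc <- rownorm(V_hpc + lambda * rownorm(B(1, 0.5)) / (1 - lambda))`
#' where `rownorm` rescales each row to unit sum.
#'
#' @param state a [cascade_state()].
#' @param lambda memory strength in (0, 1).
#' @param seed integer seed (or `NULL` for current RNG state).
#' @param pattern optional explicit pattern matrix (row-normalized
#'   binary); drawn randomly when `NULL`.
#' @return list with the updated `state` and the imprinted `pattern`.
#' @export
imprint_hpc <- function(state, lambda = state$config$lambda, seed = NULL,
                        pattern = NULL) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie strictly in (0, 1)")
  if (is.null(pattern))
    pattern <- random_memory_matrix(state$config$N, seed = seed)
  mixed <- state$V_hpc + lambda * pattern / (1 - lambda)
  state$V_hpc <- mixed / rowSums(mixed)
  list(state = state, pattern = pattern)
}

#' One night of cascade consolidation
#'
#' `T_c / dT` steps of fresh rectified-Gaussian input, delayed
#' propagation, and trace-based STDP on every shortcut matrix with
#' level-dependent amplitudes, clipped to `[0, w_max]`.
#'
#' @param state a [cascade_state()].
#' @param seed integer seed.
#' @param T_c night length in s (default from config).
#' @export
consolidate_night <- function(state, seed = 1, T_c = state$config$T_c) {
  cfg <- state$config
  n_steps <- round(T_c / cfg$dT)
  res <- with_seed(derive_seed(seed, 64L),
    cpp_cascade_night(state$V_hpc, state$W, cfg$a_plus, cfg$a_minus,
                      cfg$tau_stdp, cfg$dT, n_steps, cfg$r, cfg$w_max))
  state$W <- res$W
  state
}

#' Pearson correlation between a reference memory and a weight matrix
#'
#' Computed over all `N^2` entries; zero-variance inputs give 0 with a
#' warning.
#'
#' @param V_ref reference memory matrix.
#' @param W_i weight matrix of the same shape.
#' @export
memory_correlation <- function(V_ref, W_i) {
  stopifnot(all(dim(V_ref) == dim(W_i)))
  pearson(as.vector(V_ref), as.vector(W_i))
}

#' Monte-Carlo noise floor of the memory-correlation readout
#'
#' Standard deviation of the Pearson correlation between two independent
#' row-normalized binary matrices; approximately `1/N`.
#'
#' @param N matrix dimension.
#' @param n_draws number of matrix pairs.
#' @param seed integer seed.
#' @export
noise_floor_mc <- function(N, n_draws = 200, seed = 1) {
  cors <- with_seed(derive_seed(seed, 65L), {
    vapply(seq_len(n_draws), function(i) {
      a <- random_memory_matrix(N)
      b <- random_memory_matrix(N)
      pearson(as.vector(a), as.vector(b))
    }, numeric(1))
  })
  stats::sd(cors)
}

#' Trace a reference memory through the cascade
#'
#' Equilibrates the cascade for `N_equi` cycles (imprint + night), then
#' imprints the reference memory at day 0 and runs `N_cycle` daily cycles
#' recording the Pearson correlation of each shortcut matrix (and the HPC
#' matrix) with the reference pattern.  The maximum across layers —
#' HPC included — is the system's overall memory signal; a power law and
#' an exponential are fitted to it above the noise floor.
#'
#' @param config a [cascade_config()].
#' @param seed integer seed.
#' @param record_every record correlations every this many days (1 =
#'   daily).
#' @return object of class `forgetting_curve`: `days`, per-level
#'   correlation matrix `cor` (days x L), `hpc` series, `max` series,
#'   `noise_floor` (1/N) and the decay-model comparison `fits`.
#' @export
trace_memory <- function(config = cascade_config(), seed = 1,
                         record_every = 1L) {
  state <- cascade_state(config, seed = derive_seed(seed, 71L))
  for (j in seq_len(config$N_equi)) {
    state <- imprint_hpc(state, seed = derive_seed(seed, 1000L + j))$state
    state <- consolidate_night(state, seed = derive_seed(seed, 3000L + j))
  }
  ref <- random_memory_matrix(config$N, seed = derive_seed(seed, 72L))

  days <- seq_len(config$N_cycle)
  rec_days <- days[days %% record_every == 0L | days == 1L]
  cors <- matrix(NA_real_, length(rec_days), config$L)
  hpc <- numeric(length(rec_days))
  r <- 0L
  for (day in days) {
    state <- if (day == 1L) {
      imprint_hpc(state, pattern = ref)$state
    } else {
      imprint_hpc(state, seed = derive_seed(seed, 5000L + day))$state
    }
    state <- consolidate_night(state, seed = derive_seed(seed, 7000L + day))
    if (day %in% rec_days) {
      r <- r + 1L
      cors[r, ] <- vapply(state$W, function(w)
        suppressWarnings(memory_correlation(ref, w)), numeric(1))
      hpc[r] <- suppressWarnings(memory_correlation(ref, state$V_hpc))
    }
  }
  # overall memory signal: maximum across layers, the HPC included
  # (its fast early decay is the first segment of the forgetting curve,
  # exactly as the O_0 channel participates in the overlap theory)
  max_series <- pmax(apply(cors, 1, max), hpc)
  floor <- 1 / config$N
  fits <- tryCatch(compare_decay_models(max_series, rec_days, floor),
                   error = function(e) NULL)
  structure(list(days = rec_days, cor = cors, hpc = hpc,
                 max = max_series, noise_floor = floor, fits = fits,
                 config = config, seed = seed, reference = NULL),
            class = "forgetting_curve")
}

#' Recall latency implied by the strongest memory trace
#'
#' If the memory currently resides in shortcut level `i*`, recall from
#' the sensory periphery to the system output traverses
#' `2 (L - i*) + 1` synapses, i.e. latency `(2 (L - i*) + 1) D`.
#'
#' @param curve a [trace_memory()] result.
#' @param day probe day (must be recorded in the curve).
#' @return latency in the same units as `D` (seconds), with attribute
#'   `"level"` (the argmax level).
#' @export
recall_latency <- function(curve, day) {
  stopifnot(inherits(curve, "forgetting_curve"))
  idx <- match(day, curve$days)
  if (is.na(idx)) stop("day not recorded in this curve")
  L <- curve$config$L
  i_star <- which.max(curve$cor[idx, ])
  structure((2 * (L - i_star) + 1) * curve$config$D, level = i_star)
}

#' Argmax level of the memory trace over time
#'
#' Returns, for each recorded day, the level holding the maximum
#' correlation, optionally after smoothing each level's series with a
#' centered moving average (the memory-wave readout).
#'
#' @param curve a [trace_memory()] result.
#' @param smooth moving-average window in recorded samples (odd; 1 = no
#'   smoothing).
#' @export
wave_argmax <- function(curve, smooth = 5L) {
  cors <- curve$cor
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    cors <- apply(cors, 2, function(v)
      stats::filter(v, k, sides = 2))
    cors <- as.matrix(cors)
  }
  lev <- apply(cors, 1, function(v)
    if (all(is.na(v))) NA_integer_ else which.max(v))
  lev
}
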