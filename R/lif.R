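#' Leaky integrate-and-fire neuron parameters
#'
#' Conductance-based LIF cell; conductances are in units of the leak
#' conductance (dimensionless).  Defaults follow the single-cell
#' consolidation experiments.
#'
#' @param tau_m membrane time constant (ms).
#' @param v_rest resting potential (mV).
#' @param e_syn synaptic reversal potential (mV).
#' @param v_thresh spike threshold (mV).
#' @param v_reset reset potential (mV).
#' @param t_ref absolute refractory period (ms).
#' @param tau_syn synaptic decay time constant (ms).
#' @param dt forward-Euler step (ms).
#' @export
lif_params <- function(tau_m = 20, v_rest = -70, e_syn = 0,
                       v_thresh = -54, v_reset = -60, t_ref = 1.75,
                       tau_syn = 5, dt = 0.1) {
  stopifnot(v_reset < v_thresh, tau_m > 0, tau_syn > 0, dt > 0, t_ref >= 0)
  structure(list(tau_m = tau_m, v_rest = v_rest, e_syn = e_syn,
                 v_thresh = v_thresh, v_reset = v_reset, t_ref = t_ref,
                 tau_syn = tau_syn, dt = dt),
            class = "lif_params")
}

#' A population of (possibly plastic) synapses
#'
#' @param weights initial peak conductances (dimensionless).
#' @param plastic logical; does additive STDP act on these synapses?
#' @param g_max hard upper weight bound (lower bound is 0).
#' @param eta learning rate; LTP amplitude is `eta * g_max`, LTD amplitude
#'   `ltd_ratio` times that.
#' @param ltd_ratio ratio of depression to potentiation amplitude
#'   (default 1.05, slight depression dominance for stability).
#' @param tau_stdp STDP time constant (ms).
#' @param delay afferent transmission delay (ms), applied to the spike
#'   times of this population's input.
#' @export
synapse_population <- function(weights, plastic = TRUE, g_max = 0.006,
                               eta = 0.005, ltd_ratio = 1.05,
                               tau_stdp = 20, delay = 0) {
  stopifnot(all(weights >= 0), all(weights <= g_max + 1e-12), delay >= 0)
  structure(list(weights = pmin(weights, g_max), plastic = plastic,
                 g_max = g_max, a_plus = eta * g_max,
                 a_minus = ltd_ratio * eta * g_max,
                 tau_stdp = tau_stdp, delay = delay),
            class = "synapse_population")
}

#' Bimodal initial weights for additive STDP
#'
#' Half the weights are drawn from an exponential distribution with mean
#' `0.05 * g_max` (clipped to `[0, g_max]`), the other half as `g_max`
#' minus an independent draw of the same distribution; this matches the
#' steady-state weight distribution of additive STDP under uncorrelated
#' Poisson input.  Afferent assignment to the two modes is random.  For
#' odd `n` the larger half gets the low mode.
#'
#' @param n number of weights.
#' @param g_max weight bound.
#' @param seed integer seed.
#' @export
init_bimodal_weights <- function(n, g_max = 0.006, seed = 1) {
  stopifnot(n >= 1)
  with_seed(derive_seed(seed, 6L), {
    n_low <- ceiling(n / 2)
    low <- pmin(stats::rexp(n_low, rate = 1 / (0.05 * g_max)), g_max)
    high <- pmax(g_max - stats::rexp(n - n_low, rate = 1 / (0.05 * g_max)), 0)
    w <- c(low, high)[sample.int(n)]
  })
  w
}

#' Simulate the LIF neuron with one or more synapse populations
#'
#' Forward-Euler integration of the conductance-based LIF membrane with
#' per-population afferent delays and online additive STDP (all-to-all
#' pairing via exponential traces).  Postsynaptic spikes are detected at
#' grid points; exact pre/post coincidences fall on the depression branch.
#'
#' @param params a [lif_params()].
#' @param inputs list of `spike_input_set`s, one per population (times in
#'   ms; population delays are added here).
#' @param pops list of [synapse_population()]s, lengths matching `inputs`.
#' @param duration simulation length (ms).
#' @param snapshot_times times (ms) at which to record all weights.
#' @param record_v record the membrane trace (memory-heavy; tests only).
#' @return list with per-population final `weights` and weight
#'   `snapshots`, postsynaptic spike times `post_times`, and optionally
#'   the membrane trace `v`.
#' @export
simulate_neuron <- function(params, inputs, pops, duration,
                            snapshot_times = numeric(0), record_v = FALSE) {
  stopifnot(inherits(params, "lif_params"), length(inputs) == length(pops))
  offsets <- c(0L, cumsum(vapply(pops, function(p) length(p$weights),
                                 integer(1))))
  ids <- integer(0); ts <- numeric(0)
  for (k in seq_along(pops)) {
    tr <- inputs[[k]]$trains
    stopifnot(length(tr) == length(pops[[k]]$weights))
    ids <- c(ids, rep.int(seq_along(tr) - 1L + offsets[k], lengths(tr)))
    ts <- c(ts, unlist(tr) + pops[[k]]$delay)
  }
  o <- order(ts)
  ids <- ids[o]; ts <- ts[o]
  keep <- ts <= duration
  ids <- ids[keep]; ts <- ts[keep]

  w0 <- unlist(lapply(pops, `[[`, "weights"))
  plastic <- unlist(lapply(pops, function(p) rep(p$plastic,
                                                 length(p$weights))))
  g_max <- unlist(lapply(pops, function(p) rep(p$g_max, length(p$weights))))
  a_plus <- unlist(lapply(pops, function(p) rep(p$a_plus,
                                                length(p$weights))))
  a_minus <- unlist(lapply(pops, function(p) rep(p$a_minus,
                                                 length(p$weights))))
  tau_stdp <- pops[[1]]$tau_stdp

  res <- cpp_lif_stdp(ids, ts, w0, plastic, g_max, a_plus, a_minus,
                      tau_stdp, params$tau_m, params$v_rest, params$e_syn,
                      params$v_thresh, params$v_reset, params$t_ref,
                      params$tau_syn, params$dt, duration,
                      sort(snapshot_times), record_v)

  split_w <- function(w) lapply(seq_along(pops), function(k)
    w[(offsets[k] + 1):offsets[k + 1]])
  out <- list(
    weights = split_w(res$weights),
    snapshots = lapply(seq_along(pops), function(k)
      res$snapshots[, (offsets[k] + 1):offsets[k + 1], drop = FALSE]),
    snapshot_times = res$snapshot_times,
    post_times = res$post_times
  )
  if (record_v) out$v <- res$v
  out
}

#' Configuration for the weight-copy experiment
#'
#' The `"paper"` profile uses 1000 afferents per pathway with the
#' published cell and plasticity constants; the `"test"` profile is a
#' desk-scale version (200 afferents per pathway, conductances scaled to
#' preserve the total synaptic drive, learning rate raised tenfold,
#' shorter duration).
#'
#' @param profile `"test"` or `"paper"`.
#' @param ... overrides for individual fields.
#' @export
copy_experiment_config <- function(profile = c("test", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper") {
    list(n_aff = 1000, g_max = 0.006, eta = 0.005, rate = 10, delay = 5,
         duration = 2e6, n_snapshots = 25)
  } else {
    list(n_aff = 200, g_max = 0.03, eta = 0.01, rate = 10, delay = 5,
         duration = 1.6e6, n_snapshots = 25)
  }
  cfg$profile <- profile
  utils::modifyList(cfg, list(...))
}

#' Weight-copy experiment between parallel pathways
#'
#' The teacher pathway holds a fixed bimodal weight pattern; the learner
#' pathway is plastic and starts from an independent bimodal draw.  Both
#' pathways carry identical Poisson spike trains except that the indirect
#' pathway is delayed by `delay` ms.  With `direction =
#' "indirect_to_direct"` the teacher is the delayed (indirect) pathway and
#' the learner the direct one — consolidation succeeds because causal
#' pre-then-post timing potentiates the matching learner synapses.  With
#' `"direct_to_indirect"` the roles are swapped and consolidation fails.
#'
#' @param direction which pathway teaches.
#' @param seed integer seed.
#' @param config a [copy_experiment_config()].
#' @return list with the Pearson `correlation` trajectory between learner
#'   and teacher weight vectors, snapshot `times` (ms), initial/final
#'   normalized weights, output spike times, and the configuration.
#' @export
run_copy_experiment <- function(direction = c("indirect_to_direct",
                                              "direct_to_indirect"),
                                seed = 1,
                                config = copy_experiment_config()) {
  direction <- match.arg(direction)
  base <- poisson_trains(config$n_aff, config$rate, config$duration,
                         seed = derive_seed(seed, 11L))
  delayed <- delayed_copy(base, config$delay)

  teacher_w <- init_bimodal_weights(config$n_aff, config$g_max,
                                    seed = derive_seed(seed, 12L))
  learner_w <- init_bimodal_weights(config$n_aff, config$g_max,
                                    seed = derive_seed(seed, 13L))

  teacher <- synapse_population(teacher_w, plastic = FALSE,
                                g_max = config$g_max, eta = config$eta)
  learner <- synapse_population(learner_w, plastic = TRUE,
                                g_max = config$g_max, eta = config$eta)
  if (direction == "indirect_to_direct") {
    # teacher = indirect (delayed copy), learner = direct
    inputs <- list(delayed, base)
    pops <- list(teacher, learner)
  } else {
    # teacher = direct, learner = indirect (delayed)
    inputs <- list(base, delayed)
    pops <- list(teacher, learner)
  }
  snap <- seq(0, config$duration, length.out = config$n_snapshots)
  sim <- simulate_neuron(lif_params(), inputs, pops, config$duration,
                         snapshot_times = snap)
  corr <- apply(sim$snapshots[[2]], 1, function(w)
    suppressWarnings(stats::cor(w, teacher_w)))
  corr[is.na(corr)] <- 0
  list(direction = direction,
       correlation = corr,
       times = sim$snapshot_times,
       teacher_weights = teacher_w / config$g_max,
       learner_initial = learner_w / config$g_max,
       learner_final = sim$weights[[2]] / config$g_max,
       post_times = sim$post_times,
       config = config)
}

#' Configuration for the spatial-replay experiment
#'
#' Desk-scale surrogate of the grid-to-place consolidation: a point LIF
#' neuron replaces the compartmental cell, place (indirect) input is fixed
#' and tuned to one field, grid (direct) input is plastic and untuned.
#'
#' @param profile `"test"` or `"paper"`.
#' @param ... field overrides.
#' @export
replay_experiment_config <- function(profile = c("test", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper") {
    list(n_grid = 500, n_place = 2500, g_sc = 0.03, g_pp_max = 0.015,
         eta = 0.01, duration = 4e5, delay = 5,
         target = 1.25, n_snapshots = 21)
  } else {
    list(n_grid = 100, n_place = 500, g_sc = 0.15, g_pp_max = 0.075,
         eta = 0.02, duration = 2e5, delay = 5,
         target = 1.25, n_snapshots = 21)
  }
  cfg$profile <- profile
  utils::modifyList(cfg, list(...))
}

#' Spatial-replay consolidation experiment
#'
#' A virtual animal replays back-and-forth sweeps of a 2.5 m track.  The
#' place (indirect, delayed) pathway has fixed weights tuned to a single
#' target place field; the grid (direct) pathway is plastic from an
#' untuned initialization.  After each sweep the summed grid-input tuning
#' curve is correlated with the theoretical reference tuning
#' ([theory_tuning()]).  At replay speed (20 x physical motion) the input
#' correlation time matches the STDP window and the tuning is copied; at
#' physical speed it is not.
#'
#' @param tuning a [track_tuning()]; defaults to a desk-scale population.
#' @param speed_factor 20 (replay) or 1 (physical motion).
#' @param seed integer seed.
#' @param config a [replay_experiment_config()].
#' @return list with the tuning `correlation` trajectory, snapshot
#'   `times`, final grid weights, the reference tuning, and config.
#' @export
run_spatial_replay_experiment <- function(tuning = NULL, speed_factor = 20,
                                          seed = 1,
                                          config = replay_experiment_config()) {
  if (is.null(tuning))
    tuning <- track_tuning(n_grid = config$n_grid, n_place = config$n_place,
                           seed = derive_seed(seed, 21L))
  speed <- 0.25 * speed_factor
  pass_dur_ms <- tuning$track_length / speed * 1000
  n_passes <- max(2L, floor(config$duration / pass_dur_ms))
  session <- track_replay_session(tuning, speed_factor, n_passes,
                                  seed = derive_seed(seed, 22L),
                                  place_delay = config$delay)
  duration <- n_passes * pass_dur_ms + config$delay

  # fixed, tuned place weights: full strength for afferents whose field
  # covers the target position, zero otherwise
  in_target <- drop(place_field_active(tuning, config$target))
  w_place <- ifelse(in_target, config$g_sc, 0)
  # untuned initialization at the additive-STDP steady state (bimodal,
  # random afferent assignment): no spatial structure and no net drift
  # of the mean under chance pairings
  w_grid <- init_bimodal_weights(tuning$n_grid, config$g_pp_max,
                                 seed = derive_seed(seed, 23L))

  pops <- list(
    synapse_population(w_grid, plastic = TRUE, g_max = config$g_pp_max,
                       eta = config$eta, delay = 0),
    synapse_population(w_place, plastic = FALSE, g_max = config$g_sc,
                       delay = 0)  # delay already applied by the session
  )
  snap <- seq(0, duration, length.out = config$n_snapshots)
  sim <- simulate_neuron(lif_params(), list(session$grid, session$place),
                         pops, duration, snapshot_times = snap)

  ref <- theory_tuning(tuning, config$target)
  G <- grid_tuning_curve(tuning, ref$x)   # positions x afferents
  corr <- apply(sim$snapshots[[1]], 1, function(w) {
    curve <- drop(G %*% w)
    suppressWarnings(stats::cor(curve, ref$tuning))
  })
  corr[is.na(corr)] <- 0
  list(speed_factor = speed_factor,
       correlation = corr,
       times = sim$snapshot_times,
       grid_weights = sim$weights[[1]],
       reference = ref,
       post_times = sim$post_times,
       n_passes = n_passes,
       config = config, tuning = tuning)
}
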