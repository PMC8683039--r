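#' Configuration of the multi-stage hippocampal network
#'
#' All parameters of the rate-based EC -> DG-CA3 -> CA1 -> SUB model with
#' object/place populations.  The `"paper"` profile carries the published
#' values (N = 256 cells per population, 128 objects, 31 consolidation
#' cycles of 150 s each).  The `"test"` profile is a desk-scale world
#' (N = 64, 16 objects, 15 s nights, 8 cycles) in which the STDP
#' amplitudes are raised by the night-length ratio so that the total
#' plasticity per night (amplitude x duration) is preserved.
#'
#' Times are in seconds and rates in spikes/s throughout this module.
#'
#' @param profile `"test"` or `"paper"`.
#' @param ... field overrides.
#' @return a list of class `hippocampal_config`.
#' @export
hippocampal_config <- function(profile = c("test", "paper"), ...) {
  profile <- match.arg(profile)
  paper_Tc <- 150
  cfg <- list(
    N_cycle = 31, T_c = paper_Tc, dT = 0.005, N = 256, N_object = 128,
    r_max = 10, sigma = 0.1, D = 0.005,
    w_sc_id = 1 / 4, w_cs_id = 1 / 2, lambda_sc = 0.6, N_mem = 125,
    N_equi = 10, sigma_noise = 4.8, lesion_day = 21,
    platform = c(0.25, 0.25)
  )
  if (profile == "test") {
    cfg$N <- 64; cfg$N_object <- 16; cfg$T_c <- 15; cfg$N_cycle <- 8
    cfg$lesion_day <- 5
    # the decoder log-likelihood concentrates as N / sigma_noise^2 (the
    # squared distance between standardized responses grows with N);
    # shrink sigma_noise with sqrt(N) to keep the published concentration
    cfg$sigma_noise <- 4.8 * sqrt(64 / 256)
  }
  dots <- list(...)
  night_scale <- dots$night_scale
  dots$night_scale <- NULL
  cfg <- utils::modifyList(cfg, dots)
  if (round(sqrt(cfg$N))^2 != cfg$N)
    stop("N must be a perfect square (place cells sit on a regular grid)")
  cfg$w_max <- 1 / cfg$N
  cfg$w_init_max <- cfg$w_max / 10
  # STDP amplitudes are raised for short test nights, but less than the
  # full night-length ratio: the systematic drift per night scales as
  # A * T_c while the stochastic weight churn scales as A * sqrt(T_c),
  # so matching both is impossible; night_scale = 4 (for T_c = 15 s)
  # keeps one night sufficient for decodable consolidation without
  # letting churn dominate shortcut retention
  if (is.null(night_scale))
    night_scale <- if (cfg$T_c == paper_Tc) 1 else 4
  cfg$night_scale <- night_scale
  cfg$ap_ca1 <- 0.05 * cfg$w_max * night_scale
  cfg$am_ca1 <- -1.00025 * cfg$ap_ca1
  cfg$ap_sub <- 0.5 * cfg$ap_ca1
  cfg$am_sub <- 0.5 * cfg$am_ca1
  cfg$tau_stdp <- 0.020
  cfg$profile <- profile
  structure(cfg, class = "hippocampal_config")
}

#' Population codes of the hippocampal model
#'
#' Builds the deterministic (given the seed) code book: grid-cell tuning
#' parameters for EC place-coding cells (superpositions of three plane
#' waves at 60-degree angles, spacings spanning 2-6 periods across the
#' arena, random orientations and phases), regular-grid place-field
#' centers for DG-CA3 cells, and fixed response vectors for the
#' `N_object` objects.  Object codes are built by evaluating the place
#' codes at a random "object position" and then permuting the rates
#' within the population, so their marginal rate statistics match the
#' place codes without confining them to a 2-D manifold.
#'
#' @param config a [hippocampal_config()].
#' @param seed integer seed.
#' @return object of class `hpc_codebook`.
#' @export
make_codebook <- function(config, seed = 1) {
  N <- config$N; N_object <- config$N_object
  with_seed(derive_seed(seed, 41L), {
    i <- seq_len(N)
    m <- 2 * pi * (2 + 4 * i / N)
    theta <- stats::runif(N, 0, 2 * pi)
    px <- stats::runif(N); py <- stats::runif(N)
    ngrid <- round(sqrt(N))
    cc <- (seq_len(ngrid) - 0.5) / ngrid
    centers <- as.matrix(expand.grid(cx = cc, cy = cc))
    obj_pos <- matrix(stats::runif(2 * N_object), N_object, 2)
    cb <- list(N = N, N_object = N_object, r_max = config$r_max,
               sigma = config$sigma,
               m = m, theta = theta, px = px, py = py,
               cx = centers[, 1], cy = centers[, 2],
               obj_pos = obj_pos)
    ec_obj <- matrix(0, N, N_object)
    ca3_obj <- matrix(0, N, N_object)
    for (j in seq_len(N_object)) {
      ec_obj[, j] <- cpp_grid_rates(m, theta, px, py, config$r_max,
                                    obj_pos[j, 1], obj_pos[j, 2])[sample.int(N)]
      ca3_obj[, j] <- cpp_place_rates(cb$cx, cb$cy, config$r_max,
                                      config$sigma,
                                      obj_pos[j, 1], obj_pos[j, 2])[sample.int(N)]
    }
    cb$ec_obj <- ec_obj
    cb$ca3_obj <- ca3_obj
    cb
  }) -> cb
  structure(cb, class = "hpc_codebook")
}

#' Grid-cell population rates in EC
#'
#' Each cell's rate is a superposition of three plane waves,
#' \eqn{r_i = r_{max}\frac{2}{9}\sum_{l=1}^{3}[1/2 + \cos(m_i k_{il}
#' \cdot (p - p_i))]}, which varies between 0 and `r_max` and equals
#' `r_max` at the cell's own phase.
#'
#' @param codebook an [make_codebook()] object.
#' @param p position in the unit square (length-2).
#' @return rate vector of length `N`.
#' @export
ec_grid_rate <- function(codebook, p) {
  if (any(p < 0) || any(p > 1)) stop("position must lie in [0,1]^2")
  drop(cpp_grid_rates(codebook$m, codebook$theta, codebook$px, codebook$py,
                      codebook$r_max, p[1], p[2]))
}

#' Place-cell population rates in DG-CA3
#'
#' 2-D Gaussian fields: \eqn{r_i = r_{max}\exp(-(p - c_i)^2/(2\sigma^2))}.
#'
#' @param codebook an [make_codebook()] object.
#' @param p position in the unit square.
#' @param centers optional `N x 2` matrix of current field centers
#'   (defaults to the code book's reference grid); used after remapping.
#' @export
ca3_place_rate <- function(codebook, p, centers = NULL) {
  cx <- if (is.null(centers)) codebook$cx else centers[, 1]
  cy <- if (is.null(centers)) codebook$cy else centers[, 2]
  drop(cpp_place_rates(cx, cy, codebook$r_max, codebook$sigma, p[1], p[2]))
}

#' Initial network state
#'
#' Builds the four weight matrices in the concatenated
#' `[place; object]` layout (pre-synaptic rows, post-synaptic columns):
#' `V_SC` and `V_CA1SUB` carry scaled identity blocks on place-place and
#' object-object (the SC additionally a plastic object-to-place block,
#' initially empty), and the shortcut matrices `W_PP_CA1`, `W_PP_SUB` are
#' uniform random in `[0, w_init_max]`.
#'
#' @param config a [hippocampal_config()].
#' @param codebook a [make_codebook()] object.
#' @param seed integer seed.
#' @return object of class `hippocampal_state`.
#' @export
hippocampal_state <- function(config, codebook, seed = 1) {
  N <- config$N
  I_N <- diag(N)
  zero <- matrix(0, N, N)
  V_sc <- rbind(cbind(config$w_sc_id * I_N, zero),
                cbind(zero, config$w_sc_id * I_N))
  V_cs <- rbind(cbind(config$w_cs_id * I_N, zero),
                cbind(zero, config$w_cs_id * I_N))
  with_seed(derive_seed(seed, 42L), {
    W_ca1 <- matrix(stats::runif(4 * N * N, 0, config$w_init_max),
                    2 * N, 2 * N)
    W_sub <- matrix(stats::runif(4 * N * N, 0, config$w_init_max),
                    2 * N, 2 * N)
  })
  structure(list(config = config,
                 V_sc = V_sc, V_cs = V_cs,
                 W_ca1 = W_ca1, W_sub = W_sub,
                 centers = cbind(codebook$cx, codebook$cy),
                 ca1_lesioned = FALSE),
            class = "hippocampal_state")
}

block_idx <- function(N, which = c("place", "object")) {
  which <- match.arg(which)
  if (which == "place") seq_len(N) else N + seq_len(N)
}

#' Linear forward pass through the network
#'
#' `y_CA1 = W_PP_CA1' x_EC + V_SC' x_CA3(t - D)` and
#' `y_SUB = W_PP_SUB' x_EC + V_CA1SUB' y_CA1(t - D)`; the delayed
#' arguments are the previous-step activities (the delay equals one
#' integration step).
#'
#' @param state a [hippocampal_state()].
#' @param x_ec EC activity (length `2N`).
#' @param x_ca3_delayed DG-CA3 activity one step earlier (length `2N`).
#' @param y_ca1_delayed CA1 activity one step earlier; defaults to the
#'   steady-state value implied by the same inputs.
#' @return list with `y_ca1`, `y_sub`.
#' @export
forward_pass <- function(state, x_ec, x_ca3_delayed, y_ca1_delayed = NULL) {
  N2 <- 2 * state$config$N
  stopifnot(length(x_ec) == N2, length(x_ca3_delayed) == N2)
  y_ca1 <- drop(t(state$W_ca1) %*% x_ec + t(state$V_sc) %*% x_ca3_delayed)
  if (is.null(y_ca1_delayed)) y_ca1_delayed <- y_ca1
  y_sub <- drop(t(state$W_sub) %*% x_ec + t(state$V_cs) %*% y_ca1_delayed)
  list(y_ca1 = y_ca1, y_sub = y_sub)
}

norm_max_colsum <- function(M) {
  s <- max(colSums(M))
  if (s <= 0) stop("cannot normalize a matrix with no positive column sum")
  M / s
}

#' Imprint an object-place association into the SC pathway
#'
#' Updates only the object-to-place block of `V_SC` with the Hebbian
#' outer product of the DG-CA3 object representation and the CA1 place
#' response, using the nested normalization
#' `V <- norm(V + lambda * norm(x y') / (1 - lambda))`, where `norm(M)`
#' rescales all entries by one factor so that the largest column sum is
#' 1.  The inner norm equalizes the influence of memories regardless of
#' activity level; the outer norm bounds the weights and induces
#' forgetting by interference.
#'
#' @param state a [hippocampal_state()].
#' @param codebook a [make_codebook()] object.
#' @param object object id (1-based).
#' @param p position in the unit square.
#' @param lambda memory strength in (0, 1); default from the config.
#' @return the updated state.
#' @export
imprint_association <- function(state, codebook, object, p,
                                lambda = state$config$lambda_sc) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie strictly in (0, 1)")
  N <- state$config$N
  x_ec <- c(ec_grid_rate(codebook, p), codebook$ec_obj[, object])
  x_ca3 <- c(ca3_place_rate(codebook, p, centers = state$centers),
             codebook$ca3_obj[, object])
  y_ca1 <- forward_pass(state, x_ec, x_ca3)$y_ca1
  obj <- block_idx(N, "object"); pl <- block_idx(N, "place")
  outer_upd <- codebook$ca3_obj[, object] %o% y_ca1[pl]
  state$V_sc[obj, pl] <- norm_max_colsum(
    state$V_sc[obj, pl] + lambda * norm_max_colsum(outer_upd) / (1 - lambda))
  state
}

#' Remap the DG-CA3 place code
#'
#' Assigns new uniform random field centers, modelling a new environment
#' for each day's association; reduces interference between memories.
#'
#' @param state a [hippocampal_state()].
#' @param seed integer seed.
#' @export
remap_ca3 <- function(state, seed = 1) {
  N <- state$config$N
  state$centers <- with_seed(derive_seed(seed, 43L),
                             matrix(stats::runif(2 * N), N, 2))
  state
}

#' One consolidation phase (night)
#'
#' For `T_c / dT` steps, a random position and object are activated
#' independently in EC, activities are propagated with a one-step delay,
#' and the shortcut matrices are updated by the trace-based STDP rule
#' (exponential pre/post traces with time constant `tau_stdp`), clipped
#' to `[0, w_max]`.
#'
#' @param state a [hippocampal_state()].
#' @param codebook a [make_codebook()] object.
#' @param seed integer seed.
#' @param T_c night length in s (default from config).
#' @return the updated state.
#' @export
consolidation_phase <- function(state, codebook, seed = 1,
                                T_c = state$config$T_c) {
  cfg <- state$config
  n_steps <- round(T_c / cfg$dT)
  res <- with_seed(derive_seed(seed, 44L),
    cpp_hpc_consolidation(state$W_ca1, state$W_sub, state$V_sc, state$V_cs,
                          codebook$m, codebook$theta, codebook$px,
                          codebook$py,
                          state$centers[, 1], state$centers[, 2],
                          codebook$ec_obj, codebook$ca3_obj,
                          cfg$r_max, cfg$sigma,
                          cfg$ap_ca1, cfg$am_ca1, cfg$ap_sub, cfg$am_sub,
                          cfg$tau_stdp, cfg$dT, n_steps, cfg$w_max,
                          !state$ca1_lesioned, TRUE))
  if (!state$ca1_lesioned) state$W_ca1 <- res$W_ca1
  state$W_sub <- res$W_sub
  state
}

#' Lesion the direct EC-to-CA1 pathway
#'
#' Sets all PP_CA1 weights to zero and disables their plasticity.
#'
#' @param state a [hippocampal_state()].
#' @export
lesion_pp_ca1 <- function(state) {
  state$W_ca1[] <- 0
  state$ca1_lesioned <- TRUE
  state
}

#' Bayesian place decoding from a place-population response
#'
#' Gaussian-likelihood decoder over the `N` reference place-cell grid
#' positions: response and templates (`mu(p)`, proportional to the DG-CA3
#' place code) are standardized to zero mean and unit variance, and the
#' posterior is `exp(-||y - mu(p)||^2 / (2 sigma_noise^2))` under a
#' flat prior, renormalized to sum to one.  A zero-variance response
#' yields a uniform posterior with a warning.
#'
#' @param y_place place-population response (length `N`).
#' @param codebook a [make_codebook()] object.
#' @param sigma_noise noise standard deviation of the likelihood.
#' @return object of class `posterior_map`: `prob` (length `N`, sums to
#'   1), candidate positions `cx`, `cy`.
#' @export
decode_place <- function(y_place, codebook, sigma_noise = 4.8) {
  N <- codebook$N
  stopifnot(length(y_place) == N)
  zscore <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(NULL)
    (v - mean(v)) / s
  }
  yz <- zscore(y_place)
  if (is.null(yz)) {
    warning("zero-variance response; returning a uniform posterior")
    prob <- rep(1 / N, N)
  } else {
    mu <- vapply(seq_len(N), function(k)
      zscore(cpp_place_rates(codebook$cx, codebook$cy, codebook$r_max,
                             codebook$sigma, codebook$cx[k],
                             codebook$cy[k])),
      numeric(N))
    d2 <- colSums((yz - mu)^2)
    # exponent without the population-size factor: with standardized
    # responses ||y - mu||^2 ~ 2N(1 - rho), so dividing by N as well
    # would cap the log-likelihood range at 2/sigma^2 ~ 0.09 and make
    # the posterior uninformative at any N
    loglik <- -d2 / (2 * sigma_noise^2)
    prob <- exp(loglik - max(loglik))
    prob <- prob / sum(prob)
  }
  structure(list(prob = prob, cx = codebook$cx, cy = codebook$cy),
            class = "posterior_map")
}

decode_pathway <- function(state, codebook, object,
                           pathway = c("SC", "PP_CA1", "PP_SUB")) {
  pathway <- match.arg(pathway)
  N <- state$config$N
  obj <- block_idx(N, "object"); pl <- block_idx(N, "place")
  y <- switch(pathway,
    SC = drop(t(state$V_sc[obj, pl]) %*% codebook$ca3_obj[, object]),
    PP_CA1 = drop(t(state$W_ca1[obj, pl]) %*% codebook$ec_obj[, object]),
    PP_SUB = drop(t(state$W_sub[obj, pl]) %*% codebook$ec_obj[, object]))
  decode_place(y, codebook, state$config$sigma_noise)
}

#' Quadrant of each candidate place
#'
#' Quadrants are the four equal sub-squares of the unit square, numbered
#' 1 = lower-left, 2 = lower-right, 3 = upper-left, 4 = upper-right;
#' boundary points go to the lower/left quadrant.
#'
#' @param cx,cy candidate coordinates.
#' @export
quadrant_of <- function(cx, cy) {
  1L + as.integer(cx > 0.5) + 2L * as.integer(cy > 0.5)
}

#' Quadrant occupancy from pathway posteriors
#'
#' Selects the pathway whose posterior has the highest maximum (ties go
#' to the later-consolidating pathway, SC < PP_CA1 < PP_SUB), sums its
#' posterior per quadrant, and mixes linearly with uniform exploration:
#' `occupancy = explore_frac * 0.25 + (1 - explore_frac) * P_quadrant`.
#'
#' @param posteriors named list of `posterior_map`s in consolidation
#'   order (SC first).
#' @param explore_frac exploration fraction (default 0.7).
#' @return list with `occupancy` (length 4, sums to 1) and the selected
#'   `pathway` name.
#' @export
quadrant_occupancy <- function(posteriors, explore_frac = 0.7) {
  stopifnot(length(posteriors) >= 1)
  peaks <- vapply(posteriors, function(p) max(p$prob), numeric(1))
  # which.max takes the first maximum; reverse so ties go to the most
  # peripheral (latest) pathway
  sel_rev <- which.max(rev(peaks))
  sel <- length(peaks) + 1L - sel_rev
  post <- posteriors[[sel]]
  q <- quadrant_of(post$cx, post$cy)
  pq <- vapply(1:4, function(k) sum(post$prob[q == k]), numeric(1))
  occ <- explore_frac * 0.25 + (1 - explore_frac) * pq
  list(occupancy = occ,
       pathway = names(posteriors)[sel] %||% as.character(sel))
}

#' Run a watermaze consolidation experiment
#'
#' Equilibrates the SC with `N_mem` imprints and the shortcut matrices
#' with `N_equi` consolidation cycles, imprints the tracked object-place
#' association (the platform) on day 0, and then runs `N_cycle` daily
#' cycles of (new interfering association, night of consolidation,
#' probe).  Probes decode the tracked object through SC, PP_CA1 and
#' PP_SUB and convert the winning posterior into quadrant occupancies.
#' Lesion schedules zero the PP_CA1 weights and freeze their plasticity
#' either before acquisition or after the probe on `lesion_day`.
#'
#' @param config a [hippocampal_config()].
#' @param schedule `"control"`, `"lesion-before"` or `"lesion-day21"`.
#' @param seed integer seed.
#' @param probe_days days at which to probe (default: every day).
#' @return object of class `watermaze_result`: tidy data frames `probes`
#'   (day, pathway, target-quadrant posterior mass, peak posterior) and
#'   `occupancy` (day, quadrant, occupancy, selected pathway), plus the
#'   target quadrant and inputs.
#' @export
run_watermaze <- function(config = hippocampal_config(),
                          schedule = c("control", "lesion-before",
                                       "lesion-day21"),
                          seed = 1, probe_days = NULL) {
  schedule <- match.arg(schedule)
  if (is.null(probe_days)) probe_days <- seq_len(config$N_cycle)
  codebook <- make_codebook(config, seed = derive_seed(seed, 51L))
  state <- hippocampal_state(config, codebook, seed = derive_seed(seed, 52L))

  draws <- with_seed(derive_seed(seed, 53L), {
    n_draws <- config$N_mem + config$N_equi + config$N_cycle
    list(obj = sample.int(config$N_object, n_draws, replace = TRUE),
         pos = matrix(stats::runif(2 * n_draws), n_draws, 2),
         tracked_obj = sample.int(config$N_object, 1))
  })
  k <- 0L
  next_draw <- function() {
    k <<- k + 1L
    list(obj = draws$obj[k], pos = draws$pos[k, ])
  }

  # SC equilibration: N_mem imprints in remapped environments
  for (j in seq_len(config$N_mem)) {
    state <- remap_ca3(state, seed = derive_seed(seed, 100L + j))
    d <- next_draw()
    state <- imprint_association(state, codebook, d$obj, d$pos)
  }
  # shortcut equilibration: N_equi full cycles
  for (j in seq_len(config$N_equi)) {
    state <- remap_ca3(state, seed = derive_seed(seed, 300L + j))
    d <- next_draw()
    state <- imprint_association(state, codebook, d$obj, d$pos)
    state <- consolidation_phase(state, codebook,
                                 seed = derive_seed(seed, 400L + j))
  }

  if (schedule == "lesion-before") state <- lesion_pp_ca1(state)

  # day 0: the tracked association, in the reference environment
  state$centers <- cbind(codebook$cx, codebook$cy)
  platform <- config$platform
  target_q <- quadrant_of(platform[1], platform[2])
  state <- imprint_association(state, codebook, draws$tracked_obj, platform)

  pathways <- c("SC", "PP_CA1", "PP_SUB")
  probes <- list(); occs <- list()
  for (day in seq_len(config$N_cycle)) {
    if (day > 1) {
      state <- remap_ca3(state, seed = derive_seed(seed, 500L + day))
      d <- next_draw()
      state <- imprint_association(state, codebook, d$obj, d$pos)
    }
    state <- consolidation_phase(state, codebook,
                                 seed = derive_seed(seed, 600L + day))
    if (day %in% probe_days) {
      post <- lapply(stats::setNames(pathways, pathways), function(pw)
        suppressWarnings(decode_pathway(state, codebook,
                                        draws$tracked_obj, pw)))
      qidx <- quadrant_of(post[[1]]$cx, post[[1]]$cy)
      probes[[length(probes) + 1L]] <- data.frame(
        day = day, pathway = pathways,
        target_prob = vapply(post, function(p)
          sum(p$prob[qidx == target_q]), numeric(1)),
        peak = vapply(post, function(p) max(p$prob), numeric(1)),
        row.names = NULL)
      occ <- quadrant_occupancy(post)
      occs[[length(occs) + 1L]] <- data.frame(
        day = day, quadrant = 1:4, occupancy = occ$occupancy,
        pathway = occ$pathway, target = (1:4) == target_q,
        row.names = NULL)
    }
    if (schedule == "lesion-day21" && day == config$lesion_day)
      state <- lesion_pp_ca1(state)
  }
  structure(list(schedule = schedule, seed = seed,
                 target_quadrant = target_q,
                 probes = do.call(rbind, probes),
                 occupancy = do.call(rbind, occs),
                 config = config,
                 state = state, codebook = codebook,
                 tracked_object = draws$tracked_obj),
            class = "watermaze_result")
}

#' Days until target-quadrant decodability falls to chance
#'
#' For each pathway, the first probe day at which the target-quadrant
#' posterior mass drops to `0.25 + band` or below; censored at
#' `N_cycle + 1` if it never does.
#'
#' @param result a [run_watermaze()] result.
#' @param band tolerance above the 0.25 chance level (default 0.05).
#' @export
days_to_chance <- function(result, band = 0.05) {
  pr <- result$probes
  vapply(split(pr, pr$pathway), function(df) {
    df <- df[order(df$day), ]
    hit <- which(df$target_prob <= 0.25 + band)
    if (length(hit)) df$day[hit[1]] else max(df$day) + 1
  }, numeric(1))
}
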