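test_that("learning window evaluates the exponential STDP rule", {
  w <- learning_window(a_plus = 1, a_minus = 1.05, tau_stdp = 20)
  # boundary lag belongs to the depression branch
  expect_equal(eval_window(w, 0), -1.05)
  # causal pair one time constant apart
  expect_equal(eval_window(learning_window(1, 1, 20), 20), exp(-1))
  # antisymmetric window: eval(-lag) = -eval(lag) for lag != 0
  wa <- learning_window(0.7, 0.7, 15)
  lags <- c(0.5, 3, 15, 60)
  expect_equal(eval_window(wa, -lags), -eval_window(wa, lags))
  # simulator convention is the mirror image
  expect_equal(eval_window_dt(w, -12), eval_window(w, 12))
  expect_equal(eval_window_dt(w, 0), eval_window(w, 0))
  # invalid constructions
  expect_error(learning_window(1, 1, 0), "tau_stdp")
  expect_error(learning_window(-1), "magnitudes")
})

test_that("coefficient_A matches closed forms and symmetry", {
  f10 <- correlation_kernel("exponential", tau = 10)
  # antisymmetric window x symmetric kernel integrates to zero
  expect_lt(abs(coefficient_A(learning_window(1, 1, 20), f10)), 1e-10)
  # causal-only window: integral of exp(-t/20)exp(-t/10) over t>0
  A <- coefficient_A(learning_window(1, 0, 20), f10)
  expect_equal(as.numeric(A), 20 * 10 / 30, tolerance = 1e-10)
  expect_lt(attr(A, "abs_error"), 1e-8)
  # depression-dominated window gives negative A
  expect_lt(coefficient_A(learning_window(1, 1.05, 20), f10), 0)
  # delta kernel collapses to L(0)
  expect_equal(
    as.numeric(coefficient_A(learning_window(1, 1.05, 20),
                             correlation_kernel("delta"))),
    -1.05)
  # asymmetric kernels are rejected
  f_bad <- correlation_kernel("tabulated", lags = c(-10, 0, 10),
                              values = c(0, 1, 0.5))
  expect_error(coefficient_A(learning_window(1, 1, 20), f_bad),
               "symmetric")
})

test_that("coefficient_B captures the delay dependence", {
  w <- learning_window(1, 1, 20)
  # delta cross-correlation: B = L(D)
  expect_equal(as.numeric(coefficient_B(w, correlation_kernel("delta"), 10)),
               exp(-0.5))
  # delay far beyond the window abolishes consolidation
  g_narrow <- correlation_kernel("exponential", tau = 1)
  expect_lt(abs(coefficient_B(w, g_narrow, 10 * 20)), 1e-4)
  # no delay + antisymmetric window + symmetric g reduces to the A case
  expect_lt(abs(coefficient_B(w, correlation_kernel("gaussian", tau = 8), 0)),
            1e-10)
  # adding symmetric mass to g at D = 0 leaves the antisymmetric-window
  # integral at zero (integral symmetry)
  lags <- seq(-100, 100, by = 0.5)
  g_plus <- correlation_kernel("tabulated", lags = lags,
                               values = exp(-abs(lags) / 8) +
                                 0.5 * exp(-lags^2 / 50))
  expect_lt(abs(coefficient_B(w, g_plus, 0)), 1e-8)
  # narrow g with positive delay lands on the potentiating branch
  expect_gt(coefficient_B(w, g_narrow, 10), 0)
  # swapping pathway roles (D -> -D) flips the sign of B
  expect_lt(coefficient_B(w, g_narrow, -10), 0)
  expect_equal(coefficient_B(w, g_narrow, -10),
               -coefficient_B(w, g_narrow, 10), tolerance = 1e-8)
})

test_that("drift coefficients classify the learning regimes", {
  expect_equal(classify_regime(drift_coefficients(-1, 1)), "consolidating")
  expect_equal(classify_regime(drift_coefficients(-1, -1)), "stable-eroding")
  expect_equal(classify_regime(drift_coefficients(0, 1)), "unstable")
  expect_equal(classify_regime(drift_coefficients(2, 1)), "unstable")
  expect_true(is.na(drift_coefficients(0, 1)$beta))
  expect_equal(drift_coefficients(-2, 1)$beta, 0.5)
})

make_random_stats <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(40 * n), 40, n)
  C <- crossprod(X) / 40 + diag(n) * 0.1
  Xp <- X %*% matrix(rnorm(n * n), n) / sqrt(n)
  pathway_statistics(C, crossprod(X, Xp) / 40)
}

test_that("fixed point equals the least-squares solution", {
  co <- drift_coefficients(-2, 1.2)
  for (seed in 1:5) {
    st <- make_random_stats(10, seed)
    V <- rnorm(10)
    W <- fixed_point_weights(st, V, co)
    W_ls <- normal_equations_W(st$cov_direct, st$cov_cross, V, co$beta)
    expect_lt(max(abs(W - W_ls)) / max(abs(W_ls)), 1e-8)
  }
  # identical pathways: fixed point is beta * V
  C <- diag(4) + 0.2
  st_id <- pathway_statistics(C, C)
  V <- c(1, -2, 0.5, 3)
  expect_equal(fixed_point_weights(st_id, V, co), co$beta * V,
               tolerance = 1e-10)
  # uncorrelated pathways: no teaching signal
  st0 <- pathway_statistics(C, matrix(0, 4, 4))
  expect_equal(fixed_point_weights(st0, V, co), numeric(4))
  # unstable regime refused
  expect_error(fixed_point_weights(st_id, V, drift_coefficients(1, 1)),
               "unstable")
  # singular covariance falls back to a pseudo-inverse with a warning
  Cs <- tcrossprod(matrix(rnorm(8), 4, 2))
  st_s <- pathway_statistics(Cs, Cs)
  expect_warning(fixed_point_weights(st_s, V, co), "pseudo-inverse")
})

test_that("regression error is the empirical objective", {
  set.seed(42)
  x <- matrix(rnorm(500 * 6), 500, 6)
  V <- rnorm(6)
  beta <- 0.8
  # W = beta V with identical pathway inputs gives zero error
  expect_equal(regression_error(beta * V, V, beta, x, x), 0)
  # W = 0 reduces to the mean squared indirect drive
  expect_equal(regression_error(numeric(6), V, 1, x, x),
               mean((x %*% V)^2))
  # the fixed point minimizes the error over random perturbations
  st <- make_random_stats(6, 7)
  co <- drift_coefficients(-1.5, 0.9)
  set.seed(8)
  xs <- matrix(rnorm(4000 * 6), 4000, 6)
  xp <- xs %*% solve(st$cov_direct, st$cov_cross)  # E[x' | x] consistent pair
  W_star <- fixed_point_weights(st, V, co)
  e_star <- regression_error(W_star, V, co$beta, xs, xp)
  for (k in 1:100) {
    e_k <- regression_error(W_star + rnorm(6, sd = 0.1), V, co$beta, xs, xp)
    expect_gte(e_k, e_star)
  }
})

test_that("rate learning converges monotonically to the fixed point", {
  st <- make_random_stats(8, 3)
  co <- drift_coefficients(-2, 1)
  V <- rnorm(8)
  W_star <- fixed_point_weights(st, V, co)
  run <- simulate_rate_learning(st, V, co, eta = 0.05, duration = 600,
                                dt = 0.05)
  d <- sqrt(rowSums((run$W - matrix(W_star, nrow(run$W), 8,
                                    byrow = TRUE))^2))
  expect_lt(d[length(d)] / sqrt(sum(W_star^2)), 1e-3)
  # monotone after a short transient
  tail_d <- d[-(1:100)]
  expect_true(all(diff(tail_d) <= 1e-12))
  # frozen learning
  run0 <- simulate_rate_learning(st, V, co, eta = 0, duration = 10, dt = 0.1,
                                 W0 = V)
  expect_equal(run0$W_final, V)
  # B < 0 with the non-negativity clamp deletes the memory: with
  # non-negative indirect weights and covariances the drive is negative
  # everywhere, so clamped weights decay to zero
  C <- diag(4) + 0.2
  st_pos <- pathway_statistics(C, C)
  co_neg <- drift_coefficients(-2, -1)
  run_del <- simulate_rate_learning(st_pos, abs(rnorm(4)), co_neg,
                                    eta = 0.05, duration = 600, dt = 0.05,
                                    W0 = abs(rnorm(4)),
                                    clamp_nonnegative = TRUE)
  expect_lt(sqrt(sum(run_del$W_final^2)), 1e-3)
  # unstable regime aborts
  expect_error(
    simulate_rate_learning(st, V, drift_coefficients(5, 1), eta = 0.5,
                           duration = 2000, dt = 0.5, W0 = rnorm(8)),
    "unstable")
})

test_that("profiles export and kernels round-trip through kv configs", {
  w <- learning_window(1, 1.05, 20)
  f <- correlation_kernel("exponential", tau = 10)
  g <- correlation_kernel("gaussian", tau = 5)
  path <- tempfile(fileext = ".csv")
  df <- export_kernel_profile(w, f, g, delay_D = 5, path = path)
  back <- read.csv(path)
  expect_named(back, c("tau", "L", "f", "g", "integrand"))
  expect_equal(back$integrand, back$L * back$g)
  expect_equal(nrow(back), nrow(df))

  cfgp <- tempfile(fileext = ".cfg")
  write_kv_config(list(a_plus = 1, a_minus = 1.05, tau_stdp = 20,
                       form = "exponential", taus = c(10, 20)), cfgp)
  cfg <- read_kv_config(cfgp)
  expect_equal(cfg$a_minus, 1.05)
  expect_equal(cfg$form, "exponential")
  expect_equal(cfg$taus, c(10, 20))
})
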