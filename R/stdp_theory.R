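#' Learning windows for spike timing-dependent plasticity
#'
#' Constructs the exponential STDP learning window
#' \deqn{L(\tau) = a_+ e^{-\tau/\tau_{STDP}} \ (\tau > 0), \qquad
#'       L(\tau) = -a_- e^{+\tau/\tau_{STDP}} \ (\tau \le 0),}
#' in the convention where the lag \eqn{\tau} is *positive when the
#' presynaptic spike precedes the postsynaptic spike* (causal pairing,
#' potentiation).  The spiking simulator uses the opposite convention
#' \eqn{\Delta t = t_{pre} - t_{post}}; use [eval_window_dt()] for that
#' accessor.  The boundary \eqn{\tau = 0} (i.e. \eqn{\Delta t = 0}) is
#' assigned to the depression branch.
#'
#' @param a_plus potentiation amplitude (weight change per causal pair),
#'   must be >= 0.
#' @param a_minus depression magnitude, stored positive, >= 0.  Defaults to
#'   `a_plus` (antisymmetric window).
#' @param tau_stdp decay time constant in ms, > 0.
#' @return an object of class `learning_window`.
#' @examples
#' w <- learning_window(a_plus = 1, a_minus = 1.05, tau_stdp = 20)
#' eval_window(w, 20)   # causal pair, one time constant apart
#' @export
learning_window <- function(a_plus = 1, a_minus = a_plus, tau_stdp = 20) {
  stopifnot(is.numeric(a_plus), is.numeric(a_minus), is.numeric(tau_stdp))
  if (tau_stdp <= 0) stop("tau_stdp must be > 0")
  if (a_plus < 0 || a_minus < 0)
    stop("amplitudes a_plus and a_minus are stored as magnitudes and must be >= 0")
  structure(
    list(a_plus = a_plus, a_minus = a_minus, tau_stdp = tau_stdp),
    class = "learning_window"
  )
}

#' @exportS3Method base::print
print.learning_window <- function(x, ...) {
  cat(sprintf(
    "STDP learning window: a+ = %g, a- = %g, tau = %g ms%s\n",
    x$a_plus, x$a_minus, x$tau_stdp,
    if (isTRUE(all.equal(x$a_plus, x$a_minus))) " (antisymmetric)" else ""
  ))
  invisible(x)
}

#' Evaluate a learning window at a pre-minus-post lag
#'
#' @param window a [learning_window()].
#' @param lag_tau numeric vector of lags in ms; positive means the
#'   presynaptic spike came first.
#' @return weight changes, same length as `lag_tau`.
#' @export
eval_window <- function(window, lag_tau) {
  stopifnot(inherits(window, "learning_window"))
  ifelse(lag_tau > 0,
         window$a_plus * exp(-lag_tau / window$tau_stdp),
         -window$a_minus * exp(lag_tau / window$tau_stdp))
}

#' Evaluate a learning window in the simulator convention
#'
#' The simulator convention measures pairs by \eqn{\Delta t = t_{pre} -
#' t_{post}}, so causal pairs have \eqn{\Delta t < 0}.  Equivalent to
#' `eval_window(window, -dt)`.
#'
#' @param window a [learning_window()].
#' @param dt numeric vector, \eqn{t_{pre} - t_{post}} in ms.
#' @export
eval_window_dt <- function(window, dt) eval_window(window, -dt)

#' Input correlation kernels
#'
#' Scalar correlation functions of the lag used in the separable-statistics
#' theory: the autocorrelation kernel `f` of the direct-pathway input and
#' the cross-correlation kernel `g` between pathways.  Both are assumed
#' maximal at lag 0 and decaying to 0 at large lags.
#'
#' Forms:
#' \describe{
#'   \item{exponential}{`amplitude * exp(-|lag|/tau)`}
#'   \item{gaussian}{`amplitude * exp(-lag^2/(2 tau^2))`}
#'   \item{delta}{a Dirac delta of weight `amplitude`; handled symbolically
#'     by the drift-coefficient integrals (never evaluated pointwise).}
#'   \item{tabulated}{linear interpolation of user-supplied `(lags, values)`,
#'     0 outside the tabulated range.}
#' }
#'
#' @param form kernel form, see Details.
#' @param amplitude peak value (or delta weight).
#' @param tau time constant / width in ms (ignored for delta and tabulated).
#' @param lags,values tabulation points for `form = "tabulated"`.
#' @return an object of class `correlation_kernel`.
#' @export
correlation_kernel <- function(form = c("exponential", "gaussian", "delta",
                                        "tabulated"),
                               amplitude = 1, tau = 10,
                               lags = NULL, values = NULL) {
  form <- match.arg(form)
  if (form != "delta" && form != "tabulated" && tau <= 0)
    stop("kernel time constant must be > 0")
  if (form == "tabulated") {
    stopifnot(!is.null(lags), !is.null(values), length(lags) == length(values))
    o <- order(lags)
    lags <- lags[o]; values <- values[o]
  }
  k <- structure(
    list(form = form, amplitude = amplitude, tau = tau,
         lags = lags, values = values),
    class = "correlation_kernel"
  )
  k$symmetric <- kernel_is_symmetric(k)
  k
}

kernel_is_symmetric <- function(kernel) {
  switch(kernel$form,
    exponential = TRUE,
    gaussian = TRUE,
    delta = TRUE,
    tabulated = {
      probe <- seq(0, max(abs(kernel$lags)), length.out = 257)
      isTRUE(all.equal(eval_kernel(kernel, probe), eval_kernel(kernel, -probe),
                       tolerance = 1e-12))
    }
  )
}

#' @exportS3Method base::print
print.correlation_kernel <- function(x, ...) {
  cat(sprintf("correlation kernel: %s, amplitude %g, tau %g ms\n",
              x$form, x$amplitude, x$tau))
  invisible(x)
}

#' Evaluate a correlation kernel
#'
#' @param kernel a [correlation_kernel()].
#' @param lag numeric vector of lags in ms.
#' @export
eval_kernel <- function(kernel, lag) {
  stopifnot(inherits(kernel, "correlation_kernel"))
  switch(kernel$form,
    exponential = kernel$amplitude * exp(-abs(lag) / kernel$tau),
    gaussian = kernel$amplitude * exp(-lag^2 / (2 * kernel$tau^2)),
    delta = stop("delta kernels are symbolic; they cannot be evaluated pointwise"),
    tabulated = {
      y <- stats::approx(kernel$lags, kernel$values, xout = lag,
                         rule = 1)$y
      y[is.na(y)] <- 0
      y
    }
  )
}

# Largest time constant appearing in a window/kernel pair; delta and
# tabulated kernels contribute their support width instead.
kernel_scale <- function(kernel) {
  switch(kernel$form,
    delta = 0,
    tabulated = max(abs(kernel$lags)),
    kernel$tau
  )
}

# Piecewise adaptive quadrature of fun over [lo, hi] with interior
# breakpoints (integrand kinks); tight tolerances, errors summed.
piecewise_integrate <- function(fun, lo, hi, breaks = numeric(0)) {
  pts <- sort(unique(c(lo, hi, breaks[breaks > lo & breaks < hi])))
  total <- 0; err <- 0
  for (i in seq_len(length(pts) - 1L)) {
    res <- stats::integrate(fun, pts[i], pts[i + 1L],
                            rel.tol = 1e-12, abs.tol = 1e-13,
                            subdivisions = 2000L, stop.on.error = FALSE)
    if (!res$message %in% c("OK", "roundoff error was detected"))
      stop("quadrature failed: ", res$message)
    total <- total + res$value
    err <- err + res$abs.error
  }
  list(value = total, abs_error = err)
}

#' Drift coefficient A: stability of the direct-pathway weights
#'
#' Computes \eqn{A = \int L(\tau) f(\tau)\, d\tau}, the coefficient that
#' multiplies the direct pathway's own covariance in the rate-based
#' learning dynamics.  `A < 0` gives stable dynamics.  Because the
#' autocorrelation kernel `f` of a stationary input is necessarily
#' symmetric, the integral is folded onto the half line,
#' \eqn{A = \int_0^\infty [L(\tau) + L(-\tau)] f(\tau)\, d\tau},
#' which makes the antisymmetric-window cancellation exact rather than a
#' difference of two large quadratures.
#'
#' @param window a [learning_window()].
#' @param f a symmetric [correlation_kernel()]; non-symmetric kernels are
#'   rejected (the separability assumption requires a symmetric
#'   autocorrelation).
#' @return scalar A, with attribute `"abs_error"` (quadrature error bound).
#' @export
coefficient_A <- function(window, f) {
  stopifnot(inherits(window, "learning_window"),
            inherits(f, "correlation_kernel"))
  if (!isTRUE(f$symmetric))
    stop("autocorrelation kernel f must be symmetric ",
         "(separability assumption violated)")
  if (f$form == "delta") {
    # integral collapses to f-weight * L(0); L(0) sits on the depression branch
    val <- f$amplitude * eval_window(window, 0)
    return(structure(val, abs_error = 0))
  }
  S <- 25 * max(window$tau_stdp, kernel_scale(f))
  folded <- function(u)
    (eval_window(window, u) + eval_window(window, -u)) * eval_kernel(f, u)
  res <- piecewise_integrate(folded, 0, S)
  structure(res$value, abs_error = res$abs_error)
}

#' Drift coefficient B: consolidation drive from the indirect pathway
#'
#' Computes \eqn{B = \int L(\tau) g(\tau - D)\, d\tau}, the coefficient
#' multiplying the cross-pathway covariance.  `B > 0` means the delayed
#' indirect pathway drives net potentiation in the direct pathway
#' (consolidation possible).  A negative `delay_D` corresponds to swapping
#' the roles of the two pathways (consolidating "backwards").
#'
#' @param window a [learning_window()].
#' @param g cross-correlation [correlation_kernel()].
#' @param delay_D indirect-pathway delay in ms.
#' @return scalar B, with attribute `"abs_error"`.
#' @export
coefficient_B <- function(window, g, delay_D = 0) {
  stopifnot(inherits(window, "learning_window"),
            inherits(g, "correlation_kernel"))
  if (g$form == "delta") {
    return(structure(g$amplitude * eval_window(window, delay_D),
                     abs_error = 0))
  }
  S <- 25 * max(window$tau_stdp, kernel_scale(g)) + abs(delay_D)
  fun <- function(tau) eval_window(window, tau) * eval_kernel(g, tau - delay_D)
  res <- piecewise_integrate(fun, -S, S, breaks = c(0, delay_D))
  structure(res$value, abs_error = res$abs_error)
}

#' Drift coefficients of the rate-based learning dynamics
#'
#' Bundles the stability coefficient `A`, the consolidation coefficient
#' `B`, and their ratio `beta = -B/A` (the gain with which the indirect
#' weights are copied into the direct pathway at the fixed point).
#' `beta` is reported as `NA` when `A = 0`, where the direct pathway's
#' own learning term vanishes and the indirect pathway acts as a pure
#' supervisor.
#'
#' @param A,B scalars, or a window + kernels via [coefficient_A()] /
#'   [coefficient_B()].
#' @return object of class `drift_coefficients` with fields `A`, `B`, `beta`.
#' @export
drift_coefficients <- function(A, B) {
  A <- as.numeric(A); B <- as.numeric(B)
  beta <- if (A != 0) -B / A else NA_real_
  structure(list(A = A, B = B, beta = beta), class = "drift_coefficients")
}

#' @exportS3Method base::print
print.drift_coefficients <- function(x, ...) {
  cat(sprintf("drift coefficients: A = %g, B = %g, beta = %s  [%s]\n",
              x$A, x$B,
              if (is.na(x$beta)) "undefined (A = 0)" else format(x$beta),
              classify_regime(x)))
  invisible(x)
}

#' Classify the learning regime from the drift coefficients
#'
#' @param coeffs a [drift_coefficients()] object.
#' @return one of `"consolidating"` (A < 0, B > 0), `"stable-eroding"`
#'   (A < 0, B <= 0) or `"unstable"` (A >= 0; at A = 0 the dynamics is
#'   marginal and the indirect path acts as a pure supervisor).
#' @export
classify_regime <- function(coeffs) {
  stopifnot(inherits(coeffs, "drift_coefficients"))
  if (coeffs$A < 0) {
    if (coeffs$B > 0) "consolidating" else "stable-eroding"
  } else {
    "unstable"
  }
}

#' Pathway input statistics for the separable theory
#'
#' @param cov_direct zero-lag covariance matrix of the direct-pathway
#'   input (symmetric positive semi-definite).
#' @param cov_cross zero-lag cross-covariance between direct and indirect
#'   inputs.
#' @param f,g auto- and cross-correlation kernels
#'   ([correlation_kernel()]).
#' @param delay_D indirect-pathway delay in ms (>= 0).
#' @return object of class `pathway_statistics`.
#' @export
pathway_statistics <- function(cov_direct, cov_cross,
                               f = correlation_kernel("exponential", tau = 10),
                               g = f, delay_D = 5) {
  cov_direct <- as.matrix(cov_direct); cov_cross <- as.matrix(cov_cross)
  if (!isTRUE(all.equal(cov_direct, t(cov_direct), tolerance = 1e-8)))
    stop("cov_direct must be symmetric")
  if (min(eigen(cov_direct, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * max(abs(cov_direct)))
    stop("cov_direct must be positive semi-definite")
  if (delay_D < 0) stop("delay_D must be >= 0")
  structure(list(cov_direct = cov_direct, cov_cross = cov_cross,
                 f = f, g = g, delay_D = delay_D),
            class = "pathway_statistics")
}

pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fixed point of the direct-pathway learning dynamics
#'
#' For stable dynamics (`A < 0`) the direct weights converge to
#' \deqn{W^* = -\frac{B}{A}\,\langle x x^T\rangle^{-1}
#'       \langle x x'^T\rangle V,}
#' the minimizer of the regression error between the direct input
#' \eqn{W^T x} and the scaled indirect input \eqn{\beta V^T x'}.
#'
#' @param stats a [pathway_statistics()] object.
#' @param V indirect-pathway weight vector.
#' @param coeffs a [drift_coefficients()] object with `A < 0`.
#' @return weight vector `W*`.
#' @export
fixed_point_weights <- function(stats, V, coeffs) {
  stopifnot(inherits(stats, "pathway_statistics"),
            inherits(coeffs, "drift_coefficients"))
  if (coeffs$A >= 0)
    stop("unstable regime: fixed point requires A < 0")
  C <- stats$cov_direct
  inv <- tryCatch(solve(C), error = function(e) {
    warning("cov_direct is singular; using pseudo-inverse")
    pseudo_inverse(C)
  })
  drop(coeffs$beta * inv %*% stats$cov_cross %*% V)
}

#' Empirical regression error of a weight configuration
#'
#' The mean of \eqn{(W^T x - \beta V^T x')^2} over paired input samples,
#' the objective on which the stable learning dynamics performs gradient
#' descent.
#'
#' @param W,V direct / indirect weight vectors.
#' @param beta scalar gain.
#' @param x,xprime sample matrices (rows = draws, cols = inputs).
#' @return non-negative scalar.
#' @export
regression_error <- function(W, V, beta, x, xprime) {
  x <- as.matrix(x); xprime <- as.matrix(xprime)
  stopifnot(nrow(x) == nrow(xprime),
            ncol(x) == length(W), ncol(xprime) == length(V))
  mean((x %*% W - beta * (xprime %*% V))^2)
}

#' Simulate the rate-based learning dynamics of the direct pathway
#'
#' Forward-Euler integration of
#' \deqn{\dot W = \eta\,[A \langle x x^T\rangle W +
#'       B \langle x x'^T\rangle V].}
#' When `A < 0` the trajectory converges to [fixed_point_weights()].
#' An optional non-negativity clamp emulates the sign constraint of real
#' synapses (off by default; the simulations it mirrors used bounds with
#' no qualitative impact).
#'
#' @param stats a [pathway_statistics()] object.
#' @param V indirect weights (held fixed throughout).
#' @param coeffs a [drift_coefficients()] object.
#' @param eta learning rate (per unit time).
#' @param duration total integration time.
#' @param dt Euler step.
#' @param W0 initial direct weights (default 0).
#' @param clamp_nonnegative clip W at 0 after each step.
#' @return object of class `rate_learning_run`: trajectory matrix `W`
#'   (rows = time points), `times`, final weights `W_final`, and the
#'   inputs used.
#' @export
simulate_rate_learning <- function(stats, V, coeffs, eta = 0.1,
                                   duration = 100, dt = 0.1,
                                   W0 = NULL, clamp_nonnegative = FALSE) {
  stopifnot(inherits(stats, "pathway_statistics"),
            inherits(coeffs, "drift_coefficients"))
  n <- ncol(stats$cov_direct)
  if (is.null(W0)) W0 <- numeric(n)
  stopifnot(length(W0) == n, length(V) == ncol(stats$cov_cross))
  nstep <- round(duration / dt)
  W <- matrix(NA_real_, nstep + 1L, n)
  W[1L, ] <- W0
  drive <- drop(coeffs$B * (stats$cov_cross %*% V))
  AC <- coeffs$A * stats$cov_direct
  w <- W0
  init_norm <- max(sqrt(sum(w^2)), 1)
  for (k in seq_len(nstep)) {
    w <- w + eta * dt * (drop(AC %*% w) + drive)
    if (clamp_nonnegative) w <- pmax(w, 0)
    if (sqrt(sum(w^2)) > 1e6 * init_norm)
      stop("unstable regime: weight norm diverged during rate learning")
    W[k + 1L, ] <- w
  }
  structure(list(W = W, times = seq(0, by = dt, length.out = nstep + 1L),
                 W_final = w, V = V, eta = eta, dt = dt,
                 coeffs = coeffs),
            class = "rate_learning_run")
}

#' Export window/kernel profiles for plotting
#'
#' Writes a CSV with columns `tau, L, f, g, integrand` where `integrand`
#' is `L(tau) * g(tau - D)` (the B-integrand).
#'
#' @param window a [learning_window()].
#' @param f,g correlation kernels (no delta kernels).
#' @param delay_D delay in ms.
#' @param taus lag grid; default covers 5 window time constants.
#' @param path output CSV path.
#' @return the data frame, invisibly.
#' @export
export_kernel_profile <- function(window, f, g, delay_D = 5,
                                  taus = NULL, path) {
  if (is.null(taus))
    taus <- seq(-5 * window$tau_stdp, 5 * window$tau_stdp + delay_D,
                length.out = 501)
  df <- data.frame(
    tau = taus,
    L = eval_window(window, taus),
    f = eval_kernel(f, taus),
    g = eval_kernel(g, taus - delay_D)
  )
  df$integrand <- df$L * df$g
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
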