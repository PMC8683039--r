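# Independent oracles used across tests.  These deliberately avoid the
# package's own computational paths.

# All-pairs additive STDP: sum the learning window over every (pre, post)
# spike pair, in the simulator convention dt = t_pre - t_post with the
# dt = 0 boundary on the depression branch.  No weight bounds.
all_pairs_stdp <- function(pre_times, post_times, a_plus, a_minus,
                           tau_stdp) {
  dw <- 0
  for (tp in pre_times) {
    for (to in post_times) {
      dt <- tp - to
      dw <- dw + if (dt >= 0) -a_minus * exp(-dt / tau_stdp)
                 else a_plus * exp(dt / tau_stdp)
    }
  }
  dw
}

# Mean of a Gaussian(mu, sd) rectified at zero, by quadrature.
rectified_gaussian_mean <- function(mu, sd) {
  stats::integrate(function(x) x * stats::dnorm(x, mu, sd), 0, Inf,
                   rel.tol = 1e-10)$value
}

# Closed-form least squares: minimize <(W'x - beta V'x')^2> given the
# zero-lag covariances, via the normal equations.
normal_equations_W <- function(cov_direct, cov_cross, V, beta) {
  drop(beta * solve(cov_direct, cov_cross %*% V))
}

# Dense matrix-exponential solution of a linear ODE dy/dt = M y.
expm_solution <- function(M, y0, times) {
  t(vapply(times, function(t)
    as.numeric(Matrix::expm(M * t) %*% y0), numeric(length(y0))))
}
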