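#' Output-gene dynamics parameters
#'
#' The concentration of the output TF follows
#' dc3/dt = beta * P_on(c1, c2, c3) - mu * c3, so the reachable output range
#' is \[0, c_max\] with c_max = beta / mu. Absolute time scales are
#' irrelevant to all steady-state measures; time is expressed in units of
#' 1/mu (tau0).
#'
#' @param beta maximal production rate (nM per tau0); default 1000.
#' @param mu degradation rate constant (1/tau0); default 1, defining tau0.
#' @param eps_ss steady-state tolerance (nM): a state c is accepted when
#'   |beta P_on - mu c| < mu * eps_ss. Default 0.1.
#' @param eps_rt response-time proximity threshold (nM); default 1.
#' @param t_max maximum integration time (tau0) before a non-convergence
#'   flag; default 200.
#' @param V volume factor converting concentration to copy number
#'   (molecules per nM); default 1.
#' @param fd_step finite-difference step (nM) for the derivatives of the
#'   production rate used by the noise approximation; default 0.1.
#' @export
dynamics_params <- function(beta = 1000, mu = 1, eps_ss = 0.1, eps_rt = 1,
                            t_max = 200, V = 1, fd_step = 0.1) {
  stopifnot(beta > 0, mu > 0, eps_ss > 0, eps_rt > 0, t_max > 0, V > 0,
            fd_step > 0)
  structure(list(beta = beta, mu = mu, c_max = beta / mu, eps_ss = eps_ss,
                 eps_rt = eps_rt, t_max = t_max, V = V, fd_step = fd_step),
            class = "dynamics_params")
}

#' Steady-state output concentration
#'
#' The limit point of dc3/dt = beta * P_on - mu * c3 started from `c3_init`.
#' Because the dynamics are one-dimensional and bounded, the flow converges
#' monotonically to the first stable fixed point in the direction of the
#' initial drift; the solver brackets that root and refines it by bisection
#' with a secant polish, then verifies the residual |beta P_on - mu c| <
#' mu * eps_ss.
#'
#' @param x a [genotype()] or [site_model()].
#' @param models a [model_set()].
#' @param c1,c2 input TF concentrations (nM).
#' @param c3_init initial output concentration (nM) in \[0, c_max\].
#' @return c3* in nM.
#' @export
steady_state <- function(x, models, c1, c2, c3_init = 0) {
  dyn <- models$dyn
  if (c3_init < 0 || c3_init > dyn$c_max)
    stop("c3_init must lie in [0, c_max]")
  em <- engine_model(x, models)
  ss <- .steady_state_cpp(em, c1, c2, c3_init, dyn$beta, dyn$mu, dyn$eps_ss)
  resid <- dyn$beta * .pon_cpp(em, c(c1, c2, ss)) - dyn$mu * ss
  if (abs(resid) >= dyn$mu * dyn$eps_ss)
    stop("steady-state solver failed the residual check")
  ss
}

#' Detect bistability at one input condition
#'
#' Solves for the steady state from both extreme initial conditions
#' (c3 = 0 and c3 = c_max). If the two limits differ by more than `eps_ss`
#' the response at this input is history-dependent and the squared
#' difference (in units of c0^2) is returned as a fitness penalty.
#'
#' @inheritParams steady_state
#' @param c0 normalization concentration (nM); default 1.
#' @return list with `ss_low`, `ss_high` (nM) and `penalty` (dimensionless).
#' @export
detect_bistability <- function(x, models, c1, c2, c0 = 1) {
  dyn <- models$dyn
  em <- engine_model(x, models)
  lo <- .steady_state_cpp(em, c1, c2, 0, dyn$beta, dyn$mu, dyn$eps_ss)
  hi <- .steady_state_cpp(em, c1, c2, dyn$c_max, dyn$beta, dyn$mu, dyn$eps_ss)
  pen <- if (abs(hi - lo) > dyn$eps_ss) (hi - lo)^2 / c0^2 else 0
  list(ss_low = lo, ss_high = hi, penalty = pen)
}

#' All stable fixed points of the output dynamics
#'
#' Dense sign-change scan of g(c) = beta * P_on(c) - mu * c over
#' \[0, c_max\], with each bracketed root refined by [stats::uniroot()].
#' Stable roots are the down-crossings of g (and stable boundary points).
#'
#' @inheritParams steady_state
#' @param n_grid number of scan points (>= 100); default 400.
#' @return numeric vector of stable fixed points (nM), increasing.
#' @export
bistability_scan <- function(x, models, c1, c2, n_grid = 400L) {
  stopifnot(n_grid >= 100L)
  dyn <- models$dyn
  em <- engine_model(x, models)
  cs <- seq(0, dyn$c_max, length.out = n_grid)
  g <- dyn$beta * .pon_vec_cpp(em, c1, c2, cs) - dyn$mu * cs
  gf <- function(c) dyn$beta * .pon_cpp(em, c(c1, c2, c)) - dyn$mu * c
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1L)) {
    if (g[i] > 0 && g[i + 1L] <= 0) { # down-crossing: stable
      r <- stats::uniroot(gf, c(cs[i], cs[i + 1L]), tol = 1e-9)$root
      roots <- c(roots, r)
    }
  }
  # boundary fixed point at 0 is stable when the drift at 0+ is negative
  if (g[1] <= 0) roots <- c(0, roots)
  sort(unique(roots))
}

#' Time to reach the steady state
#'
#' Integrates dc3/dt = beta * P_on - mu * c3 from `c3_init` with an adaptive
#' embedded Runge-Kutta scheme (relative tolerance 1e-8) and returns the
#' first time at which |c3(t) - c3*| < eps_rt, where c3* is the steady state
#' reached from the same initial condition.
#'
#' @inheritParams steady_state
#' @return time in tau0 units, or `NA` (non-convergence within `t_max`).
#' @export
response_time <- function(x, models, c1, c2, c3_init) {
  dyn <- models$dyn
  em <- engine_model(x, models)
  ss <- .steady_state_cpp(em, c1, c2, c3_init, dyn$beta, dyn$mu, dyn$eps_ss)
  .response_time_cpp(em, c1, c2, c3_init, ss, dyn$beta, dyn$mu,
                     dyn$eps_rt, dyn$t_max)
}

#' Stationary intrinsic-noise magnitude
#'
#' Small-noise (linear-noise) approximation of the stationary standard
#' deviation of the output concentration around a stable fixed point. With
#' production f(c3) = beta * P_on and degradation mu * c3, the birth-death
#' noise intensity is (f + mu c3) / (2V) and
#' sigma^2 = (f(c3*) + mu c3*) / (2 V (mu - f'(c3*))).
#' For a constitutive gene (f' = 0) this reduces exactly to the Poisson
#' copy-number limit sigma = sqrt(c3*/V). Derivatives are computed by
#' central finite differences (step `fd_step`); the second derivative is
#' attached as a diagnostic together with the implied next-order shift of
#' the mean, f'' sigma^2 / (2 (mu - f')).
#'
#' @inheritParams steady_state
#' @return sigma in nM (attributes `f1`, `f2`, `mean_shift`), or `NA` with a
#'   warning when the fixed point is marginally stable (mu - f' <= 0), which
#'   callers treat as maximal noise.
#' @export
intrinsic_noise_sd <- function(x, models, c1, c2) {
  dyn <- models$dyn
  em <- engine_model(x, models)
  ss <- .steady_state_cpp(em, c1, c2, 0, dyn$beta, dyn$mu, dyn$eps_ss)
  h <- dyn$fd_step
  f <- function(c) dyn$beta * .pon_cpp(em, c(c1, c2, max(c, 0)))
  f0 <- f(ss); fp <- f(ss + h); fm <- f(ss - h)
  f1 <- (fp - fm) / (2 * h)
  f2 <- (fp - 2 * f0 + fm) / h^2
  if (dyn$mu - f1 <= 0) {
    warning("marginal stability: mu - f' <= 0; returning NA (maximal noise)")
    return(structure(NA_real_, f1 = f1, f2 = f2, mean_shift = NA_real_))
  }
  var <- (f0 + dyn$mu * ss) / (2 * dyn$V * (dyn$mu - f1))
  structure(sqrt(var), f1 = f1, f2 = f2,
            mean_shift = f2 * var / (2 * (dyn$mu - f1)))
}

#' Steady-state response surface on an input grid
#'
#' Evaluates [detect_bistability()] at every grid point; the surface value
#' is the steady state reached from c3 = 0 (the convention used throughout
#' the fitness machinery), with the high-start state and the bistability
#' penalty recorded alongside.
#'
#' @inheritParams steady_state
#' @param grid data.frame/matrix with columns c1, c2 (nM); see
#'   [evaluation_grid()].
#' @param c0 normalization concentration (nM).
#' @return a `response_surface`: data.frame with c1, c2, c3 (the output),
#'   ss_high and penalty.
#' @export
response_surface <- function(x, models, grid, c0 = 1) {
  grid <- as.matrix(grid)
  if (nrow(grid) == 0) stop("empty evaluation grid")
  dyn <- models$dyn
  em <- engine_model(x, models)
  res <- .score_gate_cpp(em, grid, numeric(nrow(grid)), dyn$beta, dyn$mu,
                         dyn$eps_ss, c0)
  pen <- (res$ss_high - res$ss_low)^2 / c0^2
  pen[abs(res$ss_high - res$ss_low) <= dyn$eps_ss] <- 0
  structure(data.frame(c1 = grid[, 1], c2 = grid[, 2], c3 = res$ss_low,
                       ss_high = res$ss_high, penalty = pen),
            class = c("response_surface", "data.frame"))
}
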