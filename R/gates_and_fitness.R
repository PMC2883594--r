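GATE_NAMES <- c("AND", "OR", "NOR", "NAND", "ACT", "IN",
                "LACT", "LIN", "MEAN", "NMEAN")

#' Transcriptional gate specification
#'
#' The ten goal functions that the evolutionary algorithm selects for, over
#' the input domain \[0, 1000\] nM. The six logic gates (AND, OR, NOR, NAND,
#' ACT, IN) map inputs classified as low/high at the 500 nM threshold to the
#' goal levels low = 0 nM / high = 1000 nM; inputs >= 500 nM count as high.
#' The four graded gates are linear: LACT responds as c1, LIN as 1000 - c1,
#' MEAN as (c1 + c2)/2 and NMEAN as 1000 - (c1 + c2)/2. ACT, IN, LACT and
#' LIN take one input; the rest take two.
#'
#' @param name gate name.
#' @param threshold logic high/low threshold (nM).
#' @param level_high goal "high" output level (nM); low is 0.
#' @export
gate_spec <- function(name = GATE_NAMES, threshold = 500,
                      level_high = 1000) {
  name <- match.arg(name)
  arity <- if (name %in% c("ACT", "IN", "LACT", "LIN")) 1L else 2L
  structure(list(name = name, arity = arity, threshold = threshold,
                 level_high = level_high),
            class = "gate_spec")
}

#' Goal output of a gate
#'
#' @param gate a [gate_spec()].
#' @param c1,c2 input concentrations (nM) in \[0, 1000\]; `c2` is ignored
#'   for one-input gates. Vectorized.
#' @return goal output(s) in nM.
#' @export
goal_function <- function(gate, c1, c2 = 0) {
  if (any(c1 < 0 | c1 > 1000) || any(c2 < 0 | c2 > 1000))
    stop("gate inputs must lie in [0, 1000] nM")
  hi <- gate$level_high
  h1 <- c1 >= gate$threshold
  h2 <- c2 >= gate$threshold
  switch(gate$name,
    AND   = ifelse(h1 & h2, hi, 0),
    OR    = ifelse(h1 | h2, hi, 0),
    NOR   = ifelse(!h1 & !h2, hi, 0),
    NAND  = ifelse(h1 & h2, 0, hi),
    ACT   = ifelse(h1, hi, 0),
    IN    = ifelse(h1, 0, hi),
    LACT  = c1 + 0 * c2,
    LIN   = hi - c1 + 0 * c2,
    MEAN  = (c1 + c2) / 2,
    NMEAN = hi - (c1 + c2) / 2)
}

#' Fitness evaluation grid of a gate
#'
#' Two-input gates are evaluated on the 16 combinations of
#' \{125, 375, 625, 875\} nM (two concentrations per logic class, symmetric
#' about the 500 nM threshold); one-input gates on 7 values equally spaced
#' over \[0, 1000\] nM. The four corner conditions (c1, c2) in \{0, 1000\}^2
#' are used by the footprinting analysis.
#'
#' @param gate a [gate_spec()], or an arity (1 or 2).
#' @param type "fitness" for the scoring grid, "corners" for the footprint
#'   corner conditions.
#' @return data.frame with columns c1, c2 (nM; c2 = 0 for one-input gates).
#' @export
evaluation_grid <- function(gate, type = c("fitness", "corners")) {
  type <- match.arg(type)
  arity <- if (inherits(gate, "gate_spec")) gate$arity else as.integer(gate)
  if (type == "corners")
    return(expand.grid(c1 = c(0, 1000), c2 = c(0, 1000)))
  if (arity == 2L) {
    v <- c(125, 375, 625, 875)
    expand.grid(c1 = v, c2 = v)
  } else {
    data.frame(c1 = seq(0, 1000, length.out = 7), c2 = 0)
  }
}

#' Fitness weights and the selection-pressure ramp
#'
#' @param S0 offset making all realized scores positive; default 1e8.
#' @param c0 normalization concentration (nM) making E_RF dimensionless.
#' @param lambda_rt,lambda_noise final weights on the response-time and
#'   noise measures (their units make the products dimensionless like E_RF).
#' @param t_ramp number of cycles over which the lambda weights ramp
#'   linearly from 0 to their final values; default 500.
#' @export
fitness_weights <- function(S0 = 1e8, c0 = 1, lambda_rt = 0,
                            lambda_noise = 0, t_ramp = 500L) {
  stopifnot(S0 > 0, c0 > 0, lambda_rt >= 0, lambda_noise >= 0, t_ramp >= 1)
  structure(list(S0 = S0, c0 = c0, lambda_rt = lambda_rt,
                 lambda_noise = lambda_noise, t_ramp = as.integer(t_ramp)),
            class = "fitness_weights")
}

#' Selection-pressure ramp
#'
#' The weight on a dynamical fitness component at cycle `t`: zero at t = 0,
#' rising linearly to `lambda_max` at `t_ramp` cycles and constant after.
#' Ramping avoids the local optimum in which a dysfunctional, silent gate is
#' retained purely because its response times are trivially short.
#'
#' @param t cycle index (>= 0). Vectorized.
#' @param lambda_max final weight.
#' @param t_ramp ramp length in cycles.
#' @export
lambda_ramp <- function(t, lambda_max, t_ramp = 500L) {
  stopifnot(all(t >= 0))
  lambda_max * pmin(t / t_ramp, 1)
}

#' Response-function deviation measure E_RF
#'
#' Sum over the gate's evaluation grid of the squared deviations between the
#' steady-state output and the goal function, in units of c0^2, plus the
#' bistability penalty accumulated by [detect_bistability()] at each point.
#'
#' @param surface a [response_surface()] evaluated on the gate's grid.
#' @param gate a [gate_spec()].
#' @param c0 normalization concentration (nM).
#' @return E_RF (dimensionless).
#' @export
fitness_rf <- function(surface, gate, c0 = 1) {
  g <- goal_function(gate, surface$c1, surface$c2)
  sum((surface$c3 - g)^2) / c0^2 + sum(surface$penalty)
}

#' Response-time measure E_RT
#'
#' Sum of the times to reach the steady state from both extreme initial
#' conditions (c3 = 0 and c3 = c_max) at every grid point: 32 response
#' times for a two-input gate, 14 for a one-input gate.
#'
#' @param x a [genotype()] or [site_model()].
#' @param models a [model_set()].
#' @param grid evaluation grid (see [evaluation_grid()]).
#' @return E_RT in tau0 units, or `NA` when any integration fails
#'   (treated as the worst score by the evolutionary engine).
#' @export
fitness_rt <- function(x, models, grid) {
  dyn <- models$dyn
  em <- engine_model(x, models)
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    for (init in c(0, dyn$c_max)) {
      ss <- .steady_state_cpp(em, grid$c1[i], grid$c2[i], init,
                              dyn$beta, dyn$mu, dyn$eps_ss)
      rt <- .response_time_cpp(em, grid$c1[i], grid$c2[i], init, ss,
                               dyn$beta, dyn$mu, dyn$eps_rt, dyn$t_max)
      if (is.na(rt)) return(NA_real_)
      tot <- tot + rt
    }
  }
  tot
}

#' Intrinsic-noise measure E_N
#'
#' Sum over the evaluation grid of the stationary noise standard deviation
#' of the output ([intrinsic_noise_sd()]).
#'
#' @inheritParams fitness_rt
#' @return E_N in nM, or `NA` on marginal stability (worst score).
#' @export
fitness_noise <- function(x, models, grid) {
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    s <- suppressWarnings(
      intrinsic_noise_sd(x, models, grid$c1[i], grid$c2[i]))
    if (is.na(s)) return(NA_real_)
    tot <- tot + as.numeric(s)
  }
  tot
}

#' Composite fitness score
#'
#' S = S0 - E_RF - lambda_RT(t) * E_RT - lambda_N(t) * E_N, with the lambda
#' weights ramped by [lambda_ramp()]. S0 is an arbitrary offset whose only
#' role is to keep every realized score positive; it does not affect
#' selection order.
#'
#' @param e_rf,e_rt,e_n fitness components (>= 0); `e_rt`/`e_n` may be 0
#'   when not selected for.
#' @param weights a [fitness_weights()].
#' @param t cycle index for the ramp.
#' @return S > 0.
#' @export
fitness_total <- function(e_rf, e_rt = 0, e_n = 0,
                          weights = fitness_weights(), t = Inf) {
  stopifnot(e_rf >= 0, e_rt >= 0, e_n >= 0)
  s <- weights$S0 - e_rf -
    lambda_ramp(min(t, weights$t_ramp), weights$lambda_rt, weights$t_ramp) * e_rt -
    lambda_ramp(min(t, weights$t_ramp), weights$lambda_noise, weights$t_ramp) * e_n
  if (s <= 0)
    stop("fitness score <= 0: S0 is configured too small for this population")
  s
}
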