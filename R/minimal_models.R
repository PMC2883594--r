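MINIMAL_LAYOUTS <- c("act_1site", "act_2site_coop", "cond_auto_act",
                     "rep_2site_coop", "rep_2site_coop_plus_autoact",
                     "lin_rep_unequal_sites")

#' Stylized minimal regulatory models
#'
#' Six site layouts with explicit dissociation constants, used to study the
#' design principles that recur in evolved gates in closed form:
#'
#' * `act_1site`: one TF1 activator site recruiting RNAP.
#' * `act_2site_coop`: a proximal recruiting TF1 site plus a distal TF1 site
#'   that binds cooperatively but is too far to recruit.
#' * `cond_auto_act`: as above, but the distal site is an operator for the
#'   output TF3 - conditional auto-activation: TF3 activates only by
#'   stabilizing TF1 on its recruiting site.
#' * `rep_2site_coop`: two cooperatively bound TF1 repressor sites
#'   overlapping the promoter.
#' * `rep_2site_coop_plus_autoact`: the repression pair plus a TF3
#'   activator site (auto-activation competing with repression).
#' * `lin_rep_unequal_sites`: the same layout with one repressor site many
#'   times weaker, yielding an approximately linear repression curve.
#'
#' A single factor `omega` plays both the TF-TF cooperativity and the
#' TF-RNAP recruitment role. `p` is the RNAP concentration normalized by its
#' promoter dissociation constant (the basal promoter weight).
#'
#' @param layout one of the six layout names.
#' @param K1,K1b,K3 dissociation constants (nM) of the TF1 site(s) and the
#'   TF3 site, where applicable. `K1b` defaults to `K1` (30 * K1 for the
#'   unequal-sites linear layout); set a constant to `Inf` to delete the
#'   site.
#' @param p normalized RNAP weight (dimensionless, > 0).
#' @param omega cooperativity/recruitment factor (>= 1).
#' @param beta,mu production and degradation constants (c_max = beta/mu).
#' @export
minimal_model_spec <- function(layout = MINIMAL_LAYOUTS, K1 = 100,
                               K1b = NULL, K3 = 100, p = 1, omega = 50,
                               beta = 1000, mu = 1) {
  layout <- match.arg(layout)
  if (is.null(K1b))
    K1b <- if (layout == "lin_rep_unequal_sites") 30 * K1 else K1
  stopifnot(K1 > 0, K1b > 0, K3 > 0, p > 0, omega >= 1, beta > 0, mu > 0)
  structure(list(layout = layout, K1 = K1, K1b = K1b, K3 = K3, p = p,
                 omega = omega, beta = beta, mu = mu),
            class = "minimal_model_spec")
}

#' Closed-form promoter occupancy of a minimal model
#'
#' Returns the layout's occupancy function P_on(c1, c3) assembled from the
#' explicit configuration sums (vectorized in both arguments).
#'
#' @param spec a [minimal_model_spec()].
#' @export
minimal_pon <- function(spec) {
  w <- spec$omega; p <- spec$p
  switch(spec$layout,
    act_1site = function(c1, c3 = 0) {
      u <- c1 / spec$K1
      zon <- p * (1 + w * u)
      zon / (zon + 1 + u)
    },
    act_2site_coop = function(c1, c3 = 0) {
      u <- c1 / spec$K1; ub <- c1 / spec$K1b
      zon <- p * (1 + w * u + ub + w^2 * u * ub)
      zoff <- 1 + u + ub + w * u * ub
      zon / (zon + zoff)
    },
    cond_auto_act = function(c1, c3) {
      u <- c1 / spec$K1; v <- c3 / spec$K3
      zon <- p * (1 + w * u + v + w^2 * u * v)
      zoff <- 1 + u + v + w * u * v
      zon / (zon + zoff)
    },
    rep_2site_coop = function(c1, c3 = 0) {
      u <- c1 / spec$K1; ub <- c1 / spec$K1b
      zoff <- 1 + u + ub + w * u * ub
      p / (p + zoff)
    },
    rep_2site_coop_plus_autoact = ,
    lin_rep_unequal_sites = function(c1, c3) {
      u <- c1 / spec$K1; ub <- c1 / spec$K1b; v <- c3 / spec$K3
      zon <- p * (1 + w * v)
      zoff <- (1 + u + ub + w * u * ub) * (1 + v)
      zon / (zon + zoff)
    })
}

has_feedback <- function(spec) {
  spec$layout %in% c("cond_auto_act", "rep_2site_coop_plus_autoact",
                     "lin_rep_unequal_sites") && is.finite(spec$K3)
}

# First stable root of beta*P_on(c) - mu*c encountered from `from`.
stable_root <- function(pon_c3, cmax, from = 0, tol = 1e-10) {
  g <- function(c) cmax * pon_c3(c) - c
  c0 <- min(max(from, 0), cmax)
  g0 <- g(c0)
  if (abs(g0) < 1e-12 * max(1, c0)) return(c0)
  up <- g0 > 0
  step <- 1e-3
  prev <- c0
  repeat {
    nxt <- if (up) min(prev + step, cmax) else max(prev - step, 0)
    gn <- g(nxt)
    if ((up && gn <= 0) || (!up && gn >= 0))
      return(stats::uniroot(g, sort(c(prev, nxt)), tol = tol)$root)
    if (nxt == 0 || nxt == cmax) return(nxt)
    prev <- nxt
    step <- step * 1.7
  }
}

#' Steady-state response of a minimal model
#'
#' Solves the self-consistency condition beta * P_on(c1, c3) = mu * c3 for
#' the layout's occupancy function and returns the stable fixed point
#' reached from c3 = 0. If the high-start branch differs (bistable regime),
#' the result carries a `bistable` attribute and both branches.
#'
#' @param spec a [minimal_model_spec()].
#' @param c1 input concentration(s), nM (vectorized).
#' @return c3* in nM; attributes `bistable` (logical vector) and `branches`
#'   (matrix with low/high columns).
#' @export
minimal_response <- function(spec, c1) {
  stopifnot(all(c1 >= 0))
  pon <- minimal_pon(spec)
  cmax <- spec$beta / spec$mu
  if (!has_feedback(spec)) {
    v <- cmax * pon(c1, 0)
    return(structure(v, bistable = rep(FALSE, length(v)),
                     branches = cbind(low = v, high = v)))
  }
  lo <- hi <- numeric(length(c1))
  for (i in seq_along(c1)) {
    f <- function(c3) pon(c1[i], c3)
    lo[i] <- stable_root(f, cmax, from = 0)
    hi[i] <- stable_root(f, cmax, from = cmax)
  }
  bis <- abs(hi - lo) > 1e-6 * cmax
  structure(lo, bistable = bis, branches = cbind(low = lo, high = hi))
}

#' Logarithmic sensitivity of a response
#'
#' S(c1) = |d ln c3* / d ln c1|, estimated by a central log-log finite
#' difference with multiplicative step 1.01. The sensitivity of a Hill
#' function is bounded by its Hill coefficient; responses exploiting
#' conditional auto-activation can exceed any such bound.
#'
#' @param responder a [minimal_model_spec()] or a function c1 -> c3*.
#' @param c1 input concentration(s) > 0 (vectorized).
#' @param step multiplicative step factor; default 1.01.
#' @export
sensitivity <- function(responder, c1, step = 1.01) {
  stopifnot(all(c1 > 0), step > 1)
  f <- if (inherits(responder, "minimal_model_spec")) {
    function(c) as.numeric(minimal_response(responder, c))
  } else responder
  up <- f(c1 * step)
  dn <- f(c1 / step)
  if (any(up <= 0) || any(dn <= 0))
    stop("sensitivity undefined for a zero response")
  abs(log(up) - log(dn)) / (2 * log(step))
}

log_grid <- function(range, per_decade = 20) {
  n <- max(2L, ceiling(per_decade * log10(range[2] / range[1])) + 1L)
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Maximal sensitivity over input and parameter sweeps
#'
#' Maximizes S(c1) over a logarithmic c1 grid (refined around the best
#' point) and over a logarithmic sweep of the model parameters. For the
#' two-site repression layout without auto-activation the result can never
#' exceed 2 (the number of repressor sites); with an auto-activation site
#' the sweep finds points well above 2; for conditional auto-activation the
#' supremum grows without bound as the basal promoter weight decreases.
#'
#' @param spec a [minimal_model_spec()]; swept parameters override its
#'   values.
#' @param c1_range range of input concentrations (nM), default c(1, 10000).
#' @param param_ranges named list of sweep ranges; recognized names are
#'   `K1` (applied to K1 and, unless `tie_K1b = FALSE`, to K1b), `K1b`,
#'   `K3`, `omega` and `p`. Fixed-value parameters may be given as length-1
#'   vectors.
#' @param n_c1 number of c1 grid points (>= 200 by default).
#' @param per_decade sweep resolution, grid points per decade; default 20.
#' @param tie_K1b sweep K1b together with K1 (default TRUE).
#' @return list with `s_max`, the maximizing `c1`, `params`, and `curve`
#'   (the sensitivity curve at the optimal parameter point).
#' @export
max_sensitivity <- function(spec, c1_range = c(1, 10000),
                            param_ranges = list(), n_c1 = 201L,
                            per_decade = 20, tie_K1b = TRUE) {
  stopifnot(length(param_ranges) == 0 || !is.null(names(param_ranges)))
  c1s <- exp(seq(log(c1_range[1]), log(c1_range[2]), length.out = n_c1))
  sweep_of <- function(name) {
    r <- param_ranges[[name]]
    if (is.null(r)) return(spec[[name]])
    if (length(r) == 1) return(r)
    log_grid(sort(r), per_decade)
  }
  grids <- list(K1 = sweep_of("K1"), K1b = sweep_of("K1b"),
                K3 = sweep_of("K3"), omega = sweep_of("omega"),
                p = sweep_of("p"))
  if (tie_K1b && is.null(param_ranges$K1b)) grids$K1b <- NA # tied marker
  combos <- expand.grid(K1 = grids$K1, K1b = grids$K1b, K3 = grids$K3,
                        omega = grids$omega, p = grids$p)
  best <- list(s_max = -Inf)
  for (i in seq_len(nrow(combos))) {
    sp <- spec
    sp$K1 <- combos$K1[i]
    sp$K1b <- if (is.na(combos$K1b[i])) combos$K1[i] else combos$K1b[i]
    sp$K3 <- combos$K3[i]
    sp$omega <- combos$omega[i]
    sp$p <- combos$p[i]
    s <- sensitivity(sp, c1s)
    j <- which.max(s)
    if (s[j] > best$s_max)
      best <- list(s_max = s[j], c1 = c1s[j], spec = sp)
  }
  # refine c1 around the maximizer at the best parameter point
  lo <- max(c1_range[1], best$c1 / 1.5)
  hi <- min(c1_range[2], best$c1 * 1.5)
  fine <- exp(seq(log(lo), log(hi), length.out = 101L))
  s_fine <- sensitivity(best$spec, fine)
  j <- which.max(s_fine)
  if (s_fine[j] > best$s_max) {
    best$s_max <- s_fine[j]
    best$c1 <- fine[j]
  }
  curve <- data.frame(c1 = c1s, S = sensitivity(best$spec, c1s))
  list(s_max = best$s_max, c1 = best$c1,
       params = best$spec[c("K1", "K1b", "K3", "omega", "p")],
       curve = curve)
}

#' Map a minimal model onto the full sequence-level engine
#'
#' Places explicit-Kd sites on a synthetic region so that the engine's
#' distance rules reproduce the minimal model's interaction pattern exactly:
#' the proximal site sits 2 bp upstream of the RNAP footprint (recruiting),
#' the distal site 12 bp further (cooperative with the proximal site but too
#' far from the footprint to recruit), repressor sites sit inside the
#' footprint 1 bp apart, and the auto-activation site of the repression
#' layouts sits 14 bp upstream of the footprint (recruiting, but beyond
#' cooperation range of the repressors). The minimal models are thereby
#' special cases of the general machinery, which serves as their oracle.
#'
#' @param spec a [minimal_model_spec()].
#' @param L region length (bp); default 80.
#' @param l_tf site length (bp); default 9.
#' @return list with `x` (a [site_model()]) and `models` (a [model_set()]
#'   with omega_coop = omega_act = spec$omega and the spec's dynamics).
#' @export
minimal_to_engine <- function(spec, L = 80L, l_tf = 9L) {
  fp <- footprint_coords(L)
  prox <- fp$lo - 2L - l_tf       # gap 2 <= d_act: recruits
  dist <- prox - 12L - l_tf       # gap 12 <= d_coop, 23 > d_act
  repA <- fp$lo + 5L
  repB <- repA + l_tf + 1L        # gap 1: cooperative pair in the footprint
  auto <- fp$lo - 14L - l_tf      # gap 14 <= d_act, 19 > d_coop to repA
  sites <- switch(spec$layout,
    act_1site = data.frame(tf = "TF1", start = prox, kd = spec$K1),
    act_2site_coop = data.frame(tf = c("TF1", "TF1"),
                                start = c(prox, dist),
                                kd = c(spec$K1, spec$K1b)),
    cond_auto_act = data.frame(tf = c("TF1", "TF3"),
                               start = c(prox, dist),
                               kd = c(spec$K1, spec$K3)),
    rep_2site_coop = data.frame(tf = c("TF1", "TF1"),
                                start = c(repA, repB),
                                kd = c(spec$K1, spec$K1b)),
    rep_2site_coop_plus_autoact = ,
    lin_rep_unequal_sites = data.frame(
      tf = c("TF1", "TF1", "TF3"),
      start = c(repA, repB, auto),
      kd = c(spec$K1, spec$K1b, spec$K3)))
  sites <- sites[is.finite(sites$kd), , drop = FALSE]
  x <- site_model(L, sites, q_R = spec$p, l_tf = l_tf)
  models <- model_set(thermo = thermo_params(omega_coop = spec$omega,
                                             omega_act = spec$omega),
                      dyn = dynamics_params(beta = spec$beta, mu = spec$mu))
  list(x = x, models = models)
}

#' Optimize binding-site affinities of a minimal model against a gate
#'
#' Derivative-free (Nelder-Mead) local minimization of the
#' response-function deviation E_RF (including the bistability penalty) over
#' the log10 dissociation constants of the layout's sites, from multiple
#' seeded random restarts. Affinities are constrained to
#' \[1, 10^6\] nM; the upper bound models effective removal of a site.
#'
#' @param spec a [minimal_model_spec()]; its omega, p and dynamics are held
#'   fixed.
#' @param gate a one-input [gate_spec()] (e.g. ACT, LACT, LIN).
#' @param grid evaluation grid (default: the gate's 7-point grid).
#' @param n_restarts number of random restarts (>= 1); default 10.
#' @param seed RNG seed for the restart draws.
#' @return list with `spec` (optimized), `e_rf`, and `starts` (the E_RF of
#'   every restart). Never worse than the best evaluated starting point.
#' @export
optimize_affinities <- function(spec, gate, grid = NULL, n_restarts = 10L,
                                seed = 1L) {
  if (gate$arity != 1L)
    stop("affinity optimization is defined for one-input gates")
  if (is.null(grid)) grid <- evaluation_grid(gate)
  keys <- switch(spec$layout,
    act_1site = "K1",
    act_2site_coop = c("K1", "K1b"),
    cond_auto_act = c("K1", "K3"),
    rep_2site_coop = c("K1", "K1b"),
    rep_2site_coop_plus_autoact = c("K1", "K1b", "K3"),
    lin_rep_unequal_sites = c("K1", "K1b", "K3"))
  goals <- goal_function(gate, grid$c1, grid$c2)
  clamp <- function(th) pmin(pmax(th, 0), 6)
  obj <- function(theta) {
    sp <- spec
    sp[keys] <- as.list(10^clamp(theta))
    r <- minimal_response(sp, grid$c1)
    br <- attr(r, "branches")
    sum((as.numeric(r) - goals)^2) + sum((br[, 2] - br[, 1])^2)
  }
  set.seed(seed)
  inits <- matrix(stats::runif(n_restarts * length(keys), 0, 6),
                  nrow = n_restarts)
  inits[1, ] <- clamp(log10(unlist(spec[keys]))) # include the given spec
  best <- list(value = Inf)
  starts <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    v0 <- obj(inits[r, ])
    starts[r] <- v0
    fit <- if (length(keys) == 1L) {
      # Nelder-Mead degenerates in one dimension; use bounded Brent
      stats::optim(inits[r, ], obj, method = "Brent", lower = 0, upper = 6,
                   control = list(maxit = 500))
    } else {
      stats::optim(inits[r, ], obj, method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-12))
    }
    cand <- if (fit$value <= v0) fit else list(par = inits[r, ], value = v0)
    if (cand$value < best$value) best <- cand
  }
  out <- spec
  out[keys] <- as.list(10^clamp(best$par))
  list(spec = out, e_rf = best$value, starts = starts)
}

#' Verify the total-derivative identity of linear repression
#'
#' Along the fixed-point branch c3*(c1) defined by c3 = Phi(c1, c3) with
#' Phi = (beta/mu) P_on, the total derivative obeys
#' dc3*/dc1 = (dPhi/dc1) / (1 - dPhi/dc3). Without auto-regulation the
#' denominator equals 1 and the slope is a Hill-type function of c1; with
#' auto-regulation the denominator can flatten the slope, enabling linear
#' repression. Both sides are evaluated numerically (central differences)
#' and the maximal absolute residual is returned.
#'
#' @param spec a [minimal_model_spec()] (repression layouts).
#' @param c1_range input range (nM); default c(1, 1000).
#' @param n number of evaluation points.
#' @return list with `max_resid` and a data.frame `details` (c1, lhs, rhs,
#'   denominator).
#' @export
linear_repression_derivative_check <- function(spec, c1_range = c(1, 1000),
                                               n = 21L) {
  pon <- minimal_pon(spec)
  cmax <- spec$beta / spec$mu
  c1s <- seq(c1_range[1], c1_range[2], length.out = n)
  resp <- function(c1) as.numeric(minimal_response(spec, c1))
  if (any(attr(minimal_response(spec, c1s), "bistable")))
    stop("bistable regime: the fixed-point branch is not single-valued")
  lhs <- rhs <- denom <- numeric(n)
  for (i in seq_len(n)) {
    c1 <- c1s[i]
    h1 <- 1e-3 * max(c1, 1)
    lhs[i] <- (resp(c1 + h1) - resp(max(c1 - h1, 0))) /
      (h1 + min(h1, c1))
    cs <- resp(c1)
    h3 <- 1e-3 * max(cs, 1)
    dPdc1 <- cmax * (pon(c1 + h1, cs) - pon(max(c1 - h1, 0), cs)) /
      (h1 + min(h1, c1))
    dPdc3 <- cmax * (pon(c1, cs + h3) - pon(c1, max(cs - h3, 0))) /
      (h3 + min(h3, cs))
    denom[i] <- 1 - dPdc3
    rhs[i] <- dPdc1 / denom[i]
  }
  list(max_resid = max(abs(lhs - rhs)),
       details = data.frame(c1 = c1s, lhs = lhs, rhs = rhs,
                            denominator = denom))
}
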