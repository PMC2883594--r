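#' Evolutionary run configuration
#'
#' A population of genotypes is subjected to cycles of selection,
#' replication and mutation: the top `survive` fraction (by fitness) is kept
#' unchanged, the population is refilled by duplicating random survivors,
#' and every duplicated offspring is mutated. Keeping the survivors intact
#' makes the best fitness monotone non-decreasing (truncation elitism) while
#' the offspring supply the variation.
#'
#' @param gate a [gate_spec()] (or gate name) defining the goal function.
#' @param pop_size population size N; default 200.
#' @param cycles number of mutation-selection cycles; default 1000.
#' @param survive surviving fraction per cycle; default 0.2.
#' @param p_sub probability of one base substitution per cis region per
#'   mutation event; default 0.5.
#' @param p_indel probability of a single-base insertion or deletion
#'   (50/50) per cis region; default 0.1. The promoter anatomy stays
#'   anchored to the right end, so indels shift upstream sequence only.
#' @param p_tf per-TF probability of one amino-acid point mutation;
#'   default 0.03.
#' @param seed RNG seed; all randomness in a run flows from it.
#' @param weights a [fitness_weights()].
#' @param cis_len initial cis-region length (bp); default 200.
#' @param cis_min,cis_max length bounds enforced on indels.
#' @param l_tf TF binding-domain length; default 9.
#' @param allow_autoreg if FALSE, TF3 binding is removed from the model and
#'   TF3 is never mutated, reproducing the no-auto-regulation regime.
#' @export
evolution_config <- function(gate = "ACT", pop_size = 200L, cycles = 1000L,
                             survive = 0.2, p_sub = 0.5, p_indel = 0.1,
                             p_tf = 0.03, seed = 1L,
                             weights = fitness_weights(),
                             cis_len = 200L, cis_min = 40L, cis_max = 300L,
                             l_tf = 9L, allow_autoreg = TRUE) {
  if (is.character(gate)) gate <- gate_spec(gate)
  stopifnot(survive > 0, survive < 1,
            p_sub >= 0, p_sub <= 1, p_indel >= 0, p_indel <= 1,
            p_tf >= 0, p_tf <= 1, pop_size >= 2, cycles >= 1)
  structure(list(gate = gate, pop_size = as.integer(pop_size),
                 cycles = as.integer(cycles), survive = survive,
                 p_sub = p_sub, p_indel = p_indel, p_tf = p_tf,
                 seed = as.integer(seed), weights = weights,
                 cis_len = as.integer(cis_len), cis_min = as.integer(cis_min),
                 cis_max = as.integer(cis_max), l_tf = as.integer(l_tf),
                 allow_autoreg = isTRUE(allow_autoreg)),
            class = "evolution_config")
}

#' Mutate a genotype
#'
#' With probability `p_sub` one uniformly chosen cis base is replaced by a
#' uniform random nucleotide; with `p_indel` one base is inserted at or
#' deleted from a uniform position (insert/delete 50/50; deletions that
#' would shrink the region below `cis_min` and insertions beyond `cis_max`
#' are skipped); with `p_tf` per TF one uniformly chosen residue is replaced
#' by a uniform *different* amino acid. Draws come from R's RNG stream, so
#' runs are reproducible from the seed.
#'
#' @param g a [genotype()].
#' @param config an [evolution_config()].
#' @export
mutate_genotype <- function(g, config) {
  cis <- strsplit(as.character(g$cis), "")[[1]]
  if (stats::runif(1) < config$p_sub) {
    i <- sample.int(length(cis), 1L)
    cis[i] <- DNA_ALPHABET[sample.int(4L, 1L)]
  }
  if (stats::runif(1) < config$p_indel) {
    if (stats::runif(1) < 0.5) { # insertion
      if (length(cis) < config$cis_max) {
        i <- sample.int(length(cis) + 1L, 1L)
        cis <- append(cis, DNA_ALPHABET[sample.int(4L, 1L)], after = i - 1L)
      }
    } else if (length(cis) > config$cis_min) {
      i <- sample.int(length(cis), 1L)
      cis <- cis[-i]
    }
  }
  tfs <- g$tfs
  for (k in seq_along(tfs)) {
    if (!config$allow_autoreg && tfs[[k]]$id == "TF3") next
    if (stats::runif(1) < config$p_tf) {
      aa <- strsplit(tfs[[k]]$seq, "")[[1]]
      i <- sample.int(length(aa), 1L)
      alt <- setdiff(AA_ALPHABET, aa[i])
      aa[i] <- alt[sample.int(length(alt), 1L)]
      tfs[[k]]$seq <- paste(aa, collapse = "")
    }
  }
  structure(list(cis = structure(paste(cis, collapse = ""),
                                 class = "cis_region"),
                 tfs = tfs),
            class = "genotype")
}

#' Truncation selection and replication
#'
#' Keeps the `ceiling(survive * N)` highest-scoring genotypes (ties broken
#' by input order) and refills to N by duplicating uniformly chosen
#' survivors.
#'
#' @param population list of genotypes.
#' @param scores numeric fitness scores, same length.
#' @param config an [evolution_config()].
#' @return list with `population` (size N; survivors first), `scores`
#'   (scores of the survivors, NA for fresh duplicates), and `n_survive`.
#' @export
select_and_replicate <- function(population, scores, config) {
  n <- length(population)
  if (n == 0L) stop("empty population")
  stopifnot(length(scores) == n, all(is.finite(scores)))
  k <- ceiling(config$survive * n)
  ord <- order(scores, decreasing = TRUE) # stable for ties
  keep <- ord[seq_len(k)]
  refill <- keep[sample.int(k, n - k, replace = TRUE)]
  list(population = c(population[keep], population[refill]),
       scores = c(scores[keep], rep(NA_real_, n - k)),
       n_survive = k, keep = keep, refill = refill)
}

# Score one genotype's fitness components; any evaluation failure is
# recorded as NA (the ramped total then becomes the worst score, 0).
# Components are time-independent; the ramped weights enter only in
# score_from_components, so cached survivor components stay valid.
score_genotype <- function(g, models, config, grid, goals) {
  w <- config$weights
  em <- engine_model(g, models, drop_tf3 = !config$allow_autoreg)
  dyn <- models$dyn
  sc <- .score_gate_cpp(em, as.matrix(grid), goals, dyn$beta, dyn$mu,
                        dyn$eps_ss, w$c0)
  e_rf <- sc$e_rf + sc$penalty
  e_rt <- if (w$lambda_rt > 0) fitness_rt_em(em, dyn, grid) else 0
  e_n <- if (w$lambda_noise > 0 && !is.na(e_rt))
    fitness_noise_em(em, dyn, grid) else 0
  list(e_rf = e_rf, e_rt = e_rt, e_n = e_n)
}

score_from_components <- function(comp, weights, t) {
  if (is.na(comp$e_rt) || is.na(comp$e_n)) return(0) # worst score
  lam_rt <- lambda_ramp(min(t, weights$t_ramp), weights$lambda_rt,
                        weights$t_ramp)
  lam_n <- lambda_ramp(min(t, weights$t_ramp), weights$lambda_noise,
                       weights$t_ramp)
  s <- weights$S0 - comp$e_rf - lam_rt * comp$e_rt - lam_n * comp$e_n
  if (s <= 0)
    stop("fitness score <= 0: S0 is configured too small for this population")
  s
}

# engine_model-level variants used in the evolution inner loop
fitness_rt_em <- function(em, dyn, grid) {
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

fitness_noise_em <- function(em, dyn, grid) {
  tot <- 0
  h <- dyn$fd_step
  for (i in seq_len(nrow(grid))) {
    ss <- .steady_state_cpp(em, grid$c1[i], grid$c2[i], 0,
                            dyn$beta, dyn$mu, dyn$eps_ss)
    f <- function(c) dyn$beta *
      .pon_cpp(em, c(grid$c1[i], grid$c2[i], max(c, 0)))
    f0 <- f(ss); fp <- f(ss + h); fm <- f(ss - h)
    f1 <- (fp - fm) / (2 * h)
    if (dyn$mu - f1 <= 0) return(NA_real_)
    tot <- tot + sqrt((f0 + dyn$mu * ss) / (2 * dyn$V * (dyn$mu - f1)))
  }
  tot
}

#' Run the evolutionary algorithm
#'
#' Initializes `pop_size` random genotypes, then iterates: score every
#' not-yet-scored genotype, record the cycle, select the top fraction and
#' refill the population with mutated duplicates of survivors. Fully
#' reproducible from `config$seed`.
#'
#' @param config an [evolution_config()].
#' @param models a [model_set()].
#' @param log_feedback if TRUE (default), the feedback measure F of the best
#'   genotype is recorded every `feedback_every` cycles (it costs one extra
#'   surface evaluation).
#' @param feedback_every cycle interval for the F column; default 10.
#' @return an `evolution_run`: list with `log` (one row per cycle: cycle,
#'   best and median fitness, components of the best genotype, feedback
#'   measure F), `population` (final genotypes, survivors first), `scores`,
#'   and `config`.
#' @export
evolve <- function(config, models = model_set(), log_feedback = TRUE,
                   feedback_every = 10L) {
  set.seed(config$seed)
  gate <- config$gate
  grid <- evaluation_grid(gate)
  goals <- goal_function(gate, grid$c1, grid$c2)
  pop <- replicate(config$pop_size,
                   random_genotype(lengths = list(cis = config$cis_len,
                                                  tf = config$l_tf)),
                   simplify = FALSE)
  scores <- rep(NA_real_, config$pop_size)
  comp <- vector("list", config$pop_size)
  log <- vector("list", config$cycles)
  ramped <- config$weights$lambda_rt > 0 || config$weights$lambda_noise > 0
  for (t in seq_len(config$cycles) - 1L) {
    todo <- which(is.na(scores))
    for (i in todo)
      comp[[i]] <- score_genotype(pop[[i]], models, config, grid, goals)
    # the ramped weights make fitness time-dependent; survivors keep their
    # cached components but their scores are re-derived every cycle
    redo <- if (ramped) seq_along(pop) else todo
    for (i in redo)
      scores[i] <- score_from_components(comp[[i]], config$weights, t)
    best <- which.max(scores)
    fb <- NA_real_
    if (log_feedback && config$allow_autoreg &&
        (t %% feedback_every == 0L || t == config$cycles - 1L)) {
      fb <- feedback_measure(pop[[best]], models, grid)
    }
    log[[t + 1L]] <- data.frame(
      cycle = t, best_S = scores[best], median_S = stats::median(scores),
      best_e_rf = comp[[best]]$e_rf,
      best_e_rt = comp[[best]]$e_rt, best_e_n = comp[[best]]$e_n,
      best_F = fb)
    sel <- select_and_replicate(pop, scores, config)
    k <- sel$n_survive
    pop <- sel$population
    scores <- sel$scores
    comp <- c(comp[sel$keep], comp[sel$refill])
    for (i in seq_len(config$pop_size)) {
      if (i > k) pop[[i]] <- mutate_genotype(pop[[i]], config)
    }
    # survivors keep their (deterministic) scores; offspring are rescored
  }
  structure(list(log = do.call(rbind, log), population = pop,
                 scores = scores, config = config),
            class = "evolution_run")
}
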