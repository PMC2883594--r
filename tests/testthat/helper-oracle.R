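# Shared fixtures and the independent enumeration oracle used to verify the
# dynamic-programming partition function.

default_models <- model_set()

empty_sites <- function() {
  data.frame(tf = character(0), start = integer(0), kd = numeric(0))
}

# A constitutive explicit-site model: no TF sites, basal weight q.
constitutive_model <- function(q, L = 80L) site_model(L, empty_sites(), q_R = q)

# Exhaustive enumeration of every configuration of non-overlapping
# placements, computing Z_on, Z_off and per-site occupancy numerators
# directly from the configuration-weight rules. Completely independent of
# the package's DP (plain recursion over subsets).
enum_partition <- function(em, conc) {
  placements <- list()
  for (t in 1:3) {
    sp <- em$species[[t]]
    for (i in seq_along(sp$starts)) {
      w <- conc[t] / sp$kd[i]
      if (w > 0)
        placements[[length(placements) + 1L]] <-
          list(t = t, s = sp$starts[i], e = sp$starts[i] + sp$len, w = w)
    }
  }
  n <- length(placements)
  if (n > 0) {
    ord <- order(vapply(placements, `[[`, 0, "s"))
    placements <- placements[ord]
  }
  Z_off <- 0
  Z_on_raw <- 0
  occ_num <- lapply(1:3, function(t) numeric(em$L))
  score <- function(chosen) {
    k <- length(chosen)
    w <- 1
    if (k > 1) {
      for (i in 2:k) {
        gap <- chosen[[i]]$s - chosen[[i - 1]]$e
        if (gap <= em$dc) w <- w * em$wc
      }
    }
    for (p in chosen) w <- w * p$w
    Z_off <<- Z_off + w
    for (p in chosen)
      occ_num[[p$t]][p$s + 1L] <<- occ_num[[p$t]][p$s + 1L] + w
    won <- w
    okon <- TRUE
    for (p in chosen) {
      if (p$s < em$fp_hi && p$e > em$fp_lo) { okon <- FALSE; break }
      gap <- if (p$e <= em$fp_lo) em$fp_lo - p$e else p$s - em$fp_hi
      if (gap <= em$da) won <- won * em$wa
    }
    if (okon) {
      Z_on_raw <<- Z_on_raw + won
      for (p in chosen)
        occ_num[[p$t]][p$s + 1L] <<- occ_num[[p$t]][p$s + 1L] + em$qR * won
    }
  }
  subsets <- function(i, chosen, last_end) {
    if (i > n) { score(chosen); return(invisible()) }
    subsets(i + 1L, chosen, last_end)
    p <- placements[[i]]
    if (p$s >= last_end) subsets(i + 1L, c(chosen, list(p)), p$e)
  }
  subsets(1L, list(), -Inf)
  Z <- Z_off + em$qR * Z_on_raw
  list(Z_on = em$qR * Z_on_raw, Z_off = Z_off,
       occ = lapply(occ_num, function(v) v / Z),
       p_on = em$qR * Z_on_raw / Z)
}

# Random explicit-site toy system on a short region (for oracle tests).
random_toy <- function(L = NULL, max_sites = 6L) {
  if (is.null(L)) L <- sample(40:60, 1)
  lt <- sample(c(6L, 9L), 1)
  nsites <- sample(1:max_sites, 1)
  sites <- data.frame(tf = sample(c("TF1", "TF2", "TF3"), nsites, TRUE),
                      start = sample(0:(L - lt), nsites, TRUE),
                      kd = 10^stats::runif(nsites, 0.5, 4))
  sites <- sites[!duplicated(sites[c("tf", "start")]), ]
  sm <- site_model(L, sites, q_R = 10^stats::runif(1, -2, 1), l_tf = lt)
  th <- thermo_params(omega_coop = sample(c(1, 20, 50), 1),
                      omega_act = sample(c(1, 20, 50), 1))
  list(x = sm, models = model_set(thermo = th),
       conc = stats::runif(3, 0, 1000) * stats::rbinom(3, 1, 0.8))
}

engine_model_of <- function(x, models, drop_tf3 = FALSE) {
  cisevolve:::engine_model(x, models, drop_tf3)
}
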