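#' Synthetic amino-acid x nucleotide contact energy matrix
#'
#' Draws a seeded 20 x 4 matrix in which every amino acid has one strongly
#' favoured nucleotide (contact energy about -`specificity` kT, slightly
#' jittered) while the other contacts sit near zero. The crystallographic
#' matrix the model was originally built on is not reproduced; gate designs
#' are insensitive to the individual matrix elements provided dissociation
#' constants remain tunable over 1-10000 nM, which this construction
#' guarantees together with the [default_K0()] calibration (a perfect
#' 9-residue site reaches about 1 nM, random sites sit far above 10^4 nM).
#'
#' @param seed RNG seed (default 42; the shipped default matrix).
#' @param specificity depth (kT) of the favoured contact; default 3.
#' @return an [energy_matrix()] with provenance "synthetic".
#' @export
make_synthetic_matrix <- function(seed = 42L, specificity = 3) {
  stopifnot(specificity >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # non-favoured contacts are mildly unfavourable with a wide jitter so
  # that sums over site positions form a dense set - site affinities are
  # then tunable essentially continuously over the whole 1-10000 nM range
  m <- matrix(stats::runif(80, -0.2, 1.0), 20, 4)
  fav <- sample.int(4L, 20L, replace = TRUE)
  m[cbind(1:20, fav)] <- -specificity * (1 + stats::runif(20, 0, 0.05))
  energy_matrix(m, provenance = "synthetic",
                range = c(-max(3, specificity * 1.05 + 1e-9), 3))
}

# save/restore the global RNG state so fixture generators with their own
# seed do not perturb a caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Random genotype
#'
#' Uniform random cis-regulatory and TF binding-domain sequences - the
#' initial condition of every evolutionary run.
#'
#' @param seed optional RNG seed; if `NULL` the ambient stream is used (as
#'   inside [evolve()]).
#' @param lengths list with `cis` (bp, default 200) and `tf` (residues,
#'   default 9).
#' @export
random_genotype <- function(seed = NULL, lengths = list(cis = 200L, tf = 9L)) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  cis <- paste(sample(DNA_ALPHABET, lengths$cis, replace = TRUE),
               collapse = "")
  tfs <- replicate(3, paste(sample(AA_ALPHABET, lengths$tf, replace = TRUE),
                            collapse = ""))
  genotype(cis, tfs[1], tfs[2], tfs[3])
}

# Greedy inverse design with random restarts: a site sequence for `tf_seq`
# with Kd as close as possible to target_kd. `fixed` is a named integer
# vector (position -> base index) of bases that must not change (e.g.
# promoter hexamer overlap).
design_site_seq <- function(tf_seq, matrix, target_kd, K0 = default_K0(),
                            fixed = integer(0), restarts = 12L) {
  a <- aa_ints(tf_seq)
  lt <- length(a)
  target <- log(target_kd / K0)
  free <- setdiff(seq_len(lt), as.integer(names(fixed)))
  descend <- function(b) {
    dg <- sum(matrix[cbind(a, b)])
    repeat {
      best <- NULL
      for (i in free) {
        for (nb in setdiff(1:4, b[i])) {
          cand <- dg - matrix[a[i], b[i]] + matrix[a[i], nb]
          if (abs(cand - target) < abs(dg - target) - 1e-12 &&
              (is.null(best) || abs(cand - target) < abs(best$dg - target)))
            best <- list(i = i, nb = nb, dg = cand)
        }
      }
      if (is.null(best)) break
      b[best$i] <- best$nb
      dg <- best$dg
    }
    list(b = b, err = abs(dg - target))
  }
  b0 <- apply(unclass(matrix)[a, , drop = FALSE], 1, which.min)
  if (length(fixed)) b0[as.integer(names(fixed))] <- fixed
  sol <- descend(b0)
  for (r in seq_len(restarts)) {
    if (sol$err < 0.05) break
    b <- b0
    b[free] <- sample.int(4L, length(free), replace = TRUE)
    cand <- descend(b)
    if (cand$err < sol$err) sol <- cand
  }
  paste(DNA_ALPHABET[sol$b], collapse = "")
}

# Background cleanup by monotone hill-climbing: repeatedly apply the single
# free-base change that most reduces the total "offense", the summed
# log-excess affinity of accidental (non-designed) sites of all TFs.
# The affinity threshold is zone-dependent: outside the RNAP footprint an
# accidental site can be amplified up to omega_act * omega_coop-fold by
# recruitment/cooperativity chains, so the bar is 1e7 nM; sites overlapping
# the footprint cannot recruit (their only effect is feeble competition in
# Z_off), so 1e5 nM suffices there. Returns the cleaned sequence plus the
# strongest remaining accidental Kd in each zone.
cleanup_background <- function(cis, tf_ints, matrix, K0, designed_starts,
                               free_idx, thresh_out = 1e7, thresh_fp = 1e5,
                               max_iter = 2000L) {
  L <- length(cis)
  lt <- length(tf_ints[[1]])
  cis_i <- match(cis, DNA_ALPHABET)
  fp <- footprint_coords(L)
  starts0 <- 0:(L - lt)
  in_fp <- starts0 < fp$hi & starts0 + lt > fp$lo
  ldg <- ifelse(in_fp, log(thresh_fp / K0), log(thresh_out / K0))
  offense <- function(ci) {
    tot <- 0
    worst_out <- Inf
    worst_fp <- Inf
    for (t in 1:3) {
      dg <- .scan_energies_cpp(tf_ints[[t]], ci, unclass(matrix))
      bad <- setdiff(which(dg < ldg), designed_starts[[t]] + 1L)
      if (length(bad)) {
        tot <- tot + sum(ldg[bad] - dg[bad])
        kd <- K0 * exp(dg[bad])
        if (any(!in_fp[bad]))
          worst_out <- min(worst_out, kd[!in_fp[bad]])
        if (any(in_fp[bad]))
          worst_fp <- min(worst_fp, kd[in_fp[bad]])
      }
    }
    list(tot = tot, worst_out = worst_out, worst_fp = worst_fp)
  }
  cur <- offense(cis_i)
  for (iter in seq_len(max_iter)) {
    if (cur$tot <= 0) break
    # candidate positions: free bases inside any offending window
    cand <- integer(0)
    for (t in 1:3) {
      dg <- .scan_energies_cpp(tf_ints[[t]], cis_i, unclass(matrix))
      bad <- setdiff(which(dg < ldg), designed_starts[[t]] + 1L)
      for (s1 in bad) cand <- c(cand, s1:(s1 + lt - 1L))
    }
    cand <- intersect(unique(cand), free_idx)
    best <- NULL
    for (pos in cand) {
      for (nb in setdiff(1:4, cis_i[pos])) {
        trial <- cis_i
        trial[pos] <- nb
        o <- offense(trial)
        if (o$tot < cur$tot - 1e-12 &&
            (is.null(best) || o$tot < best$o$tot))
          best <- list(pos = pos, nb = nb, o = o)
      }
    }
    if (is.null(best)) break # local minimum; caller decides tolerance
    cis_i[best$pos] <- best$nb
    cur <- best$o
  }
  list(cis = DNA_ALPHABET[cis_i], worst_out = cur$worst_out,
       worst_fp = cur$worst_fp)
}

# Choose a TF amino-acid sequence whose favoured bases satisfy the given
# constraints (position -> required base index); free positions are random.
design_tf_seq <- function(matrix, l_tf = 9L, constraints = integer(0)) {
  fav <- apply(unclass(matrix), 1, which.min)
  a <- sample.int(20L, l_tf, replace = TRUE)
  for (i in seq_along(constraints)) {
    pos <- as.integer(names(constraints))[i]
    pool <- which(fav == constraints[i])
    if (!length(pool))
      stop("no amino acid in this matrix favours base ",
           DNA_ALPHABET[constraints[i]])
    a[pos] <- pool[sample.int(length(pool), 1L)]
  }
  paste(AA_ALPHABET[a], collapse = "")
}

# Weaken the free hexamer positions of a consensus promoter until the basal
# RNAP weight reaches q_target. `protect` = 1-based region indices that must
# not change.
design_promoter <- function(cis, pm, q_target, rnap = 30,
                            K0R = default_K0R(pm, rnap),
                            protect = integer(0)) {
  L <- length(cis)
  idx <- hexamer_indices(L)
  cons <- apply(pm, 1, which.max)
  free <- which(!(idx %in% protect)) # protected positions keep their bases
  cis[idx[free]] <- DNA_ALPHABET[cons[free]]
  e <- function() -sum(log(pm[cbind(1:12, match(cis[idx], DNA_ALPHABET))]))
  target <- log(rnap / (q_target * K0R))
  repeat {
    cur <- e()
    best <- NULL
    for (i in free) {
      save <- cis[idx[i]]
      for (nb in DNA_ALPHABET[-match(save, DNA_ALPHABET)]) {
        cis[idx[i]] <- nb
        cand <- e()
        if (abs(cand - target) < abs(cur - target) - 1e-12 &&
            (is.null(best) || abs(cand - target) < abs(best$e - target)))
          best <- list(i = i, nb = nb, e = cand)
      }
      cis[idx[i]] <- save
    }
    if (is.null(best)) break
    cis[idx[best$i]] <- best$nb
  }
  cis
}

#' Hand-constructed reference designs
#'
#' Genotypes whose engineered binding sites reproduce the recurring design
#' schematics of evolved gates. Sites are designed by inverting the energy
#' model (greedy search for site sequences with target dissociation
#' constants); no sequences are copied from elsewhere. Available designs:
#'
#' * `AND_heterocoop`: weak recruiting TF1 site next to the promoter plus a
#'   strong cooperative TF2 site upstream - output high only when both
#'   inputs are high.
#' * `AND_cond_autoact`: the same module extended by a distal TF3 operator
#'   that can only act by stabilizing the TF1/TF2 module (conditional
#'   auto-activation).
#' * `NAND_autoact`: a hetero-cooperative TF1/TF2 repression module
#'   overlapping the promoter plus a recruiting TF3 site - auto-activation
#'   sustains expression until both inputs rise.
#' * `LIN_autoact`: one strong and one much weaker TF1 repressor site plus a
#'   TF3 activator, giving an approximately linear decreasing response.
#' * `bistable_autoact`: two cooperative recruiting TF3 sites on a very weak
#'   basal promoter - a positive-feedback switch with two stable states.
#'
#' Where a designed site overlaps a promoter hexamer, the TF's residues are
#' chosen so that their favoured bases coincide with the consensus hexamer
#' bases, so the site and the promoter share sequence without conflict.
#' Background sequence is random; any accidental background site with
#' Kd < 10^5 nM is mutated away (deterministically, from the seed).
#'
#' @param name design name.
#' @param models a [model_set()]; designs are built against its energy
#'   matrix, promoter model and calibration constants.
#' @param seed RNG seed for background sequence and free TF residues.
#' @param L region length (bp); default 120.
#' @return a [genotype()]; attribute `sites` records the designed site
#'   table (tf, start, kd_target).
#' @export
reference_design <- function(name = c("AND_heterocoop", "AND_cond_autoact",
                                      "NAND_autoact", "LIN_autoact",
                                      "bistable_autoact"),
                             models = model_set(), seed = 1L, L = 120L) {
  name <- match.arg(name)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  th <- models$thermo
  pm <- models$pm
  mx <- models$matrix
  fp <- footprint_coords(L)
  l_tf <- 9L
  cons <- apply(pm, 1, which.max) # consensus base per hexamer position
  # geometry anchors (0-based starts)
  prox <- fp$lo - 2L - l_tf     # recruiting site, gap 2
  dist <- prox - 12L - l_tf     # cooperative, non-recruiting (gap 23 to fp)
  dist2 <- dist - 12L - l_tf    # third link of a chain
  repA <- fp$lo + 3L            # repressor overlapping the -35 hexamer tail
  repB <- repA + l_tf + 1L      # repressor in the spacer, gap 1
  auto <- fp$lo - 17L - l_tf    # recruiting TF3 site, gap 17 (> 18+ to repA)
  tandem <- prox - l_tf         # second recruiting site, flush with prox
  # constraint for sites overlapping the -35 hexamer: positions of repA
  # covering hexamer indices (repA covers idx repA..repA+8; -35 hexamer idx
  # fp$lo..fp$lo+5 0-based)
  hex35 <- fp$lo + 0:5
  ov <- intersect(repA + 0:(l_tf - 1L), hex35)
  constr <- structure(cons[match(ov, hex35)], names = as.character(ov - repA + 1L))
  q_targets <- c(AND_heterocoop = 0.12, AND_cond_autoact = 0.12,
                 NAND_autoact = 0.05, LIN_autoact = 0.05,
                 bistable_autoact = 3e-4)
  spec <- switch(name,
    AND_heterocoop = list(
      tf_constr = list(TF1 = integer(0), TF2 = integer(0), TF3 = integer(0)),
      sites = data.frame(tf = c("TF1", "TF2"), start = c(prox, dist),
                         kd = c(80000, 600))),
    AND_cond_autoact = list(
      tf_constr = list(TF1 = integer(0), TF2 = integer(0), TF3 = integer(0)),
      sites = data.frame(tf = c("TF1", "TF2", "TF3"),
                         start = c(prox, dist, dist2),
                         kd = c(80000, 600, 120))),
    NAND_autoact = list(
      tf_constr = list(TF1 = constr, TF2 = integer(0), TF3 = integer(0)),
      sites = data.frame(tf = c("TF1", "TF2", "TF3"),
                         start = c(repA, repB, auto),
                         kd = c(2000, 2000, 50))),
    LIN_autoact = list(
      tf_constr = list(TF1 = constr, TF2 = integer(0), TF3 = integer(0)),
      sites = data.frame(tf = c("TF1", "TF1", "TF3"),
                         start = c(repA, repB, auto),
                         kd = c(150, 4500, 150))),
    bistable_autoact = list(
      tf_constr = list(TF1 = integer(0), TF2 = integer(0), TF3 = integer(0)),
      sites = data.frame(tf = c("TF3", "TF3"), start = c(tandem, prox),
                         kd = c(1500, 1500))))
  for (try in 1:60) {
    tf_seqs <- lapply(c(TF1 = "TF1", TF2 = "TF2", TF3 = "TF3"), function(id)
      design_tf_seq(mx, l_tf, spec$tf_constr[[id]]))
    cis <- sample(DNA_ALPHABET, L, replace = TRUE)
    # promoter first (so hexamer-overlapping sites see the final bases).
    # Positions shared with a designed repressor site are pinned to
    # consensus - the TF residue constraints make the site favour exactly
    # those bases - and excluded from the weakening search.
    hex1 <- hexamer_indices(L)
    cis[hex1] <- DNA_ALPHABET[cons]
    prot_ov <- if (length(spec$tf_constr$TF1)) ov + 1L else integer(0)
    cis <- design_promoter(cis, pm, q_targets[name], th$rnap, th$K0R,
                           protect = prot_ov)
    protected <- hex1
    for (i in seq_len(nrow(spec$sites))) {
      s <- spec$sites$start[i]
      id <- spec$sites$tf[i]
      span <- (s + 1L):(s + l_tf)
      fixed_pos <- which(span %in% protected)
      fixed <- structure(match(cis[span[fixed_pos]], DNA_ALPHABET),
                         names = as.character(fixed_pos))
      site <- design_site_seq(tf_seqs[[id]], mx, spec$sites$kd[i], th$K0,
                              fixed = fixed)
      cis[span] <- strsplit(site, "")[[1]]
      protected <- union(protected, span)
    }
    # Cross-affinity vetting: a designed site sequence must be weak for the
    # two TFs it was not designed for; cross binders only substitute for
    # the (much stronger) designed occupant, so 1e6 nM suffices outside
    # the footprint and 5e4 nM inside it. Redraw TF sequences otherwise.
    cross_ok <- TRUE
    for (i in seq_len(nrow(spec$sites))) {
      s <- spec$sites$start[i]
      lim <- if (s < fp$hi && s + l_tf > fp$lo) 5e4 else 1e6
      site_seq <- paste(cis[(s + 1L):(s + l_tf)], collapse = "")
      for (id in setdiff(c("TF1", "TF2", "TF3"), spec$sites$tf[i])) {
        dg <- tf_site_energy(tf_seqs[[id]], site_seq, mx)
        if (th$K0 * exp(dg) < lim) { cross_ok <- FALSE; break }
      }
      if (!cross_ok) break
    }
    if (!cross_ok) next
    # Background cleanup: accidental sites of any TF stronger than 1e7 nM
    # are hill-climbed away (weak binding gets amplified up to
    # omega_act * omega_coop-fold in cooperative chains near the promoter).
    # Residual sites stuck in protected sequence are tolerated down to
    # 1e6 nM; anything stronger forces a redraw of the TF sequences.
    free_idx <- setdiff(seq_len(L), protected)
    tf_ints <- lapply(tf_seqs, aa_ints)
    designed_starts <- lapply(c(TF1 = "TF1", TF2 = "TF2", TF3 = "TF3"),
      function(id) spec$sites$start[spec$sites$tf == id])
    cl <- cleanup_background(cis, tf_ints, mx, th$K0, designed_starts,
                             free_idx)
    if (cl$worst_out >= 1e6 && cl$worst_fp >= 5e4) {
      g <- genotype(paste(cl$cis, collapse = ""),
                    tf_seqs$TF1, tf_seqs$TF2, tf_seqs$TF3)
      attr(g, "sites") <- spec$sites
      attr(g, "design") <- name
      # behavioural verification: designed Kds realize only approximately
      # (site energies live on a discrete lattice), so accept a draw only
      # when the realized genotype shows the intended qualitative behaviour
      if (verify_design(g, name, models)) return(g)
    }
  }
  stop("could not realize reference design ", name,
       " with the intended qualitative behaviour")
}

# The qualitative behavioural contract of each reference design, evaluated
# with the full engine under the given models.
verify_design <- function(g, name, models) {
  corners <- evaluation_grid(2L, type = "corners") # (0,0),(1e3,0),(0,1e3),(1e3,1e3)
  switch(name,
    AND_heterocoop = {
      s <- response_surface(g, models, corners)
      s$c3[4] > 500 && all(s$c3[1:3] < 500) && sum(s$penalty) == 0
    },
    AND_cond_autoact = {
      s <- response_surface(g, models, corners)
      s$c3[4] > 500 && all(s$c3[1:3] < 500) && sum(s$penalty) == 0 &&
        feedback_measure(g, models) > 1e3
    },
    NAND_autoact = {
      s <- response_surface(g, models, corners)
      all(s$c3[1:3] > 500) && s$c3[4] < 500 && sum(s$penalty) == 0 &&
        feedback_measure(g, models) > 1e3
    },
    LIN_autoact = {
      s <- response_surface(g, models, evaluation_grid(1L))
      all(diff(s$c3) < 0) &&
        feedback_measure(g, models, evaluation_grid(1L)) > 1e3
    },
    bistable_autoact = {
      length(bistability_scan(g, models, 0, 0)) >= 2
    })
}
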