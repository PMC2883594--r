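#' Feedback measure F: how much auto-regulation shapes the response
#'
#' Computes the response surface n(c1, c2) of the genotype, then recomputes
#' it with TF3's affinity for every site set to zero (n0) and returns the
#' mean of the squared differences over the grid points, in nM^2. A design
#' that does not exploit auto-regulation gives F near 0; a uniform shift of
#' 100 nM at every point gives F = 10^4 nM^2.
#'
#' @param x a [genotype()] or [site_model()].
#' @param models a [model_set()].
#' @param grid evaluation grid (default: the 16-point two-input grid).
#' @return F in nM^2. Bistable grid points are excluded with a warning.
#' @export
feedback_measure <- function(x, models, grid = evaluation_grid(2L)) {
  s1 <- response_surface(x, models, grid)
  em0 <- engine_model(x, models, drop_tf3 = TRUE)
  dyn <- models$dyn
  r0 <- .score_gate_cpp(em0, as.matrix(grid), numeric(nrow(grid)),
                        dyn$beta, dyn$mu, dyn$eps_ss, 1)
  ok <- s1$penalty == 0 & abs(r0$ss_high - r0$ss_low) <= dyn$eps_ss
  if (!all(ok))
    warning(sum(!ok), " bistable grid point(s) excluded from F")
  if (!any(ok)) stop("no monostable grid points; F undefined")
  feedback_from_surfaces(s1$c3[ok], r0$ss_low[ok])
}

#' @describeIn feedback_measure the bare definition: mean of the squared
#'   differences between the two surfaces (nM^2).
#' @param n,n0 steady-state outputs with and without TF3 binding (nM).
#' @export
feedback_from_surfaces <- function(n, n0) {
  stopifnot(length(n) == length(n0), length(n) > 0)
  mean((n - n0)^2)
}

#' Computational DNA footprint of a genotype
#'
#' For each of the four corner conditions (c1, c2) in \{0, 1000\}^2 nM the
#' output concentration is set to its self-consistent steady state (reached
#' from c3 = 0) and the equilibrium occupancy of every (TF, start) placement
#' is computed. The profile records O_max, the maximum over the four
#' conditions - the computational analogue of a DNase I footprint. Sites
#' that matter for the response show a significant O_max in at least one
#' corner.
#'
#' @inheritParams feedback_measure
#' @param corners data.frame of corner conditions (columns c1, c2).
#' @return a `footprint_profile`: data.frame with tf, start (0-based),
#'   o_max, plus attributes `l_tf` and `L`.
#' @export
footprint <- function(x, models,
                      corners = evaluation_grid(2L, type = "corners")) {
  em <- engine_model(x, models)
  dyn <- models$dyn
  prof <- NULL
  for (i in seq_len(nrow(corners))) {
    c1 <- corners$c1[i]; c2 <- corners$c2[i]
    ss <- .steady_state_cpp(em, c1, c2, 0, dyn$beta, dyn$mu, dyn$eps_ss)
    occ <- occupancy_profile(em, c1, c2, ss)
    m <- cbind(occ$TF1, occ$TF2, occ$TF3)
    prof <- if (is.null(prof)) m else pmax(prof, m)
  }
  lens <- vapply(em$species, function(s) s$len, 1L)
  out <- do.call(rbind, lapply(1:3, function(t) {
    n <- em$L - lens[t] + 1L
    data.frame(tf = paste0("TF", t), start = 0:(n - 1L),
               o_max = prof[seq_len(n), t])
  }))
  structure(out, class = c("footprint_profile", "data.frame"),
            l_tf = lens, L = em$L)
}

#' Call binding sites from a footprint profile
#'
#' Selects every (TF, start) whose maximal occupancy reaches the cutoff,
#' merges overlapping same-TF calls keeping the highest-occupancy start, and
#' annotates each call by its regulatory role: repressor if the site
#' overlaps the RNAP footprint, activator if within recruitment distance,
#' distal otherwise; TF3 calls get an "auto-" prefix.
#'
#' @param profile a [footprint()] profile.
#' @param models a [model_set()] (for the distance thresholds).
#' @param threshold occupancy cutoff; default 0.5 (a rather stringent value
#'   separating the functional mode of the bimodal O_max distribution from
#'   pseudo-sites; lower it if a simplified model fails to reproduce the
#'   full response).
#' @return data.frame tf, start, end (half-open), o_max, role.
#' @export
call_binding_sites <- function(profile, models, threshold = 0.5) {
  lens <- attr(profile, "l_tf")
  L <- attr(profile, "L")
  fp <- footprint_coords(L)
  da <- models$thermo$d_act
  hits <- profile[profile$o_max >= threshold, , drop = FALSE]
  out <- NULL
  for (id in unique(hits$tf)) {
    h <- hits[hits$tf == id, , drop = FALSE]
    h <- h[order(-h$o_max, h$start), , drop = FALSE]
    lt <- lens[match(id, c("TF1", "TF2", "TF3"))]
    kept <- h[0, ]
    for (i in seq_len(nrow(h))) {
      s <- h$start[i]
      if (nrow(kept) == 0 ||
          all(s + lt <= kept$start | s >= kept$start + lt)) {
        kept <- rbind(kept, h[i, ])
      }
    }
    out <- rbind(out, kept)
  }
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(tf = character(0), start = integer(0),
                      end = integer(0), o_max = numeric(0),
                      role = character(0)))
  lt <- lens[match(out$tf, c("TF1", "TF2", "TF3"))]
  e <- out$start + lt
  overlap <- out$start < fp$hi & e > fp$lo
  gap <- ifelse(e <= fp$lo, fp$lo - e, out$start - fp$hi)
  role <- ifelse(overlap, "repressor",
                 ifelse(gap <= da, "activator", "distal"))
  role <- ifelse(out$tf == "TF3", paste0("auto-", role), role)
  res <- data.frame(tf = out$tf, start = out$start, end = e,
                    o_max = out$o_max, role = role)
  res[order(res$start), , drop = FALSE]
}

#' Simplify a genotype to its called sites and verify the reduction
#'
#' Builds a reduced explicit-site model in which only the called sites keep
#' their sequence-derived dissociation constants (all other affinities are
#' zero, the basal promoter weight is retained) and compares its response
#' surface with the full model's. Successful simplification means the called
#' sites are sufficient to explain the response.
#'
#' @param x a [genotype()].
#' @param calls output of [call_binding_sites()] (nonempty).
#' @param models a [model_set()].
#' @param grid evaluation grid.
#' @param tol maximal tolerated deviation (nM); default 50.
#' @return list with `reduced` (a [site_model()]), `max_dev` (nM),
#'   `success`, and the two surfaces.
#' @export
simplify_and_verify <- function(x, calls, models,
                                grid = evaluation_grid(2L), tol = 50) {
  if (nrow(calls) == 0) stop("no called sites to build a reduced model from")
  em <- engine_model(x, models)
  kd <- mapply(function(tf, s) {
    t <- match(tf, c("TF1", "TF2", "TF3"))
    sp <- em$species[[t]]
    sp$kd[match(s, sp$starts)]
  }, calls$tf, calls$start)
  lens <- vapply(em$species, function(s) s$len, 1L)
  if (length(unique(lens)) != 1L)
    stop("reduced models require a common site length")
  red <- site_model(em$L,
                    data.frame(tf = calls$tf, start = calls$start, kd = kd),
                    q_R = em$qR, l_tf = lens[1])
  s_full <- response_surface(x, models, grid)
  s_red <- response_surface(red, models, grid)
  max_dev <- max(abs(s_full$c3 - s_red$c3))
  list(reduced = red, max_dev = max_dev, success = max_dev <= tol,
       full = s_full, simplified = s_red)
}

#' In-degree statistics of auto-regulating transcription factors
#'
#' Summarizes, per regulator class (auto-activator / auto-repressor), how
#' many regulators there are, their total number of non-auto inputs, the
#' fraction with at least one input and the mean in-degree (the auto-edge is
#' excluded by construction of the input counts).
#'
#' @param records data.frame with columns `class` ("auto-activator" or
#'   "auto-repressor") and `n_inputs` (non-negative integers).
#' @return data.frame with one row per class: n, total_inputs,
#'   frac_with_input, mean_in_degree.
#' @export
degree_stats <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no regulator records")
  stopifnot(all(records$class %in% c("auto-activator", "auto-repressor")),
            all(records$n_inputs >= 0))
  out <- do.call(rbind, lapply(split(records, records$class), function(d) {
    data.frame(class = d$class[1], n = nrow(d),
               total_inputs = sum(d$n_inputs),
               frac_with_input = mean(d$n_inputs >= 1),
               mean_in_degree = mean(d$n_inputs))
  }))
  rownames(out) <- NULL
  out
}
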