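#' Thermodynamic interaction parameters
#'
#' Parameters of the configuration-weight model: cooperativity between
#' DNA-bound TFs, regulated recruitment of RNAP by nearby TFs, the distance
#' thresholds for both interactions, the free RNAP concentration and the
#' affinity calibration constants.
#'
#' @param omega_coop TF-TF cooperativity factor (>= 1). Two adjacently bound
#'   TFs with edge-to-edge gap <= `d_coop` multiply the configuration weight
#'   by this factor. The biologically validated range is 10-100; default 50.
#' @param omega_act TF-RNAP recruitment factor (>= 1) applied for each bound
#'   TF whose site lies within `d_act` bp of the RNAP footprint; default 50.
#' @param d_coop maximum edge-to-edge gap (bp) for TF-TF cooperativity;
#'   default 18 (twice the default binding-site length).
#' @param d_act maximum gap (bp) between a TF site and the RNAP footprint
#'   for recruitment; default 20.
#' @param rnap free RNAP concentration (nM); default 30.
#' @param K0 TF affinity calibration (nM), see [default_K0()].
#' @param K0R promoter affinity calibration (nM), see [default_K0R()].
#' @export
thermo_params <- function(omega_coop = 50, omega_act = 50,
                          d_coop = 18L, d_act = 20L, rnap = 30,
                          K0 = default_K0(), K0R = NULL) {
  stopifnot(omega_coop >= 1, omega_act >= 1, d_coop >= 0, d_act >= 0,
            rnap > 0, K0 > 0)
  structure(list(omega_coop = omega_coop, omega_act = omega_act,
                 d_coop = as.integer(d_coop), d_act = as.integer(d_act),
                 rnap = rnap, K0 = K0, K0R = K0R),
            class = "thermo_params")
}

#' Bundle the scoring models for a genotype
#'
#' Collects the energy matrix, promoter model, thermodynamic parameters and
#' dynamics parameters that together map a genotype to its regulatory
#' behaviour. All higher-level functions take such a bundle.
#'
#' @param matrix an [energy_matrix()].
#' @param pm a [promoter_model()].
#' @param thermo a [thermo_params()].
#' @param dyn a [dynamics_params()].
#' @export
model_set <- function(matrix = make_synthetic_matrix(),
                      pm = consensus_promoter_model(),
                      thermo = thermo_params(),
                      dyn = dynamics_params()) {
  if (is.null(thermo$K0R)) thermo$K0R <- default_K0R(pm, thermo$rnap)
  structure(list(matrix = matrix, pm = pm, thermo = thermo, dyn = dyn),
            class = "model_set")
}

#' Explicit-site regulatory model
#'
#' A regulatory layout specified directly by site positions and dissociation
#' constants rather than by sequences. Used for minimal models, simplified
#' (reduced) models and hand-constructed comparisons; it is scored by exactly
#' the same partition-function engine as sequence genotypes.
#'
#' @param L region length (bp).
#' @param sites data.frame with columns `tf` ("TF1"/"TF2"/"TF3"), `start`
#'   (0-based) and `kd` (nM); may be empty.
#' @param q_R basal RNAP statistical weight.
#' @param l_tf binding-site length (bp), one value for all species.
#' @export
site_model <- function(L, sites, q_R, l_tf = 9L) {
  L <- as.integer(L)
  stopifnot(L >= 40L, q_R > 0)
  if (nrow(sites) > 0) {
    stopifnot(all(sites$tf %in% c("TF1", "TF2", "TF3")),
              all(sites$start >= 0), all(sites$start + l_tf <= L),
              all(sites$kd > 0))
    if (anyDuplicated(sites[c("tf", "start")]))
      stop("duplicate (tf, start) site entries")
  }
  structure(list(L = L, sites = sites, q_R = q_R, l_tf = as.integer(l_tf)),
            class = "site_model")
}

# Build the list consumed by the C++ engine from a genotype (scanning all
# start positions of all three TFs) or from an explicit site_model.
engine_model <- function(x, models, drop_tf3 = FALSE) {
  th <- models$thermo
  if (inherits(x, "site_model")) {
    L <- x$L
    fp <- footprint_coords(L)
    species <- lapply(c("TF1", "TF2", "TF3"), function(id) {
      rows <- x$sites[x$sites$tf == id, , drop = FALSE]
      if (drop_tf3 && id == "TF3") rows <- rows[0, , drop = FALSE]
      list(starts = as.integer(rows$start), kd = as.numeric(rows$kd),
           len = x$l_tf)
    })
    qR <- x$q_R
  } else if (inherits(x, "genotype")) {
    L <- nchar(x$cis)
    fp <- footprint_coords(L)
    cis_i <- dna_ints(as.character(x$cis))
    species <- lapply(x$tfs, function(tf) {
      if (drop_tf3 && tf$id == "TF3")
        return(list(starts = integer(0), kd = numeric(0),
                    len = nchar(tf$seq)))
      dg <- .scan_energies_cpp(aa_ints(tf$seq), cis_i, unclass(models$matrix))
      list(starts = seq_along(dg) - 1L, kd = th$K0 * exp(dg),
           len = nchar(tf$seq))
    })
    qR <- rnap_promoter_energy(x$cis, models$pm, th$rnap, th$K0R)$q_R
  } else stop("x must be a genotype or a site_model")
  list(L = L, fp_lo = fp$lo, fp_hi = fp$hi, qR = qR,
       wc = th$omega_coop, wa = th$omega_act,
       dc = th$d_coop, da = th$d_act, species = unname(species))
}

check_conc <- function(...) {
  cc <- c(...)
  if (any(!is.finite(cc)) || any(cc < 0))
    stop("concentrations must be finite and >= 0")
  cc
}

#' Partition sums over all binding configurations
#'
#' Sums the Boltzmann weights of every configuration of non-overlapping TF
#' placements on the region, split into configurations that contain RNAP at
#' the core promoter (`Z_on`, includes the RNAP weight and recruitment
#' factors) and those that do not (`Z_off`, includes the empty configuration
#' with weight 1). Evaluated by a linear-scan dynamic programme whose state
#' is the end position of the last placed molecule, exact for
#' nearest-neighbour cooperativity.
#'
#' @param x a [genotype()] or [site_model()].
#' @param models a [model_set()].
#' @param c1,c2,c3 TF concentrations (nM).
#' @return list with `Z_on` and `Z_off`.
#' @export
partition_sums <- function(x, models, c1, c2, c3) {
  cc <- check_conc(c1, c2, c3)
  .partition_cpp(engine_model(x, models), cc)
}

#' Equilibrium promoter occupancy
#'
#' Fractional occupancy of the core promoter by RNAP,
#' P_on = Z_on / (Z_on + Z_off); the transcription rate is proportional to
#' this quantity.
#'
#' @inheritParams partition_sums
#' @return P_on in \[0, 1\].
#' @export
promoter_occupancy <- function(x, models, c1, c2, c3) {
  cc <- check_conc(c1, c2, c3)
  .pon_cpp(engine_model(x, models), cc)
}

#' Equilibrium occupancy of one binding site
#'
#' Probability-weighted fraction of configurations in which the given TF
#' occupies the site starting at `start` (0-based). Because placements
#' cannot overlap, the summed occupancy of all placements covering any one
#' base never exceeds 1.
#'
#' @inheritParams partition_sums
#' @param tf "TF1", "TF2" or "TF3".
#' @param start 0-based start position of the site.
#' @export
site_occupancy <- function(x, models, c1, c2, c3, tf, start) {
  cc <- check_conc(c1, c2, c3)
  em <- engine_model(x, models)
  ti <- match(tf, c("TF1", "TF2", "TF3"))
  if (is.na(ti)) stop("unknown TF id: ", tf)
  lt <- em$species[[ti]]$len
  if (start < 0 || start + lt > em$L)
    stop("invalid start position ", start, " for a ", lt, "-bp site")
  occ <- .occupancy_cpp(em, cc)
  occ[[ti]][start + 1L]
}

# Full occupancy profile (per species, per start) plus P_on; internal.
occupancy_profile <- function(em, c1, c2, c3) {
  occ <- .occupancy_cpp(em, check_conc(c1, c2, c3))
  names(occ) <- c("TF1", "TF2", "TF3")
  occ
}
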