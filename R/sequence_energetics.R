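#' @useDynLib cisevolve, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
DNA_ALPHABET <- c("A","C","G","T")

aa_ints <- function(seq) {
  v <- match(strsplit(seq, "")[[1]], AA_ALPHABET)
  if (anyNA(v)) stop("amino-acid sequence contains characters outside the 20-letter alphabet")
  v
}

dna_ints <- function(seq) {
  v <- match(strsplit(seq, "")[[1]], DNA_ALPHABET)
  if (anyNA(v)) stop("nucleotide sequence contains characters outside {A,C,G,T}")
  v
}

#' Amino-acid x nucleotide contact energy matrix
#'
#' Validates a 20 x 4 matrix of contact free energies (in kT) between the 20
#' amino acids (rows, alphabetical one-letter code) and the 4 nucleotides
#' (columns A, C, G, T). The total binding free energy of a TF for a site is
#' the sum of one contact energy per position, so this matrix fully
#' determines TF-DNA specificity.
#'
#' @param entries numeric 20 x 4 matrix, kT units.
#' @param provenance character label describing where the matrix comes from.
#' @param range permissible value range (kT); entries outside trigger an
#'   error. Default \[-3, +3\] kT.
#' @return an `energy_matrix` object (a classed matrix).
#' @seealso [make_synthetic_matrix()] for the shipped default.
#' @export
energy_matrix <- function(entries, provenance = "user",
                          range = c(-3, 3)) {
  entries <- as.matrix(entries)
  if (!is.numeric(entries) || nrow(entries) != 20L || ncol(entries) != 4L)
    stop("energy matrix must be a numeric 20 x 4 matrix")
  if (any(!is.finite(entries)))
    stop("energy matrix entries must all be finite")
  if (any(entries < range[1] | entries > range[2]))
    stop("energy matrix entries outside the configured range [",
         range[1], ", ", range[2], "] kT")
  dimnames(entries) <- list(AA_ALPHABET, DNA_ALPHABET)
  structure(entries, class = c("energy_matrix", "matrix"),
            provenance = provenance)
}

#' Cis-regulatory region constructor
#'
#' A cis-regulatory region is a nucleotide string directly upstream of the
#' transcription start site; the rightmost base sits at position -1. The
#' promoter anatomy is anchored to the right end: the -10 hexamer occupies
#' positions -12..-7, the spacer -29..-13, and the -35 hexamer -35..-30; the
#' RNA polymerase footprint covers -35..-7 (29 bp), so a TF bound anywhere in
#' that window excludes RNAP.
#'
#' @param seq nucleotide string over A, C, G, T.
#' @param max_len maximum admissible length (default 300 bp).
#' @return a `cis_region` object (a classed character scalar).
#' @export
cis_region <- function(seq, max_len = 300L) {
  seq <- toupper(as.character(seq))
  dna_ints(seq) # alphabet check
  n <- nchar(seq)
  if (n < 40L || n > max_len)
    stop("cis region length must be in [40, ", max_len, "] bp, got ", n)
  structure(seq, class = "cis_region")
}

# Footprint in 0-based left-anchored half-open coordinates.
footprint_coords <- function(L) {
  list(lo = L - 35L, hi = L - 6L) # covers TSS-relative [-35, -7]
}

#' Transcription factor constructor
#'
#' @param seq amino-acid string (one-letter code) of the DNA-binding domain;
#'   each residue contacts exactly one base pair. Lengths 6-15 are accepted,
#'   reflecting typical bacterial binding-site lengths.
#' @param id one of "TF1", "TF2", "TF3".
#' @param role "input" (TF1/TF2) or "output" (TF3, the auto-regulator).
#' @export
transcription_factor <- function(seq, id = c("TF1", "TF2", "TF3"),
                                 role = NULL) {
  id <- match.arg(id)
  seq <- toupper(as.character(seq))
  aa_ints(seq)
  if (nchar(seq) < 6L || nchar(seq) > 15L)
    stop("TF binding-domain length must be in [6, 15] residues")
  if (is.null(role)) role <- if (id == "TF3") "output" else "input"
  structure(list(id = id, seq = seq, role = role),
            class = "transcription_factor")
}

#' Genotype: one cis-regulatory region plus three transcription factors
#'
#' The unit of evolution: the cis-regulatory region of the output gene
#' (coding for TF3) and the binding domains of the two input TFs and of TF3
#' itself. All regulatory behaviour follows from these sequences.
#'
#' @param cis a [cis_region()] or plain string.
#' @param tf1,tf2,tf3 [transcription_factor()]s or plain amino-acid strings.
#' @export
genotype <- function(cis, tf1, tf2, tf3) {
  if (!inherits(cis, "cis_region")) cis <- cis_region(cis)
  wrap <- function(x, id) {
    if (inherits(x, "transcription_factor")) x else transcription_factor(x, id)
  }
  structure(list(cis = cis,
                 tfs = list(TF1 = wrap(tf1, "TF1"),
                            TF2 = wrap(tf2, "TF2"),
                            TF3 = wrap(tf3, "TF3"))),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat("cis-regulatory genotype\n")
  cat("  cis region: ", nchar(x$cis), " bp\n", sep = "")
  for (tf in x$tfs)
    cat("  ", tf$id, " (", tf$role, "): ", tf$seq, "\n", sep = "")
  invisible(x)
}

#' TF-site binding free energy
#'
#' Total binding free energy (kT) of a TF for one site: the sum over
#' positions of the contact energy between residue i and base i.
#'
#' @param tf a [transcription_factor()] or amino-acid string.
#' @param site nucleotide string of the same length as the TF domain.
#' @param matrix an [energy_matrix()].
#' @return energy in kT (more negative = stronger binding).
#' @export
tf_site_energy <- function(tf, site, matrix) {
  seq <- if (inherits(tf, "transcription_factor")) tf$seq else tf
  a <- aa_ints(seq)
  b <- dna_ints(toupper(site))
  if (length(a) != length(b))
    stop("site length (", length(b), ") must equal TF domain length (",
         length(a), ")")
  sum(matrix[cbind(a, b)])
}

#' Scan a cis region for binding affinities of one TF
#'
#' Evaluates the binding free energy at every possible start position and
#' converts it to a dissociation constant Kd = K0 * exp(dG). K0 calibrates
#' the absolute affinity scale; with the shipped synthetic matrix the default
#' puts a perfect site at about 1 nM and random sites far above 10000 nM.
#'
#' @param tf a [transcription_factor()] or amino-acid string.
#' @param cis a [cis_region()] or nucleotide string (>= TF length).
#' @param matrix an [energy_matrix()].
#' @param K0 calibration constant (nM) in Kd = K0 * exp(dG).
#' @return data.frame with columns `tf`, `start` (0-based), `dG` (kT),
#'   `kd` (nM); one row per start, `nchar(cis) - L_TF + 1` rows in total.
#' @export
scan_sites <- function(tf, cis, matrix, K0 = default_K0()) {
  seq <- if (inherits(tf, "transcription_factor")) tf$seq else tf
  id <- if (inherits(tf, "transcription_factor")) tf$id else NA_character_
  a <- aa_ints(seq)
  b <- dna_ints(toupper(as.character(cis)))
  if (length(b) < length(a))
    stop("cis region shorter than the TF binding domain")
  dg <- .scan_energies_cpp(a, b, unclass(matrix))
  data.frame(tf = id, start = seq_along(dg) - 1L, dG = dg,
             kd = K0 * exp(dg))
}

#' Default affinity calibration constant
#'
#' K0 (nM) such that, under the default synthetic energy matrix
#' (specificity 3 kT, L_TF = 9), a perfect site has Kd about 1 nM while a
#' typical random site lies far above 10000 nM, covering the biologically
#' required 1-10000 nM tuning range.
#' @param l_tf binding-domain length.
#' @param specificity favourable contact depth (kT) of the synthetic matrix.
#' @export
default_K0 <- function(l_tf = 9, specificity = 3) exp(l_tf * specificity)

#' Position score model of the basal promoter
#'
#' Per-position nucleotide scores s(b, i) for the 12 hexamer positions
#' (-35 element then -10 element), interpreted as observed base frequencies
#' normalized by the random fraction 1/4 (so the scores at each position
#' average to 1). RNAP binding energy is the log-score sum
#' E = -sum_i ln s(b_i, i).
#'
#' @param scores 12 x 4 positive matrix; rows are hexamer positions
#'   (-35..-30 then -12..-7), columns A, C, G, T.
#' @export
promoter_model <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) != 12L || ncol(scores) != 4L)
    stop("promoter model must be a 12 x 4 matrix")
  if (any(scores <= 0)) stop("promoter scores must be > 0")
  if (any(abs(rowMeans(scores) - 1) > 1e-6))
    stop("promoter scores at each position must average to 1 ",
         "(frequencies normalized by 1/4)")
  rownames(scores) <- c(paste0("m35_", -35:-30), paste0("m10_", -12:-7))
  colnames(scores) <- DNA_ALPHABET
  structure(scores, class = c("promoter_model", "matrix"))
}

#' Consensus-weighted default promoter model
#'
#' Frequencies peaked on the canonical TTGACA (-35) and TATAAT (-10)
#' hexamers: the consensus base has frequency `f_cons`; the other three
#' bases share the remainder unequally (in a fixed rotation), so promoter
#' strengths are tunable in fine steps rather than only in powers of one
#' ratio. The published position-frequency table is not reproduced; this
#' default is configurable via [read_promoter_model()].
#'
#' @param f_cons consensus-base frequency at each position (default 0.55).
#' @export
consensus_promoter_model <- function(f_cons = 0.55) {
  cons <- strsplit("TTGACATATAAT", "")[[1]]
  shares <- c(0.47, 0.31, 0.22) * (1 - f_cons)
  sc <- matrix(NA_real_, 12, 4, dimnames = list(NULL, DNA_ALPHABET))
  for (i in 1:12) {
    ci <- match(cons[i], DNA_ALPHABET)
    sc[i, ci] <- f_cons / 0.25
    others <- setdiff(1:4, ci)
    rot <- (i + seq_along(others) - 2L) %% 3L + 1L
    sc[i, others] <- shares[rot] / 0.25
  }
  promoter_model(sc)
}

# Indices (1-based) of the 12 scored hexamer positions in a region of
# length L: -35..-30 then -12..-7.
hexamer_indices <- function(L) {
  c((L - 35L):(L - 30L), (L - 12L):(L - 7L)) + 1L
}

#' RNAP-promoter binding energy and basal weight
#'
#' Scores the two hexamers of the fixed core promoter against the position
#' score model: E = -sum over the 12 positions of ln s(b_i, i) (kT).
#' The basal RNAP statistical weight follows as
#' q_R = rnap / (K0R * exp(E)).
#'
#' @param cis a [cis_region()] or nucleotide string long enough to contain
#'   the promoter anatomy (>= 40 bp).
#' @param pm a [promoter_model()].
#' @param rnap free RNAP concentration (nM).
#' @param K0R promoter-affinity calibration constant (nM); the default makes
#'   a consensus promoter's Kd equal to the default RNAP concentration, i.e.
#'   q_R = 1 at consensus.
#' @return list with `energy` (kT), `kd` (nM) and `q_R`.
#' @export
rnap_promoter_energy <- function(cis, pm, rnap = 30,
                                 K0R = default_K0R(pm, rnap)) {
  s <- toupper(as.character(cis))
  L <- nchar(s)
  if (L < 40L) stop("region too short to contain the promoter anatomy")
  b <- dna_ints(s)[hexamer_indices(L)]
  energy <- -sum(log(pm[cbind(1:12, b)]))
  kd <- K0R * exp(energy)
  list(energy = energy, kd = kd, q_R = rnap / kd)
}

#' @rdname rnap_promoter_energy
#' @export
default_K0R <- function(pm = consensus_promoter_model(), rnap = 30) {
  e_cons <- -sum(log(apply(pm, 1, max)))
  rnap / exp(e_cons) # consensus promoter Kd = rnap, q_R = 1
}
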