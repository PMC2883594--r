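# Readers and writers for the package's plain-text formats: FASTA
# (sequences; record ids carry the TF role), TSV (energy matrix, promoter
# model, run logs, curves, degree tables), BED (site calls, 0-based
# half-open) and JSON (run configuration). Every writer produces files its
# reader parses back to an equal object.
#
# The FASTA reader/writer is internal (~30 lines) because genotype files mix
# nucleotide and amino-acid records in one file, which typed parsers refuse.

read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no FASTA records in ", path)
  if (hdr[1] != 1L)
    stop("malformed FASTA: sequence before first header at line 1 of ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- character(length(hdr))
  for (i in seq_along(hdr)) {
    body <- lines[(hdr[i] + 1L):ends[i]]
    if (hdr[i] + 1L > ends[i] || !nzchar(paste(body, collapse = "")))
      stop("malformed FASTA: empty record at line ", hdr[i], " of ", path)
    seqs[i] <- gsub("[[:space:]]", "", paste(body, collapse = ""))
  }
  names(seqs) <- sub("^>", "", lines[hdr])
  seqs
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and write genotypes as FASTA
#'
#' One file holds four records: the cis-regulatory region (id `cis`) and the
#' three TF binding domains (ids `TF1 role=input` etc.).
#'
#' @param g a [genotype()].
#' @param path file path.
#' @export
write_genotype <- function(g, path) {
  seqs <- c(cis = as.character(g$cis))
  for (tf in g$tfs)
    seqs[[paste0(tf$id, " role=", tf$role)]] <- tf$seq
  write_fasta(seqs, path)
}

#' @rdname write_genotype
#' @export
read_genotype <- function(path) {
  seqs <- read_fasta(path)
  ids <- sub(" .*", "", names(seqs))
  need <- c("cis", "TF1", "TF2", "TF3")
  if (!all(need %in% ids))
    stop("genotype FASTA must contain records cis, TF1, TF2, TF3")
  genotype(seqs[ids == "cis"][1],
           seqs[ids == "TF1"][1], seqs[ids == "TF2"][1],
           seqs[ids == "TF3"][1])
}

#' Read and write populations as FASTA
#'
#' Record ids are `g<i>|cis`, `g<i>|TF1`, ... for genotype i.
#' @param pop list of genotypes.
#' @param path file path.
#' @export
write_population <- function(pop, path) {
  seqs <- character(0)
  for (i in seq_along(pop)) {
    g <- pop[[i]]
    pre <- sprintf("g%04d|", i)
    seqs[[paste0(pre, "cis")]] <- as.character(g$cis)
    for (tf in g$tfs) seqs[[paste0(pre, tf$id)]] <- tf$seq
  }
  write_fasta(seqs, path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  gid <- vapply(parts, `[`, "", 1L)
  rec <- vapply(parts, `[`, "", 2L)
  lapply(unique(gid), function(id) {
    pick <- function(what) seqs[gid == id & rec == what][1]
    genotype(pick("cis"), pick("TF1"), pick("TF2"), pick("TF3"))
  })
}

#' Read and write the contact energy matrix as TSV
#'
#' 20 rows (amino acids, alphabetical one-letter code, row names) by 4
#' columns (A, C, G, T), kT units.
#' @param m an [energy_matrix()].
#' @param path file path.
#' @param ... passed to [energy_matrix()] (e.g. `range`).
#' @export
write_energy_matrix <- function(m, path) {
  utils::write.table(format(unclass(m), digits = 17), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_energy_matrix
#' @param range permissible value range (kT); the reader is lenient by
#'   default so externally produced matrices (including the shipped
#'   synthetic default, whose favoured contacts dip slightly below -3)
#'   round-trip.
#' @export
read_energy_matrix <- function(path, range = c(-6, 6)) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  if (nrow(d) != 20L || ncol(d) != 4L)
    stop("energy matrix TSV must be 20 x 4, got ", nrow(d), " x ", ncol(d))
  if (!identical(rownames(d), AA_ALPHABET))
    stop("energy matrix rows must be the amino acids ",
         paste(AA_ALPHABET, collapse = ""))
  energy_matrix(as.matrix(d), provenance = path, range = range)
}

#' Read and write the promoter position-score model as TSV
#'
#' 12 rows (positions -35..-30 then -12..-7) by 4 columns (A, C, G, T).
#' @param pm a [promoter_model()].
#' @param path file path.
#' @export
write_promoter_model <- function(pm, path) {
  utils::write.table(format(unclass(pm), digits = 17), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_promoter_model
#' @export
read_promoter_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  if (nrow(d) != 12L || ncol(d) != 4L)
    stop("promoter model TSV must be 12 x 4, got ", nrow(d), " x ", ncol(d))
  promoter_model(as.matrix(d))
}

#' Export called binding sites as BED
#'
#' 0-based half-open intervals; name = tf:role, score = round(1000 * O_max).
#' @param calls output of [call_binding_sites()].
#' @param path file path.
#' @param chrom region name for the first column.
#' @export
write_site_calls_bed <- function(calls, path, chrom = "cis") {
  bed <- data.frame(chrom = chrom, start = calls$start, end = calls$end,
                    name = paste0(calls$tf, ":", calls$role),
                    score = round(1000 * calls$o_max), strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write evolution run logs as TSV
#' @param log the `log` data.frame of an [evolve()] run.
#' @param path file path.
#' @export
write_run_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_log
#' @export
read_run_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path)
}

#' Serialize and restore a full run configuration as JSON
#'
#' Round-trips the evolutionary configuration together with the
#' thermodynamic and dynamics parameters. The energy matrix and promoter
#' model live in their own TSV files; their paths may be recorded here.
#'
#' @param config an [evolution_config()].
#' @param path file path.
#' @param thermo,dyn parameter objects to embed.
#' @param files optional named list of data file paths (matrix, promoter,
#'   sequences) recorded verbatim.
#' @export
write_run_config <- function(config, path, thermo = thermo_params(),
                             dyn = dynamics_params(), files = list()) {
  obj <- list(
    gate = list(name = config$gate$name, threshold = config$gate$threshold,
                level_high = config$gate$level_high),
    evolution = config[c("pop_size", "cycles", "survive", "p_sub",
                         "p_indel", "p_tf", "seed", "cis_len", "cis_min",
                         "cis_max", "l_tf", "allow_autoreg")],
    weights = unclass(config$weights),
    thermo = unclass(thermo),
    dyn = unclass(dyn)[c("beta", "mu", "eps_ss", "eps_rt", "t_max", "V",
                         "fd_step")],
    files = files)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- do.call(fitness_weights, o$weights)
  ev <- o$evolution
  config <- evolution_config(
    gate = gate_spec(o$gate$name, o$gate$threshold, o$gate$level_high),
    pop_size = ev$pop_size, cycles = ev$cycles, survive = ev$survive,
    p_sub = ev$p_sub, p_indel = ev$p_indel, p_tf = ev$p_tf, seed = ev$seed,
    weights = w, cis_len = ev$cis_len, cis_min = ev$cis_min,
    cis_max = ev$cis_max, l_tf = ev$l_tf, allow_autoreg = ev$allow_autoreg)
  th <- o$thermo
  thermo <- thermo_params(th$omega_coop, th$omega_act, th$d_coop, th$d_act,
                          th$rnap, th$K0, th$K0R)
  dyn <- do.call(dynamics_params, o$dyn)
  list(config = config, thermo = thermo, dyn = dyn, files = o$files)
}

# ---------------------------------------------------------------------------
# Command-line interface

cli_usage <- function() {
  paste(
    "usage: cisevolve <command> [options]",
    "",
    "commands:",
    "  fixtures  --seed S --out DIR",
    "            write the synthetic energy matrix, promoter model and a",
    "            random genotype",
    "  evolve    --gate G --seed S --pop N --cycles C [--lambda-rt X]",
    "            [--lambda-noise X] [--matrix TSV] [--promoter TSV]",
    "            --out DIR",
    "  analyze   --pop FASTA [--matrix TSV] [--promoter TSV] --out DIR",
    "            feedback measure, footprints, site calls, simplification",
    "  footprint --genotype FASTA [--matrix TSV] [--promoter TSV] --out DIR",
    "  minimal   --layout L --out DIR  (response + sensitivity curves)",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i == length(argv) || startsWith(argv[i + 1L], "--"))
      stop("missing value for --", key)
    out[[gsub("-", "_", key)]] <- argv[i + 1L]
    i <- i + 2L
  }
  out
}

cli_models <- function(a) {
  mx <- if (!is.null(a$matrix)) read_energy_matrix(a$matrix)
        else make_synthetic_matrix()
  pm <- if (!is.null(a$promoter)) read_promoter_model(a$promoter)
        else consensus_promoter_model()
  model_set(matrix = mx, pm = pm)
}

#' Command-line entry point
#'
#' Thin wrapper over the package's functions; see `inst/cli/cisevolve` for
#' the Rscript launcher. Subcommands: `fixtures`, `evolve`, `analyze`,
#' `footprint`, `minimal`. All honour `--seed` and write their outputs under
#' `--out`.
#'
#' @param argv character vector of arguments (default: the command line).
#' @return exit status, 0 on success (invisibly).
#' @export
cisevolve_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0) {
      message(cli_usage())
      return(invisible(1L))
    }
    cmd <- argv[1]
    a <- parse_cli_args(argv[-1])
    if (is.null(a$out)) stop("--out is required")
    seed <- if (!is.null(a$seed)) as.integer(a$seed) else 1L
    switch(cmd,
      fixtures = {
        dir.create(a$out, showWarnings = FALSE, recursive = TRUE)
        write_energy_matrix(make_synthetic_matrix(seed),
                            file.path(a$out, "energy_matrix.tsv"))
        write_promoter_model(consensus_promoter_model(),
                             file.path(a$out, "promoter_model.tsv"))
        write_genotype(random_genotype(seed),
                       file.path(a$out, "genotype.fa"))
      },
      evolve = {
        models <- cli_models(a)
        config <- evolution_config(
          gate = if (!is.null(a$gate)) a$gate else "ACT",
          pop_size = if (!is.null(a$pop)) as.integer(a$pop) else 200L,
          cycles = if (!is.null(a$cycles)) as.integer(a$cycles) else 1000L,
          seed = seed,
          weights = fitness_weights(
            lambda_rt = if (!is.null(a$lambda_rt))
              as.numeric(a$lambda_rt) else 0,
            lambda_noise = if (!is.null(a$lambda_noise))
              as.numeric(a$lambda_noise) else 0))
        run <- evolve(config, models)
        dir.create(a$out, showWarnings = FALSE, recursive = TRUE)
        write_run_log(run$log, file.path(a$out, "runlog.tsv"))
        write_population(run$population, file.path(a$out, "population.fa"))
        write_run_config(config, file.path(a$out, "config.json"),
                         models$thermo, models$dyn)
      },
      analyze = {
        if (is.null(a$pop)) stop("--pop is required")
        models <- cli_models(a)
        pop <- read_population(a$pop)
        dir.create(a$out, showWarnings = FALSE, recursive = TRUE)
        res <- lapply(seq_along(pop), function(i) {
          g <- pop[[i]]
          f <- tryCatch(feedback_measure(g, models), error = function(e) NA)
          prof <- footprint(g, models)
          calls <- call_binding_sites(prof, models)
          if (nrow(calls))
            write_site_calls_bed(calls,
              file.path(a$out, sprintf("sites_g%04d.bed", i)))
          dev <- if (nrow(calls))
            simplify_and_verify(g, calls, models)$max_dev else NA
          data.frame(genotype = i, F = f, n_sites = nrow(calls),
                     simplify_max_dev = dev)
        })
        utils::write.table(do.call(rbind, res),
                           file.path(a$out, "analysis.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      footprint = {
        if (is.null(a$genotype)) stop("--genotype is required")
        models <- cli_models(a)
        g <- read_genotype(a$genotype)
        prof <- footprint(g, models)
        dir.create(a$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(prof, file.path(a$out, "footprint.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        calls <- call_binding_sites(prof, models)
        write_site_calls_bed(calls, file.path(a$out, "site_calls.bed"))
      },
      minimal = {
        layout <- if (!is.null(a$layout)) a$layout else "cond_auto_act"
        spec <- minimal_model_spec(layout)
        c1 <- exp(seq(log(1), log(10000), length.out = 200))
        resp <- as.numeric(minimal_response(spec, c1))
        dir.create(a$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(
          data.frame(c1 = c1, c3 = resp, S = sensitivity(spec, c1)),
          file.path(a$out, "minimal_curves.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      },
      stop("unknown command: ", cmd, "\n", cli_usage()))
    0L
  }, error = function(e) {
    message("cisevolve: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
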