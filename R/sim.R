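#' Simulation configuration
#'
#' Parameters of the synthetic footprint-library generator. The generative
#' model: a single 43S preinitiation stream enters each transcript at the
#' cap with unit flux; at every start codon a fraction of the stream
#' initiates (its Kozak strength) and the remainder leaky-scans onward.
#' Scanning 40S footprints are Poisson draws proportional to the surviving
#' stream per 5'UTR nucleotide; elongating 80S footprints are Poisson
#' draws proportional to the flux that initiated on each ORF, per ORF
#' nucleotide. Selective-IP libraries are binomial thinnings of the total
#' libraries with a per-position capture probability, which steps from
#' `ip_base_rate` to `ip_step_rate` part-way through the CDS on
#' "interactor" transcripts (emulating co-translational engagement of the
#' nascent chain). The "knockdown" condition multiplies every uORF
#' initiation probability by `depletion_leak_shift`, the signature of a
#' factor whose loss reduces leaky scanning.
#'
#' @param n_transcripts number of transcripts.
#' @param utr_len_range,cds_len_range,utr3_len_range inclusive nt ranges;
#'   CDS lengths are rounded to multiples of 3.
#' @param uorf_rate expected AUG-initiated uORFs per 5'UTR (Poisson mean;
#'   placement is capped by what fits in the UTR).
#' @param kozak_strengths vector of per-start initiation probabilities
#'   sampled per uORF.
#' @param morf_init initiation probability at the mORF start codon.
#' @param reinit_prob probability of resuming scanning after translating a
#'   uORF (default 0).
#' @param scan_density expected 40S reads per nt per unit scanning flux.
#' @param elong_density expected 80S reads per nt per unit initiation flux.
#' @param ip_base_rate,ip_step_rate selective-IP capture probabilities
#'   before/after the breakpoint, in (0, 1].
#' @param interactor_fraction fraction of transcripts carrying a capture
#'   step.
#' @param breakpoint_frac breakpoint position as a fraction of CDS length.
#' @param depletion_leak_shift multiplier on uORF initiation probabilities
#'   in the knockdown condition (> 1 means more uORF initiation, i.e. less
#'   leaky scanning).
#' @param rna_mean expected mRNA-seq count per gene.
#' @param seed integer RNG seed; identical seed + config give
#'   bit-identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 200,
                       utr_len_range = c(120L, 300L),
                       cds_len_range = c(300L, 1500L),
                       utr3_len_range = c(50L, 150L),
                       uorf_rate = 1,
                       kozak_strengths = c(0.05, 0.15, 0.4),
                       morf_init = 0.8,
                       reinit_prob = 0,
                       scan_density = 0.5,
                       elong_density = 1,
                       ip_base_rate = 0.1,
                       ip_step_rate = 0.5,
                       interactor_fraction = 0.1,
                       breakpoint_frac = 0.4,
                       depletion_leak_shift = 2,
                       rna_mean = 200,
                       seed = 1L) {
  cfg <- list(n_transcripts = n_transcripts, utr_len_range = utr_len_range,
              cds_len_range = cds_len_range, utr3_len_range = utr3_len_range,
              uorf_rate = uorf_rate, kozak_strengths = kozak_strengths,
              morf_init = morf_init, reinit_prob = reinit_prob,
              scan_density = scan_density, elong_density = elong_density,
              ip_base_rate = ip_base_rate, ip_step_rate = ip_step_rate,
              interactor_fraction = interactor_fraction,
              breakpoint_frac = breakpoint_frac,
              depletion_leak_shift = depletion_leak_shift,
              rna_mean = rna_mean, seed = as.integer(seed))
  for (r in c("utr_len_range", "cds_len_range", "utr3_len_range")) {
    v <- cfg[[r]]
    if (length(v) != 2 || v[1] > v[2] || v[1] < 0)
      abort(sprintf("'%s' must be a non-empty non-negative range", r))
  }
  if (cfg$utr_len_range[1] < 3)
    abort("5'UTRs must be at least 3 nt")
  if (cfg$cds_len_range[1] < 6)
    abort("CDSs must be at least 6 nt (start + stop codon)")
  probs <- c(cfg$kozak_strengths, cfg$morf_init, cfg$reinit_prob,
             cfg$ip_base_rate, cfg$ip_step_rate, cfg$interactor_fraction,
             cfg$breakpoint_frac)
  if (any(probs < 0 | probs > 1))
    abort("probabilities and fractions must lie in [0, 1]")
  if (cfg$ip_base_rate <= 0 || cfg$ip_step_rate <= 0)
    abort("IP capture rates must be positive")
  if (any(c(cfg$uorf_rate, cfg$scan_density, cfg$elong_density,
            cfg$rna_mean) < 0))
    abort("rates and densities must be non-negative")
  if (cfg$depletion_leak_shift < 0)
    abort("'depletion_leak_shift' must be non-negative")
  if (!is_count(abs(cfg$seed))) abort("'seed' must be an integer")
  structure(cfg, class = "sim_config")
}

SIM_CONDITIONS <- c("control", "knockdown")

#' Simulate a transcriptome with planted uORFs and interactors
#'
#' Generates `n_transcripts` transcript models with random 5'UTR/CDS/3'UTR
#' lengths, plants Poisson-distributed AUG-initiated uORFs in the 5'UTRs
#' (stop codons strictly upstream of the mORF start, literal ATG/stop
#' trinucleotides in the sequence, background 5'UTR sequence scrubbed of
#' spurious ATGs), and flags a random `interactor_fraction` of transcripts
#' with a capture-step breakpoint at `breakpoint_frac` of the CDS.
#'
#' @param config a [sim_config()].
#' @return list with `transcripts` (named list of [transcript_model()]s;
#'   each `uorfs` table carries the true per-uORF initiation probability)
#'   and `truth` (data.frame: `transcript_id`, `is_interactor`,
#'   `breakpoint_nt` in CDS coordinates or NA, `ip_base`, `ip_step`,
#'   `n_uorfs`, per-condition mORF initiation flux).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sense <- setdiff(all_codons(), c(STOP_CODONS, "ATG"))
  transcripts <- list()
  truth_rows <- list()
  for (i in seq_len(config$n_transcripts)) {
    set.seed(derive_seed(config$seed, 1L, i))
    id <- sprintf("tx%04d", i)
    u5 <- sample(config$utr_len_range[1]:config$utr_len_range[2], 1)
    cds_len <- 3L * sample(ceiling(config$cds_len_range[1] / 3):
                             floor(config$cds_len_range[2] / 3), 1)
    u3 <- sample(config$utr3_len_range[1]:config$utr3_len_range[2], 1)

    # plant uORFs left-to-right with random gaps; drop what does not fit
    n_u <- rpois(1, config$uorf_rate)
    u_start <- integer(); u_end <- integer(); u_p <- numeric()
    cursor <- 0L
    if (n_u > 0) for (k in seq_len(n_u)) {
      gap <- sample(3:25, 1)
      body <- sample(1:8, 1)           # codons between start and stop
      len <- 6L + 3L * body
      s <- cursor + gap
      if (s + len > u5) break
      u_start <- c(u_start, s); u_end <- c(u_end, s + len)
      u_p <- c(u_p, sample(config$kozak_strengths, 1))
      cursor <- s + len
    }

    # sequence: ATG-free 5'UTR background, then planted uORFs and mORF
    bg <- scrub_atg(random_nt(u5))
    for (k in seq_along(u_start)) {
      orf <- paste0("ATG",
                    paste(sample(sense, (u_end[k] - u_start[k]) / 3 - 2,
                                 replace = TRUE), collapse = ""),
                    sample(STOP_CODONS, 1))
      substr(bg, u_start[k] + 1, u_end[k]) <- orf
    }
    cds_seq <- paste0("ATG",
                      paste(sample(sense, cds_len / 3 - 2, replace = TRUE),
                            collapse = ""),
                      sample(STOP_CODONS, 1))
    seq <- paste0(bg, cds_seq, random_nt(u3))

    is_int <- runif(1) < config$interactor_fraction
    bp <- if (is_int) as.integer(round(config$breakpoint_frac * cds_len))
          else NA_integer_
    uorfs <- uorf_table(u_start, u_end,
                        frame = (u_start - u5) %% 3,
                        start_codon = rep("ATG", length(u_start)),
                        init_p = u_p)
    transcripts[[id]] <- transcript_model(id, utr5 = c(0L, u5),
                                          cds = c(u5, u5 + cds_len),
                                          utr3 = c(u5 + cds_len,
                                                   u5 + cds_len + u3),
                                          sequence = seq, uorfs = uorfs)
    flux_c <- morf_flux(u_p, 1, config)
    flux_k <- morf_flux(u_p, config$depletion_leak_shift, config)
    truth_rows[[id]] <- data.frame(
      transcript_id = id, is_interactor = is_int, breakpoint_nt = bp,
      ip_base = config$ip_base_rate, ip_step = config$ip_step_rate,
      n_uorfs = length(u_start),
      morf_flux_control = flux_c, morf_flux_knockdown = flux_k,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(transcripts = transcripts, truth = truth)
}

all_codons <- function() {
  nt <- c("A", "C", "G", "T")
  apply(expand.grid(nt, nt, nt), 1, paste, collapse = "")
}

random_nt <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# remove every ATG by mutating its first base; converges because the
# replacement (C) cannot complete a new ATG
scrub_atg <- function(s) {
  while (grepl("ATG", s, fixed = TRUE)) s <- sub("ATG", "CTG", s, fixed = TRUE)
  s
}

# surviving scanning flux entering the mORF, times mORF initiation prob
morf_flux <- function(uorf_p, shift, config) {
  flux <- 1
  for (p in uorf_p) {
    p_eff <- min(1, p * shift)
    init <- flux * p_eff
    flux <- flux - init + config$reinit_prob * init
  }
  flux * config$morf_init
}

# per-nt scanning flux over [0, cds_start) given uORF starts/stops and
# effective initiation probabilities (single 43S stream, leaky scanning)
scan_flux_vector <- function(tr, p_eff, config) {
  n <- tr$cds[1]
  f <- rep(1, n)
  if (!nrow(tr$uorfs)) return(f)
  flux <- 1
  events <- order(tr$uorfs$start)
  for (k in events) {
    s <- tr$uorfs$start[k]
    init <- flux * p_eff[k]
    resumed <- config$reinit_prob * init
    # stream drops at the uORF start; the reinitiating part rejoins after
    # the uORF stop codon
    if (s < n) f[(s + 1):n] <- f[(s + 1):n] - init
    e <- tr$uorfs$stop_end[k]
    if (resumed > 0 && e < n) f[(e + 1):n] <- f[(e + 1):n] + resumed
    flux <- flux - init + resumed
  }
  pmax(f, 0)
}

#' Simulate footprint libraries for one condition
#'
#' Draws the four libraries of one selective footprinting experiment
#' (total/selective x 40S/80S) for the given condition. 40S counts are
#' Poisson with mean `scan_density` times the surviving scanning flux per
#' 5'UTR nucleotide; 80S counts are Poisson with mean `elong_density`
#' times the initiation flux into each ORF, per ORF nucleotide. Selective
#' libraries are per-position binomial thinnings of the totals, with
#' capture probability `ip_base` (per truth) everywhere except downstream
#' of the breakpoint on interactor CDSs (80S only), where it is `ip_step`.
#' In the `"knockdown"` condition every uORF initiation probability is
#' multiplied by `depletion_leak_shift` (capped at 1).
#'
#' The `truth` table may be edited before calling (e.g. to plant a single
#' interactor or per-gene `ip_base` values); columns `is_interactor`,
#' `breakpoint_nt`, `ip_base` and `ip_step` are honoured per transcript.
#'
#' @param transcripts,truth output of [simulate_transcriptome()].
#' @param condition `"control"` or `"knockdown"`.
#' @param config the [sim_config()] used to generate the transcriptome.
#' @return named list of four [footprint_track()]s: `total40S`,
#'   `total80S`, `selective40S`, `selective80S`.
#' @export
simulate_footprints <- function(transcripts, truth,
                                condition = "control", config) {
  stopifnot(inherits(config, "sim_config"))
  if (!condition %in% SIM_CONDITIONS)
    abort(sprintf("unknown condition '%s' (use %s)", condition,
                  paste(SIM_CONDITIONS, collapse = "/")))
  ci <- match(condition, SIM_CONDITIONS)
  shift <- if (condition == "knockdown") config$depletion_leak_shift else 1
  tot40 <- tot80 <- sel40 <- sel80 <- list()
  for (i in seq_along(transcripts)) {
    tr <- transcripts[[i]]
    id <- tr$transcript_id
    tri <- truth[truth$transcript_id == id, , drop = FALSE]
    if (nrow(tri) != 1L) abort(sprintf("no truth row for '%s'", id))
    set.seed(derive_seed(config$seed, 2L, ci, i))
    len <- tr$length
    p_eff <- pmin(1, tr$uorfs$init_p * shift)

    # scanning 40S: surviving stream over the 5'UTR
    lam40 <- numeric(len)
    if (tr$cds[1] > 0)
      lam40[1:tr$cds[1]] <- config$scan_density *
        scan_flux_vector(tr, p_eff, config)

    # elongating 80S: per-ORF initiation flux
    lam80 <- numeric(len)
    flux <- 1
    if (nrow(tr$uorfs)) for (k in order(tr$uorfs$start)) {
      init <- flux * p_eff[k]
      rng <- (tr$uorfs$start[k] + 1):tr$uorfs$stop_end[k]
      lam80[rng] <- lam80[rng] + config$elong_density * init
      flux <- flux - init + config$reinit_prob * init
    }
    mflux <- flux * config$morf_init
    lam80[(tr$cds[1] + 1):tr$cds[2]] <-
      lam80[(tr$cds[1] + 1):tr$cds[2]] + config$elong_density * mflux

    t40 <- rpois(len, lam40)
    t80 <- rpois(len, lam80)

    p40 <- rep(tri$ip_base, len)
    p80 <- rep(tri$ip_base, len)
    if (isTRUE(tri$is_interactor) && !is.na(tri$breakpoint_nt)) {
      from <- tr$cds[1] + tri$breakpoint_nt
      if (from < tr$cds[2]) p80[(from + 1):tr$cds[2]] <- tri$ip_step
    }
    tot40[[id]] <- t40
    tot80[[id]] <- t80
    sel40[[id]] <- rbinom(len, t40, p40)
    sel80[[id]] <- rbinom(len, t80, p80)
  }
  list(total40S = footprint_track(paste0(condition, "_total40S"), "40S",
                                  "total", tot40),
       total80S = footprint_track(paste0(condition, "_total80S"), "80S",
                                  "total", tot80),
       selective40S = footprint_track(paste0(condition, "_selective40S"),
                                      "40S", "selective", sel40),
       selective80S = footprint_track(paste0(condition, "_selective80S"),
                                      "80S", "selective", sel80))
}

#' Simulate mRNA-seq counts per gene
#'
#' Poisson counts with mean `rna_mean`, identical in expectation across
#' conditions: the simulated depletion acts on translation, not on mRNA
#' abundance, so translation-efficiency changes are footprint-driven.
#'
#' @inheritParams simulate_footprints
#' @return data.frame `gene_id`, `control`, `treated`.
#' @export
simulate_rna_counts <- function(transcripts, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  counts <- vapply(seq_along(ids), function(i) {
    set.seed(derive_seed(config$seed, 3L, i))
    rpois(2, config$rna_mean)
  }, numeric(2))
  data.frame(gene_id = unname(ids), control = counts[1, ],
             treated = counts[2, ], stringsAsFactors = FALSE)
}

#' Expand a footprint track into raw read records
#'
#' Emits one `(transcript, position, length, count)` record per occupied
#' position, drawing each record's fragment length uniformly from the gel
#' size-selection window of the track's species (25-35 nt for 80S, 20-80
#' nt for 40S). The inverse of [reads_to_track()] at offset 0, up to the
#' length column; useful for exercising [filter_by_length()].
#'
#' @param track a [footprint_track()].
#' @param seed RNG seed for the length draws.
#' @return data.frame `transcript`, `position`, `length`, `count`.
#' @export
simulate_raw_reads <- function(track, seed = 1L) {
  set.seed(seed)
  w <- if (track$species == "80S") 25:35 else 20:80
  rows <- lapply(names(track$counts), function(id) {
    v <- track$counts[[id]]
    pos <- which(v > 0) - 1L
    if (!length(pos)) return(NULL)
    data.frame(transcript = id, position = pos,
               length = sample(w, length(pos), replace = TRUE),
               count = v[pos + 1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(transcript = character(), position = integer(),
                      length = integer(), count = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a full simulation to disk
#'
#' Writes the annotation (GFF3), sequences (FASTA), truth table (TSV),
#' mRNA counts (TSV) and all footprint tracks (bedGraph, one file per
#' condition/library) under `dir`.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param libraries named list of conditions, each the output of
#'   [simulate_footprints()].
#' @param rna optional data.frame from [simulate_rna_counts()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, libraries, rna = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_annotation(sim$transcripts, file.path(dir, "annotation.gff3")),
    write_sequences(sim$transcripts, file.path(dir, "sequences.fa")))
  truth_path <- file.path(dir, "truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, truth_path)
  for (cond in names(libraries)) for (lib in names(libraries[[cond]])) {
    p <- file.path(dir, sprintf("%s_%s.bedgraph", cond, lib))
    write_track(libraries[[cond]][[lib]], p)
    paths <- c(paths, p)
  }
  if (!is.null(rna)) {
    p <- file.path(dir, "rna_counts.tsv")
    write.table(rna, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
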