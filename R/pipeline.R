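#' Run the full analysis pipeline from a config
#'
#' Orchestrates simulate -> uORF annotation -> assembly scoring ->
#' metagene -> selectivity/TE as one reproducible run. The config is a
#' YAML file or an equivalent nested list with exactly one input block:
#' either `simulate:` (a [sim_config()] parameter block) or `input:`
#' (paths `annotation`, `sequences`, and named track files). Per-stage
#' parameter blocks (`score`, `metagene`, `selectivity`) override the
#' package defaults. Outputs are written under `outdir` and a manifest
#' (package version, config, seed, per-stage timings and record counts,
#' md5 checksum per output file) is written as `manifest.json`.
#'
#' @param config path to a YAML file, or a named list.
#' @param outdir output directory; overrides `config$outdir`.
#' @return the manifest, invisibly.
#' @examples
#' \donttest{
#' cfg <- list(seed = 1, outdir = tempfile(),
#'             simulate = list(n_transcripts = 20),
#'             stages = c("simulate", "uorf", "score"))
#' mf <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found",
                                            config))
    config <- yaml::read_yaml(config)
  }
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) abort("no output directory given")
  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    abort("config must supply exactly one of 'simulate' or 'input'")
  if (has_input) {
    need <- unlist(config$input[c("annotation", "sequences")], use.names = FALSE)
    need <- c(need, unlist(config$input$tracks, use.names = FALSE))
    missing <- need[!file.exists(need)]
    if (length(missing))
      abort(sprintf("input file(s) not found: %s",
                    paste(missing, collapse = ", ")))
  }
  stages <- config$stages %||%
    c("simulate", "uorf", "score", "metagene", "selectivity")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  seed <- config$seed %||% 1L
  manifest <- list(package = "riboselect",
                   version = as.character(packageVersion("riboselect")),
                   seed = seed, stages = stages, config = config,
                   outputs = list(), timings = list(), counts = list())
  state <- list()  # transcripts, truth, libraries, rna

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fun(), error = function(e) {
      manifest$failed_stage <<- name
      jsonlite::write_json(manifest,
                           file.path(outdir, "manifest.partial.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    for (f in files)
      manifest$outputs[[basename(f)]] <<- unname(tools::md5sum(f))
    files
  }

  if (has_sim) {
    if (!"simulate" %in% stages) stages <- c("simulate", stages)
  } else {
    stages <- setdiff(stages, "simulate")
    state$transcripts <- read_sequences(
      read_annotation(config$input$annotation), config$input$sequences)
    tk <- config$input$tracks
    state$libraries <- list(control = list())
    for (nm in names(tk)) {
      species <- if (grepl("40S", nm)) "40S" else "80S"
      mode <- if (grepl("selective", nm)) "selective" else "total"
      state$libraries$control[[nm]] <-
        read_track(tk[[nm]], state$transcripts, library_id = nm,
                   species = species, mode = mode)
    }
    if (!is.null(config$input$rna))
      state$rna <- read.table(config$input$rna, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }

  for (stage in stages) {
    files <- switch(stage,
      simulate = run_stage("simulate", function() {
        scfg <- do.call(sim_config, c(config$simulate %||% list(),
                                      list(seed = seed)))
        sim <- simulate_transcriptome(scfg)
        state$transcripts <<- sim$transcripts
        state$truth <<- sim$truth
        state$libraries <<- lapply(
          stats::setNames(SIM_CONDITIONS, SIM_CONDITIONS),
          function(cond) simulate_footprints(sim$transcripts, sim$truth,
                                             cond, scfg))
        state$rna <<- simulate_rna_counts(sim$transcripts, scfg)
        manifest$counts$transcripts <<- length(sim$transcripts)
        write_simulation(sim, state$libraries, state$rna, outdir)
      }),
      uorf = run_stage("uorf", function() {
        cats <- categorize_transcripts(
          state$transcripts, state$libraries[[1]]$total80S,
          min_reads = config$uorf$min_uorf_reads %||% 1)
        per_gene <- data.frame(
          gene_id = names(state$transcripts),
          n_uorfs = vapply(state$transcripts,
                           function(tr) nrow(tr$uorfs), 0),
          category = as.character(cats), stringsAsFactors = FALSE)
        manifest$counts$uorfs <<- sum(per_gene$n_uorfs)
        p <- file.path(outdir, "uorf_categories.tsv")
        write.table(per_gene, p, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        p
      }),
      score = run_stage("score", function() {
        sc <- config$score %||% list()
        tab <- score_genes(state$libraries[[1]]$selective80S,
                           state$libraries[[1]]$total80S,
                           state$transcripts,
                           n_bins = sc$n_bins %||% 100,
                           pseudocount = sc$pseudocount %||% 0.5,
                           min_counts = sc$min_counts %||% 32)
        manifest$counts$scored_genes <<- nrow(tab)
        p <- file.path(outdir, "assembly_scores.tsv")
        write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
        p
      }),
      metagene = run_stage("metagene", function() {
        mg <- config$metagene %||% list()
        trs <- annotate_translated(state$transcripts,
                                   state$libraries[[1]]$total80S)
        files <- character()
        for (cond in names(state$libraries)) {
          prof <- metagene(state$libraries[[cond]]$total80S, trs,
                           anchor = mg$anchor %||% "morf_start",
                           min_intercistronic = mg$min_intercistronic %||% 80)
          prof <- smooth_metagene(normalize_80s(prof),
                                  window = mg$smooth %||% 3)
          p <- file.path(outdir, sprintf("metagene_%s_%s.tsv", cond,
                                         prof$anchor))
          write.table(data.frame(offset = prof$offsets,
                                 value = prof$values, n = prof$n),
                      p, sep = "\t", quote = FALSE, row.names = FALSE)
          files <- c(files, p)
        }
        files
      }),
      selectivity = run_stage("selectivity", function() {
        lib1 <- state$libraries[[1]]
        stats_tab <- binding_ratio_per_gene(lib1$selective40S,
                                            lib1$total40S,
                                            state$transcripts)
        stats_tab <- decile_groups(stats_tab,
                                   config$selectivity$fraction %||% 0.1)
        files <- file.path(outdir, "binding_ratios.tsv")
        write.table(stats_tab, files[1], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        if (!is.null(state$rna) && length(state$libraries) >= 2) {
          te <- translation_efficiency(
            list(control = state$libraries[[1]]$total80S,
                 treated = state$libraries[[2]]$total80S),
            state$rna, state$transcripts)
          p <- file.path(outdir, "translation_efficiency.tsv")
          write.table(te, p, sep = "\t", quote = FALSE, row.names = FALSE)
          files <- c(files, p)
          cor_res <- correlate_binding_vs_dte(stats_tab, te)
          p2 <- file.path(outdir, "binding_dte_correlation.json")
          jsonlite::write_json(list(spearman_rho = cor_res$estimate,
                                    p_value = cor_res$p_value,
                                    n = cor_res$n),
                               p2, auto_unbox = TRUE, digits = NA)
          files <- c(files, p2)
        }
        files
      }),
      abort(sprintf("unknown stage '%s'", stage)))
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
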