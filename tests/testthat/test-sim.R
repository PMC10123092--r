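test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(utr_len_range = c(300, 120)), "range")
  expect_error(sim_config(ip_base_rate = 0), "positive")
  expect_error(sim_config(ip_step_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(scan_density = -1), "non-negative")
})

test_that("the simulated transcriptome is deterministic and well-formed", {
  cfg <- sim_config(n_transcripts = 30, seed = 5)
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(a, b)

  for (tr in a$transcripts) {
    expect_identical(substr(tr$sequence, tr$cds[1] + 1, tr$cds[1] + 3),
                     "ATG")
    expect_true(substr(tr$sequence, tr$cds[2] - 2, tr$cds[2]) %in%
                  c("TAA", "TAG", "TGA"))
    if (nrow(tr$uorfs)) {
      # literal start and stop codons at every annotated uORF
      for (k in seq_len(nrow(tr$uorfs))) {
        s <- tr$uorfs$start[k]; e <- tr$uorfs$stop_end[k]
        expect_identical(substr(tr$sequence, s + 1, s + 3), "ATG")
        expect_true(substr(tr$sequence, e - 2, e) %in%
                      c("TAA", "TAG", "TGA"))
        expect_lte(e, tr$cds[1])  # uORF stop precedes the mORF start
      }
    }
  }
  # truth breakpoint defined iff interactor
  expect_identical(is.na(a$truth$breakpoint_nt), !a$truth$is_interactor)
})

test_that("rate-zero and fraction-one edge configurations behave exactly", {
  none <- simulate_transcriptome(sim_config(n_transcripts = 25,
                                            uorf_rate = 0, seed = 2))
  expect_true(all(vapply(none$transcripts,
                         function(tr) nrow(tr$uorfs) == 0, logical(1))))
  # scrubbed background: the annotation-free 5'UTRs contain no ATG at all,
  # so sequence-based uORF calling agrees
  expect_true(all(vapply(none$transcripts, function(tr)
    nrow(find_uorfs(tr)$uorf) == 0, logical(1))))

  all_int <- simulate_transcriptome(sim_config(n_transcripts = 25,
                                               interactor_fraction = 1,
                                               seed = 2))
  expect_true(all(all_int$truth$is_interactor))
  expect_true(all(!is.na(all_int$truth$breakpoint_nt)))
})

test_that("footprint libraries obey the thinning and density model", {
  cfg <- sim_config(n_transcripts = 20, seed = 7)
  sim <- simulate_transcriptome(cfg)
  libs <- simulate_footprints(sim$transcripts, sim$truth, "control", cfg)
  expect_named(libs, c("total40S", "total80S", "selective40S",
                       "selective80S"))
  # selective is a thinning of total at every position
  for (pair in list(c("selective40S", "total40S"),
                    c("selective80S", "total80S"))) {
    for (id in names(libs[[pair[1]]]$counts)) {
      expect_true(all(libs[[pair[1]]]$counts[[id]] <=
                        libs[[pair[2]]]$counts[[id]]))
    }
  }
  # determinism at fixed seed and condition
  libs2 <- simulate_footprints(sim$transcripts, sim$truth, "control", cfg)
  expect_identical(libs, libs2)
  expect_error(simulate_footprints(sim$transcripts, sim$truth,
                                   "treated", cfg), "unknown condition")

  # zero scanning density silences the 40S libraries
  cfg0 <- sim_config(n_transcripts = 5, scan_density = 0, seed = 7)
  sim0 <- simulate_transcriptome(cfg0)
  l0 <- simulate_footprints(sim0$transcripts, sim0$truth, "control", cfg0)
  expect_identical(l0$total40S$library_size, 0L)
})

test_that("per-nt count means match the configured Poisson rates", {
  # uORF-free, interactor-free conditions: 40S rate = scan_density on the
  # 5'UTR, 80S rate = elong_density * morf_init on the CDS
  cfg <- sim_config(n_transcripts = 300, uorf_rate = 0,
                    interactor_fraction = 0, seed = 11)
  sim <- simulate_transcriptome(cfg)
  libs <- simulate_footprints(sim$transcripts, sim$truth, "control", cfg)
  utr_counts <- unlist(lapply(sim$transcripts, function(tr)
    libs$total40S$counts[[tr$transcript_id]][1:tr$cds[1]]))
  m <- mean(utr_counts); se <- sd(utr_counts) / sqrt(length(utr_counts))
  expect_lt(abs(m - cfg$scan_density), 3 * se)

  cds_counts <- unlist(lapply(sim$transcripts, function(tr)
    libs$total80S$counts[[tr$transcript_id]][(tr$cds[1] + 1):tr$cds[2]]))
  lambda <- cfg$elong_density * cfg$morf_init
  m8 <- mean(cds_counts); se8 <- sd(cds_counts) / sqrt(length(cds_counts))
  expect_lt(abs(m8 - lambda), 3 * se8)

  # selective thinning matches ip_base_rate
  sel_sum <- libs$selective80S$library_size
  tot_sum <- libs$total80S$library_size
  expect_equal(sel_sum / tot_sum, cfg$ip_base_rate, tolerance = 0.05)
})

test_that("the capture step yields the configured post/pre ratio", {
  # interactors with ip 0.05 -> 0.5 at high depth: the post/pre ratio of
  # selective/total averages to 10 across transcripts (Monte-Carlo)
  cfg <- sim_config(n_transcripts = 100, interactor_fraction = 1,
                    ip_base_rate = 0.05, ip_step_rate = 0.5,
                    elong_density = 3, uorf_rate = 0, seed = 13)
  sim <- simulate_transcriptome(cfg)
  libs <- simulate_footprints(sim$transcripts, sim$truth, "control", cfg)
  ratios <- vapply(sim$transcripts, function(tr) {
    bp <- sim$truth$breakpoint_nt[sim$truth$transcript_id ==
                                    tr$transcript_id]
    pre <- c(tr$cds[1], tr$cds[1] + bp)
    post <- c(tr$cds[1] + bp, tr$cds[2])
    (region_sum(libs$selective80S, tr$transcript_id, post) /
       region_sum(libs$total80S, tr$transcript_id, post)) /
      (region_sum(libs$selective80S, tr$transcript_id, pre) /
         region_sum(libs$total80S, tr$transcript_id, pre))
  }, numeric(1))
  expect_equal(mean(ratios), 10, tolerance = 0.1)
})

test_that("knockdown shifts 80S density onto uORFs", {
  cfg <- sim_config(n_transcripts = 80, uorf_rate = 1.5,
                    depletion_leak_shift = 2, seed = 17)
  sim <- simulate_transcriptome(cfg)
  ctl <- simulate_footprints(sim$transcripts, sim$truth, "control", cfg)
  kd <- simulate_footprints(sim$transcripts, sim$truth, "knockdown", cfg)
  uorf_density <- function(libs) {
    tot <- 0; nt <- 0
    for (tr in sim$transcripts) {
      if (!nrow(tr$uorfs)) next
      for (k in seq_len(nrow(tr$uorfs))) {
        tot <- tot + region_sum(libs$total80S, tr$transcript_id,
                                c(tr$uorfs$start[k], tr$uorfs$stop_end[k]))
        nt <- nt + tr$uorfs$stop_end[k] - tr$uorfs$start[k]
      }
    }
    tot / nt
  }
  expect_gt(uorf_density(kd), uorf_density(ctl))
})

test_that("raw read expansion respects size windows and inverts to the track", {
  cfg <- sim_config(n_transcripts = 6, seed = 19)
  sim <- simulate_transcriptome(cfg)
  libs <- simulate_footprints(sim$transcripts, sim$truth, "control", cfg)
  reads <- simulate_raw_reads(libs$total80S, seed = 3)
  expect_true(all(reads$length >= 25 & reads$length <= 35))
  expect_identical(nrow(filter_by_length(reads, "80S")), nrow(reads))
  back <- reads_to_track(reads, sim$transcripts, "back", "80S", "total")
  expect_identical(back$counts, libs$total80S$counts)

  reads40 <- simulate_raw_reads(libs$total40S, seed = 3)
  if (nrow(reads40))
    expect_true(all(reads40$length >= 20 & reads40$length <= 80))
})

test_that("RNA counts are deterministic and condition-balanced in mean", {
  cfg <- sim_config(n_transcripts = 400, rna_mean = 200, seed = 23)
  sim <- simulate_transcriptome(cfg)
  rna <- simulate_rna_counts(sim$transcripts, cfg)
  expect_identical(rna, simulate_rna_counts(sim$transcripts, cfg))
  expect_equal(mean(rna$control), 200, tolerance = 0.02)
  expect_equal(mean(rna$treated), 200, tolerance = 0.02)
})
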