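make_40s_pair <- function(n_genes = 20, sel_rate = 0.5, seed = 71,
                          utr5 = 50, codons = 10) {
  trs <- lapply(seq_len(n_genes), function(i)
    toy_transcript(sprintf("g%03d", i), utr5, codons, 0, seed = seed + i))
  names(trs) <- vapply(trs, `[[`, "", "transcript_id")
  set.seed(seed)
  tot_counts <- lapply(trs, function(tr) rpois(tr$length, 2) + 1L)
  names(tot_counts) <- names(trs)
  sel_counts <- lapply(tot_counts, function(v) rbinom(length(v), v,
                                                      sel_rate))
  tot <- toy_track(trs, tot_counts, library_id = "tot", species = "40S")
  sel <- toy_track(trs, sel_counts, library_id = "sel", species = "40S",
                   mode = "selective")
  list(trs = trs, tot = tot, sel = sel)
}

test_that("equal tracks give binding ratio 1 and zero selective stays small", {
  p <- make_40s_pair(sel_rate = 1)
  same <- binding_ratio_per_gene(p$tot, p$tot, p$trs, pseudocount = 0)
  expect_equal(same$binding_ratio, rep(1, nrow(same)))
  zero_sel <- toy_track(p$trs, library_id = "z", species = "40S",
                        mode = "selective")
  z <- binding_ratio_per_gene(zero_sel, p$tot, p$trs, pseudocount = 0.5)
  expect_true(all(z$binding_ratio > 0 & z$binding_ratio < 0.1))
  expect_error(binding_ratio_per_gene(
    toy_track(p$trs, species = "80S"), p$tot, p$trs), "40S")
})

test_that("decile groups have the documented sizes and partition the set", {
  stats <- data.frame(gene_id = sprintf("g%04d", 1:200),
                      binding_ratio = runif(200))
  g <- decile_groups(stats, 0.1)
  expect_identical(as.vector(table(g$group)[c("bottom", "top")]),
                   c(20L, 20L))
  expect_identical(sum(table(g$group)), 200L)
  expect_identical(as.vector(table(g$group)["mid"]), 160L)

  # n = 10, fraction 0.1 -> one per extreme
  small <- decile_groups(data.frame(gene_id = letters[1:10],
                                    binding_ratio = 1:10 / 10), 0.1)
  expect_identical(as.vector(table(small$group)[c("bottom", "top")]),
                   c(1L, 1L))
  expect_identical(small$group[small$gene_id == "j"],
                   factor("top", levels = c("bottom", "mid", "top")))

  # all-equal values still split deterministically via the gene-id tie-break
  ties <- decile_groups(data.frame(gene_id = letters[1:10],
                                   binding_ratio = rep(1, 10)), 0.2)
  expect_identical(as.vector(table(ties$group)[c("bottom", "top")]),
                   c(2L, 2L))
  expect_identical(sort(ties$gene_id[ties$group == "top"]), c("a", "b"))
  expect_error(decile_groups(ties[1:4, ], 0.1), "no genes")
  expect_error(decile_groups(ties, 0.6), "fraction")
})

test_that("category comparison: constants give statistic 0, separation is detected", {
  stats <- data.frame(gene_id = sprintf("g%03d", 1:60),
                      binding_ratio = rep(1, 60))
  cats <- factor(rep(c("no_uorf", "uorf_translated"), each = 30),
                 levels = c("no_uorf", "uorf_untranslated",
                            "uorf_translated"))
  names(cats) <- stats$gene_id
  res <- compare_binding_by_uorf_category(stats, cats)
  expect_equal(res$kw_statistic, 0)
  expect_equal(res$pairwise$z, 0)

  set.seed(72)
  stats2 <- data.frame(gene_id = sprintf("g%03d", 1:90),
                       binding_ratio = c(rnorm(30, 1, 0.1),
                                         rnorm(30, 1, 0.1),
                                         rnorm(30, 2, 0.1)))
  cats2 <- factor(rep(c("no_uorf", "uorf_untranslated",
                        "uorf_translated"), each = 30))
  names(cats2) <- stats2$gene_id
  res2 <- compare_binding_by_uorf_category(stats2, cats2)
  expect_lt(res2$kw_p, 1e-6)
  pw <- res2$pairwise
  sig <- pw[pw$group1 == "no_uorf" & pw$group2 == "uorf_translated", ]
  expect_lt(sig$p_adj, 1e-4)
  null_pair <- pw[pw$group1 == "no_uorf" &
                    pw$group2 == "uorf_untranslated", ]
  expect_gt(null_pair$p_adj, 0.05)
  expect_error(compare_binding_by_uorf_category(
    stats2, setNames(cats2[1:10], stats2$gene_id[1:10])), "category")
})

test_that("Dunn z statistics match the tie-corrected closed form", {
  x <- c(1, 2, 3, 4, 5, 6)
  g <- factor(rep(c("a", "b"), each = 3))
  d <- dunn_test(x, g)
  # mean ranks 2 and 5, n = 6: se = sqrt((6*7/12)*(2/3)) = sqrt(7/3)
  expect_equal(d$z, -3 / sqrt(7 / 3))
  expect_equal(d$p_raw, 2 * pnorm(-abs(d$z)))
})

test_that("translation efficiency obeys the arithmetic identities", {
  p <- make_40s_pair(n_genes = 10, seed = 73, utr5 = 30, codons = 40)
  tot80 <- toy_track(p$trs,
                     lapply(p$tot$counts, identity), library_id = "c80")
  rna <- data.frame(gene_id = names(p$trs), control = 100L,
                    treated = 100L)
  te_same <- translation_efficiency(list(control = tot80, treated = tot80),
                                    rna, p$trs)
  expect_equal(te_same$log2_dte, rep(0, 10))

  # halving one gene's treated CDS counts at constant library size gives
  # log2_dte exactly -1 (the removed reads are parked on a bulk gene)
  g1 <- toy_transcript("g1", 0, 20, 0, utr5_seq = "", seed = 80)
  bulk <- toy_transcript("bulk", 0, 20, 0, utr5_seq = "", seed = 81)
  two <- list(g1 = g1, bulk = bulk)
  ctl <- toy_track(two, list(g1 = rep(4L, 60), bulk = rep(4L, 60)),
                   library_id = "ctl")
  trt <- toy_track(two, list(g1 = rep(2L, 60), bulk = rep(6L, 60)),
                   library_id = "trt")
  rna2 <- data.frame(gene_id = c("g1", "bulk"), control = c(50L, 50L),
                     treated = c(50L, 50L))
  te <- translation_efficiency(list(control = ctl, treated = trt), rna2,
                               two, pseudocount = 0)
  expect_equal(te$log2_dte[te$gene_id == "g1"], -1)

  # genes without RNA rows are skipped with a warning
  expect_warning(te_miss <- translation_efficiency(
    list(control = tot80, treated = tot80), rna[1:8, ], p$trs),
    "without RNA")
  expect_identical(nrow(te_miss), 8L)
})

test_that("TE is invariant to scaling any one library's depth", {
  p <- make_40s_pair(n_genes = 8, seed = 74, utr5 = 30, codons = 40)
  ctl <- toy_track(p$trs, p$tot$counts, library_id = "ctl")
  trt_counts <- lapply(p$tot$counts, function(v) rev(v))
  trt <- toy_track(p$trs, trt_counts, library_id = "trt")
  rna <- data.frame(gene_id = names(p$trs),
                    control = rpois(8, 100) + 1L,
                    treated = rpois(8, 100) + 1L)
  te1 <- translation_efficiency(list(control = ctl, treated = trt), rna,
                                p$trs, pseudocount = 0)
  scaled <- toy_track(p$trs, lapply(p$tot$counts, function(v) 3L * v),
                      library_id = "ctl3")
  te2 <- translation_efficiency(list(control = scaled, treated = trt),
                                rna, p$trs, pseudocount = 0)
  expect_equal(te1$log2_dte, te2$log2_dte)
})

test_that("binding/TE correlation recovers monotone coupling and errors on tiny input", {
  stats <- data.frame(gene_id = letters[1:10], binding_ratio = 1:10 / 10)
  te_neg <- data.frame(gene_id = letters[1:10], log2_dte = -(1:10))
  expect_equal(correlate_binding_vs_dte(stats, te_neg)$estimate, -1)
  te_pos <- data.frame(gene_id = letters[1:10], log2_dte = (1:10)^2)
  expect_equal(correlate_binding_vs_dte(stats, te_pos)$estimate, 1)
  expect_error(correlate_binding_vs_dte(stats[1:2, ], te_neg[1:2, ]),
               "3 shared genes")
})
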