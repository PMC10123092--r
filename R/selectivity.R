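#' Per-gene 40S binding ratio in 5'UTRs
#'
#' For each gene, the ratio of depth-normalized selective to total 40S
#' footprint sums over the 5'UTR, with a shared pseudocount (per-million
#' scale) bounding the ratio on sparse genes. This is the per-gene
#' "binding selectivity" of the immunoprecipitated factor on scanning
#' ribosomes.
#'
#' @param selective,total 40S [footprint_track()]s.
#' @param transcripts named list of [transcript_model()]s.
#' @param pseudocount per-million pseudocount (default 0.5).
#' @param genes optional subset of gene ids (e.g. from [detected_genes()]).
#' @return data.frame `gene_id`, `binding_ratio`, `coverage` (raw total
#'   counts in the 5'UTR).
#' @export
binding_ratio_per_gene <- function(selective, total, transcripts,
                                   pseudocount = 0.5, genes = NULL) {
  if (selective$species != "40S" || total$species != "40S")
    abort("binding ratios are defined on 40S tracks")
  if (!is.null(genes)) transcripts <- transcripts[genes]
  rows <- lapply(transcripts, function(tr) {
    sel <- region_cpm(selective, tr$transcript_id, tr$utr5)
    tot <- region_cpm(total, tr$transcript_id, tr$utr5)
    data.frame(gene_id = tr$transcript_id,
               binding_ratio = (sel + pseudocount) / (tot + pseudocount),
               coverage = region_sum(total, tr$transcript_id, tr$utr5),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top/bottom binding deciles
#'
#' Ranks genes by binding ratio and labels the top and bottom
#' `floor(fraction * n)` genes; the rest are `mid`. Ties are broken by
#' gene id, for determinism.
#'
#' @param stats data.frame from [binding_ratio_per_gene()] (needs
#'   `gene_id`, `binding_ratio`).
#' @param fraction extreme fraction per tail, in (0, 0.5] (default 0.1).
#' @return `stats` with an added factor column `group` (levels `bottom`,
#'   `mid`, `top`); group sizes in the `sizes` attribute.
#' @export
decile_groups <- function(stats, fraction = 0.1) {
  if (fraction <= 0 || fraction > 0.5)
    abort("'fraction' must be in (0, 0.5]")
  n <- nrow(stats)
  k <- floor(fraction * n)
  if (k < 1) abort("fraction * n < 1: no genes per extreme group")
  ord <- order(-stats$binding_ratio, stats$gene_id)
  group <- rep("mid", n)
  group[ord[seq_len(k)]] <- "top"
  group[ord[seq.int(n - k + 1, n)]] <- "bottom"
  stats$group <- factor(group, levels = c("bottom", "mid", "top"))
  attr(stats, "sizes") <- table(stats$group)
  stats
}

#' Compare binding ratios across uORF categories
#'
#' Kruskal-Wallis omnibus test of the binding ratio across the three uORF
#' categories (no uORF / untranslated uORFs / translated uORFs), followed
#' by Dunn's pairwise rank comparisons with Bonferroni adjustment.
#'
#' @param stats data.frame from [binding_ratio_per_gene()].
#' @param categories named factor from [categorize_transcripts()] (names =
#'   gene ids).
#' @return object of class `category_comparison`: `kw_statistic`, `kw_df`,
#'   `kw_p`, `group_sizes`, and `pairwise` (data.frame of Dunn z, raw and
#'   adjusted p per pair).
#' @export
compare_binding_by_uorf_category <- function(stats, categories) {
  g <- categories[stats$gene_id]
  if (any(is.na(g))) abort("every gene in 'stats' needs a category")
  g <- droplevels(g)
  if (nlevels(g) < 2) abort("need at least 2 non-empty categories")
  if (any(table(g) == 0)) abort("empty category")
  kw <- kruskal.test(stats$binding_ratio, g)
  # all-tied data: the tie correction degenerates to 0/0; under the
  # midrank convention there is no evidence, so the statistic is 0
  if (is.nan(kw$statistic)) {
    kw$statistic <- 0
    kw$p.value <- 1
  }
  structure(list(kw_statistic = unname(kw$statistic),
                 kw_df = unname(kw$parameter), kw_p = kw$p.value,
                 group_sizes = table(g),
                 pairwise = dunn_test(stats$binding_ratio, g)),
            class = "category_comparison")
}

#' Dunn's rank-based pairwise comparisons
#'
#' Post-hoc z tests on mean ranks after a Kruskal-Wallis test, with the
#' usual tie correction, adjusted for multiplicity (Bonferroni by
#' default).
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @param method multiplicity adjustment (see [stats::p.adjust()]).
#' @return data.frame `group1`, `group2`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_test <- function(x, g, method = "bonferroni") {
  g <- droplevels(as.factor(g))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ni[p[1]] + 1 / ni[p[2]]))
    d <- rbar[p[1]] - rbar[p[2]]
    if (se == 0) 0 else d / se  # fully tied data carry no evidence
  })
  p_raw <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = unname(z),
             p_raw = unname(p_raw),
             p_adj = unname(p.adjust(p_raw, method = method)),
             stringsAsFactors = FALSE)
}

#' @export
print.category_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-squared = %.4g, df = %d, p = %.3g\n",
              x$kw_statistic, x$kw_df, x$kw_p))
  cat("Group sizes:", paste(names(x$group_sizes), x$group_sizes,
                            sep = "=", collapse = ", "), "\n")
  cat("Dunn pairwise (Bonferroni-adjusted):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Translation efficiency and its change between conditions
#'
#' Translation efficiency (TE) is the depth-normalized 80S footprint count
#' on the CDS divided by the depth-normalized mRNA-seq count, per gene and
#' condition; `log2_dte` is the log2 ratio of treated over control TE.
#' Genes with no RNA measurement are skipped with a warning. Formal
#' differential-TE significance is out of scope here: the log ratios feed
#' dedicated differential-translation tools.
#'
#' @param footprints list of two total 80S [footprint_track()]s, named
#'   `control` and `treated`.
#' @param rna data.frame with columns `gene_id`, `control`, `treated`
#'   (mRNA-seq counts).
#' @param transcripts named list of [transcript_model()]s.
#' @param pseudocount per-million pseudocount (default 0.5).
#' @param genes optional subset of gene ids.
#' @return data.frame `gene_id`, `te_control`, `te_treated`, `log2_dte`.
#' @export
translation_efficiency <- function(footprints, rna, transcripts,
                                   pseudocount = 0.5, genes = NULL) {
  if (!all(c("control", "treated") %in% names(footprints)))
    abort("'footprints' must have elements 'control' and 'treated'")
  if (!all(c("gene_id", "control", "treated") %in% names(rna)))
    abort("'rna' needs columns gene_id, control, treated")
  if (!is.null(genes)) transcripts <- transcripts[genes]
  rna_tot <- c(control = sum(rna$control), treated = sum(rna$treated))
  missing <- character()
  rows <- lapply(transcripts, function(tr) {
    i <- match(tr$transcript_id, rna$gene_id)
    if (is.na(i)) {
      missing <<- c(missing, tr$transcript_id)
      return(NULL)
    }
    te <- vapply(c("control", "treated"), function(cond) {
      fp <- region_cpm(footprints[[cond]], tr$transcript_id, tr$cds)
      rn <- rna[[cond]][i] / rna_tot[cond] * 1e6
      (fp + pseudocount) / (rn + pseudocount)
    }, numeric(1))
    data.frame(gene_id = tr$transcript_id, te_control = te[["control"]],
               te_treated = te[["treated"]],
               log2_dte = log2(te[["treated"]] / te[["control"]]),
               stringsAsFactors = FALSE)
  })
  if (length(missing))
    warning(sprintf("%d gene(s) without RNA counts skipped (e.g. %s)",
                    length(missing), missing[1]))
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Rank correlation between binding selectivity and TE change
#'
#' Spearman correlation over genes shared between a binding table and a TE
#' table; a negative coefficient means genes with stronger factor binding
#' lose more translation efficiency upon factor depletion.
#'
#' @param stats data.frame from [binding_ratio_per_gene()].
#' @param te data.frame from [translation_efficiency()].
#' @return object of class `binding_dte_cor`: `estimate` (Spearman rho),
#'   `p_value`, `n`, and `data` (the merged scatter table).
#' @export
correlate_binding_vs_dte <- function(stats, te) {
  merged <- merge(stats[, c("gene_id", "binding_ratio")],
                  te[, c("gene_id", "log2_dte")], by = "gene_id")
  if (nrow(merged) < 3) abort("need at least 3 shared genes")
  ct <- suppressWarnings(cor.test(merged$binding_ratio, merged$log2_dte,
                                  method = "spearman"))
  structure(list(estimate = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(merged), data = merged),
            class = "binding_dte_cor")
}

#' @export
print.binding_dte_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d genes), p = %.3g\n",
              x$estimate, x$n, x$p_value))
  invisible(x)
}
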