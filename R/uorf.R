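# stop codons of the standard code
STOP_CODONS <- c("TAA", "TAG", "TGA")

# single-mismatch variants of ATG used by scanning ribosomes at reduced
# efficiency
NEAR_COGNATE_STARTS <- c("CTG", "GTG", "TTG", "ACG", "ATA", "ATT", "ATC",
                         "AAG", "AGG")

#' Find upstream ORFs in a 5'UTR
#'
#' Scans the 5'UTR 5'->3' for ATG start codons (optionally also the
#' single-mismatch near-cognate set) and extends each in frame to the first
#' stop codon. An ORF whose stop codon ends at or before the mORF start is
#' a uORF; one with no in-frame stop before the mORF start is an
#' overlapping ORF (oORF) — its reading frame runs past the main start
#' codon, so a ribosome translating it cannot have initiated the mORF. A
#' stop codon that straddles the mORF start counts as oORF for the same
#' reason. Overlapping and nested uORFs are all reported; there is no
#' masking.
#'
#' @param transcript a [transcript_model()] with sequence.
#' @param allow_near_cognate also report ORFs starting at near-cognate
#'   codons (CTG, GTG, TTG, ACG, ATA, ATT, ATC, AAG, AGG). Default FALSE.
#' @return list with elements `uorf` and `oorf`, each a data.frame with
#'   columns `start`, `stop_end` (0-based half-open; for oORFs `stop_end`
#'   is the first in-frame stop anywhere in the transcript, or `NA`),
#'   `frame` (relative to the mORF start) and `start_codon`.
#' @examples
#' tr <- transcript_model("t", c(0, 13), c(13, 22), c(22, 22),
#'                        sequence = "GGATGAAATAGCCATGAAATAA")
#' find_uorfs(tr)$uorf  # one uORF at [2, 11)
#' @export
find_uorfs <- function(transcript, allow_near_cognate = FALSE) {
  seq <- transcript$sequence
  if (is.null(seq)) abort(sprintf("transcript '%s' has no sequence",
                                  transcript$transcript_id))
  cds_start <- transcript$cds[1]
  starts <- "ATG"
  if (allow_near_cognate) starts <- c(starts, NEAR_COGNATE_STARTS)
  len <- nchar(seq)
  uorf <- list(); oorf <- list()
  s_max <- cds_start - 3  # start codon must lie fully within the 5'UTR
  s <- 0
  while (s <= s_max) {
    codon <- substr(seq, s + 1, s + 3)
    if (codon %in% starts) {
      stop_end <- NA_integer_
      t <- s + 3
      while (t + 3 <= len) {
        if (substr(seq, t + 1, t + 3) %in% STOP_CODONS) {
          stop_end <- t + 3
          break
        }
        t <- t + 3
      }
      rec <- list(start = s, stop_end = stop_end,
                  frame = (s - cds_start) %% 3, start_codon = codon)
      if (!is.na(stop_end) && stop_end <= cds_start) {
        uorf[[length(uorf) + 1]] <- rec
      } else {
        oorf[[length(oorf) + 1]] <- rec
      }
    }
    s <- s + 1
  }
  as_df <- function(l) {
    if (!length(l))
      return(data.frame(start = integer(), stop_end = integer(),
                        frame = integer(), start_codon = character(),
                        stringsAsFactors = FALSE))
    data.frame(start = vapply(l, function(r) as.integer(r$start),
                              integer(1)),
               stop_end = vapply(l, function(r) as.integer(r$stop_end),
                                 integer(1)),
               frame = vapply(l, function(r) as.integer(r$frame),
                              integer(1)),
               start_codon = vapply(l, `[[`, "", "start_codon"),
               stringsAsFactors = FALSE)
  }
  list(uorf = as_df(uorf), oorf = as_df(oorf))
}

#' Annotate transcripts with detected uORFs
#'
#' Convenience wrapper: runs [find_uorfs()] on each transcript and stores
#' the result in its `uorfs` table (replacing any existing annotation).
#'
#' @inheritParams find_uorfs
#' @param transcripts named list of [transcript_model()]s with sequences.
#' @return the transcripts, with `uorfs` filled in.
#' @export
annotate_uorfs <- function(transcripts, allow_near_cognate = FALSE) {
  lapply(transcripts, function(tr) {
    found <- find_uorfs(tr, allow_near_cognate = allow_near_cognate)$uorf
    tr$uorfs <- uorf_table(found$start, found$stop_end, found$frame,
                           found$start_codon)
    tr
  })
}

#' Classify uORFs as translated from an 80S footprint track
#'
#' A uORF counts as translated when it contains at least `min_reads` 80S
#' footprints (default 1, the low-stringency rule).
#'
#' @param uorfs data.frame with `start`, `stop_end` columns (one or more
#'   uORFs of a single transcript).
#' @param track total 80S [footprint_track()].
#' @param transcript_id the transcript the uORFs belong to.
#' @param min_reads translated threshold (default 1).
#' @return logical vector, one flag per uORF.
#' @export
classify_translated <- function(uorfs, track, transcript_id, min_reads = 1) {
  if (!nrow(uorfs)) return(logical())
  vapply(seq_len(nrow(uorfs)), function(i)
    region_sum(track, transcript_id,
               c(uorfs$start[i], uorfs$stop_end[i])) >= min_reads,
    logical(1))
}

#' Set the translated flag on every transcript's uORF table
#' @param transcripts named list of [transcript_model()]s with uORFs.
#' @param track total 80S [footprint_track()].
#' @param min_reads translated threshold (default 1).
#' @export
annotate_translated <- function(transcripts, track, min_reads = 1) {
  lapply(transcripts, function(tr) {
    tr$uorfs$translated <- classify_translated(tr$uorfs, track,
                                               tr$transcript_id, min_reads)
    tr
  })
}

#' Three-way uORF category per transcript
#'
#' Partitions transcripts into those without AUG-initiated uORFs, those
#' whose annotated uORFs carry no 80S footprints (`uorf_untranslated`), and
#' those with at least one translated uORF (`uorf_translated`).
#'
#' @param transcripts named list of [transcript_model()]s with uORF tables.
#' @param track total 80S [footprint_track()].
#' @param min_reads translated threshold (default 1).
#' @return named factor with levels `no_uorf`, `uorf_untranslated`,
#'   `uorf_translated`.
#' @export
categorize_transcripts <- function(transcripts, track, min_reads = 1) {
  lab <- vapply(transcripts, function(tr) {
    if (!nrow(tr$uorfs)) return("no_uorf")
    tl <- classify_translated(tr$uorfs, track, tr$transcript_id, min_reads)
    if (any(tl)) "uorf_translated" else "uorf_untranslated"
  }, "")
  factor(lab, levels = c("no_uorf", "uorf_untranslated", "uorf_translated"))
}

#' uORF-count enrichment between gene sets (rank-sum test)
#'
#' Compares the number of AUG-initiated uORFs per 5'UTR between a target
#' and a background gene set with a two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test, and reports per-group means with 95% t confidence
#' intervals plus the per-count histogram.
#'
#' @param target_genes,background_genes disjoint, non-empty character
#'   vectors of transcript ids.
#' @param transcripts named list of [transcript_model()]s with uORF tables.
#' @return object of class `uorf_enrichment`: group sizes, means, CIs,
#'   rank-sum statistic `W`, `p_value`, and `histogram` (count frequency
#'   per group).
#' @export
uorf_count_enrichment <- function(target_genes, background_genes,
                                  transcripts) {
  if (!length(target_genes) || !length(background_genes))
    abort("both gene sets must be non-empty")
  if (length(intersect(target_genes, background_genes)))
    abort("gene sets must be disjoint")
  n_uorfs <- function(ids) vapply(ids, function(id) {
    tr <- transcripts[[id]]
    if (is.null(tr)) abort(sprintf("unknown gene '%s'", id))
    nrow(tr$uorfs)
  }, numeric(1))
  x <- n_uorfs(target_genes); y <- n_uorfs(background_genes)
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  ci <- function(v) {
    if (length(v) < 2) return(c(NA_real_, NA_real_))
    m <- mean(v); se <- sd(v) / sqrt(length(v))
    m + c(-1, 1) * qt(0.975, length(v) - 1) * se
  }
  counts <- sort(unique(c(x, y)))
  hist <- data.frame(n_uorfs = counts,
                     target = vapply(counts, function(k) mean(x == k), 0),
                     background = vapply(counts, function(k) mean(y == k), 0))
  structure(list(group_sizes = c(target = length(x),
                                 background = length(y)),
                 mean_target = mean(x), mean_background = mean(y),
                 ci_target = ci(x), ci_background = ci(y),
                 W = unname(wt$statistic), p_value = wt$p.value,
                 histogram = hist),
            class = "uorf_enrichment")
}

#' @export
print.uorf_enrichment <- function(x, ...) {
  cat(sprintf("uORF-count enrichment (Mann-Whitney): W = %g, p = %.3g\n",
              x$W, x$p_value))
  cat(sprintf("  target     n = %d, mean uORFs = %.3f\n",
              x$group_sizes["target"], x$mean_target))
  cat(sprintf("  background n = %d, mean uORFs = %.3f\n",
              x$group_sizes["background"], x$mean_background))
  invisible(x)
}

#' Binomial significance of the overlap between two gene sets
#'
#' Upper-tail binomial probability of observing at least the given overlap:
#' each of the `|A|` genes in the first set is treated as a draw with
#' success probability `|B| / universe`, and the p-value is
#' `P(X >= observed)` for `X ~ Binomial(|A|, |B|/universe)`.
#'
#' @param set_a,set_b character vectors of gene ids (subsets of the
#'   universe).
#' @param universe_size number of genes in the universe.
#' @return object of class `overlap_test`: `universe`, set sizes,
#'   `observed`, `expected` and `p_value`.
#' @examples
#' overlap_significance(letters[1:10], letters[1:10], 100)  # p = 1e-10
#' @export
overlap_significance <- function(set_a, set_b, universe_size) {
  n_a <- length(unique(set_a)); n_b <- length(unique(set_b))
  if (n_a > universe_size || n_b > universe_size)
    abort("set sizes cannot exceed the universe size")
  observed <- length(intersect(set_a, set_b))
  p <- pbinom(observed - 1, size = n_a, prob = n_b / universe_size,
              lower.tail = FALSE)
  structure(list(universe = universe_size, n_a = n_a, n_b = n_b,
                 observed = observed, expected = n_a * n_b / universe_size,
                 p_value = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Set overlap: %d of |A|=%d, |B|=%d in universe %d (expected %.2f)\n",
    x$observed, x$n_a, x$n_b, x$universe, x$expected))
  cat(sprintf("  binomial upper-tail p = %.3g\n", x$p_value))
  invisible(x)
}
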