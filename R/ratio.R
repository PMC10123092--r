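#' Selective/total footprint ratio profile along a scaled CDS
#'
#' Partitions the CDS into `n_bins` near-equal nucleotide bins (scaling
#' every CDS to 0-100% of its length) and computes, per bin, the ratio of
#' depth-normalized selective to depth-normalized total footprint sums.
#' Depth normalization divides each library's counts by its library size
#' (expressed per million assigned reads); the pseudocount is added
#' symmetrically to numerator and denominator on that per-million scale, so
#' bins with no coverage fall back to a ratio of 1 rather than being
#' dropped, keeping bin indices comparable across genes.
#'
#' @param selective,total [footprint_track()]s of the same ribosome species
#'   (selective = factor immunoprecipitation, total = input).
#' @param transcript a [transcript_model()].
#' @param n_bins number of CDS bins (default 100). CDSs shorter than
#'   `n_bins` fall back to one bin per nucleotide, with a warning.
#' @param pseudocount added to both normalized sums, in reads-per-million
#'   units (default 0.5).
#' @return Object of class `ratio_profile`: `values` (length `n_bins`),
#'   `bin_edges` (nt, 0-based half-open), `coverage` (raw total counts per
#'   bin), `pseudocount`, and `usable` (FALSE when the total library has no
#'   coverage in any bin).
#' @export
compute_ratio_profile <- function(selective, total, transcript,
                                  n_bins = 100, pseudocount = 0.5) {
  if (selective$species != total$species)
    abort("selective and total tracks must be the same ribosome species")
  id <- transcript$transcript_id
  cds <- transcript$cds
  cds_len <- cds[2] - cds[1]
  if (cds_len < n_bins) {
    warning(sprintf("transcript '%s': CDS (%d nt) shorter than %d bins; using per-nt bins",
                    id, cds_len, n_bins))
    n_bins <- cds_len
  }
  edges <- cds[1] + round(seq(0, cds_len, length.out = n_bins + 1))
  sel <- selective$counts[[id]]
  tot <- total$counts[[id]]
  if (is.null(sel) || is.null(tot))
    abort(sprintf("transcript '%s' missing from a track", id))
  sel_sum <- binned_sums(sel, edges)
  tot_sum <- binned_sums(tot, edges)
  sel_norm <- if (selective$library_size > 0)
    sel_sum / selective$library_size * 1e6 else sel_sum * 0
  tot_norm <- if (total$library_size > 0)
    tot_sum / total$library_size * 1e6 else tot_sum * 0
  values <- (sel_norm + pseudocount) / (tot_norm + pseudocount)
  values[tot_norm + pseudocount == 0] <- 0  # only reachable at pseudocount 0
  structure(list(transcript_id = id, values = values, bin_edges = edges,
                 coverage = tot_sum, pseudocount = pseudocount,
                 usable = any(tot_sum > 0)),
            class = "ratio_profile")
}

# per-bin sums of a count vector over 0-based half-open bin edges
binned_sums <- function(v, edges) {
  cs <- c(0, cumsum(v))
  cs[edges[-1] + 1] - cs[edges[-length(edges)] + 1]
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat(sprintf("<ratio_profile> %s: %d bins over CDS [%d,%d), pseudocount %g%s\n",
              x$transcript_id, length(x$values), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], x$pseudocount,
              if (x$usable) "" else " [unusable: no total coverage]"))
  invisible(x)
}

#' Co-translational assembly scores for all detected genes
#'
#' Runs [compute_ratio_profile()] + [fit_step_fast()] on every detected
#' gene and tabulates the results, sorted by descending score. With
#' replicate libraries (lists of tracks, paired by position) the score and
#' fit statistics are computed per replicate and averaged.
#'
#' @param selective,total a [footprint_track()] or list of replicate
#'   tracks (80S selective IP and matched totals).
#' @param transcripts named list of [transcript_model()]s.
#' @param n_bins,pseudocount passed to [compute_ratio_profile()].
#' @param min_counts detection threshold on total CDS counts per library
#'   (see [detected_genes()]).
#' @return data.frame with one row per detected gene: `gene_id`, `score`,
#'   `breakpoint_bin` (mean over replicates), `breakpoint_nt`
#'   (back-projected to CDS nucleotides), `mean_left`, `mean_right`, `sse`,
#'   `coverage` (total raw CDS counts) and `n_rep`; sorted by descending
#'   score.
#' @export
score_genes <- function(selective, total, transcripts, n_bins = 100,
                        pseudocount = 0.5, min_counts = 32) {
  if (inherits(selective, "footprint_track")) selective <- list(selective)
  if (inherits(total, "footprint_track")) total <- list(total)
  if (length(selective) != length(total))
    abort("selective and total replicate lists must have equal length")
  cols <- c("gene_id", "score", "breakpoint_bin", "breakpoint_nt",
            "mean_left", "mean_right", "sse", "coverage", "n_rep")
  if (!length(transcripts))
    return(stats::setNames(data.frame(character(), numeric(), numeric(),
                                      numeric(), numeric(), numeric(),
                                      numeric(), numeric(), integer(),
                                      stringsAsFactors = FALSE), cols))
  detected <- detected_genes(transcripts, total, min_counts = min_counts)
  rows <- lapply(detected, function(id) {
    tr <- transcripts[[id]]
    fits <- lapply(seq_along(selective), function(r) {
      prof <- compute_ratio_profile(selective[[r]], total[[r]], tr,
                                    n_bins = n_bins,
                                    pseudocount = pseudocount)
      if (!prof$usable) return(NULL)
      list(fit = fit_step_fast(prof), prof = prof)
    })
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) return(NULL)
    bp_bin <- mean(vapply(fits, function(f) f$fit$breakpoint, numeric(1)))
    edges <- fits[[1]]$prof$bin_edges
    bp_nt <- edges[pmin(round(bp_bin) + 1, length(edges))] - tr$cds[1]
    data.frame(gene_id = id,
               score = mean(vapply(fits, function(f) f$fit$score, numeric(1))),
               breakpoint_bin = bp_bin,
               breakpoint_nt = bp_nt,
               mean_left = mean(vapply(fits, function(f) f$fit$mean_left,
                                       numeric(1))),
               mean_right = mean(vapply(fits, function(f) f$fit$mean_right,
                                        numeric(1))),
               sse = mean(vapply(fits, function(f) f$fit$sse, numeric(1))),
               coverage = sum(vapply(seq_along(total), function(r)
                 region_sum(total[[r]], id, tr$cds), numeric(1))),
               n_rep = length(fits), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    return(stats::setNames(data.frame(character(), numeric(), numeric(),
                                      numeric(), numeric(), numeric(),
                                      numeric(), numeric(), integer(),
                                      stringsAsFactors = FALSE), cols))
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
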