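# Fixture builders shared across test files.

# toy transcript: utr5_len | cds (multiple of 3, starts ATG, ends TAA) | utr3
toy_transcript <- function(id = "t1", utr5_len = 20, cds_codons = 4,
                           utr3_len = 10, utr5_seq = NULL, seed = 1) {
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  u5 <- utr5_seq %||% paste(sample(c("C", "G", "T"), utr5_len,
                                   replace = TRUE), collapse = "")
  utr5_len <- nchar(u5)
  body <- paste(sample(c("AAA", "CCC", "GGG", "CCA", "GGT"),
                       cds_codons - 2, replace = TRUE), collapse = "")
  cds <- paste0("ATG", body, "TAA")
  u3 <- paste(sample(nt, utr3_len, replace = TRUE), collapse = "")
  transcript_model(id, utr5 = c(0, utr5_len),
                   cds = c(utr5_len, utr5_len + nchar(cds)),
                   utr3 = c(utr5_len + nchar(cds),
                            utr5_len + nchar(cds) + utr3_len),
                   sequence = paste0(u5, cds, u3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# track over given transcripts with explicit count vectors (named list),
# zero-filled where not given
toy_track <- function(transcripts, counts = list(), library_id = "lib",
                      species = "80S", mode = "total") {
  full <- lapply(transcripts, function(tr) {
    v <- counts[[tr$transcript_id]]
    if (is.null(v)) integer(tr$length) else as.integer(v)
  })
  names(full) <- vapply(transcripts, `[[`, "", "transcript_id")
  footprint_track(library_id, species, mode, full)
}

# independent brute-force uORF oracle: enumerate every (position, frame)
# over all three frames with substring arithmetic; no shared code with
# find_uorfs()
brute_force_uorfs <- function(seq, cds_start,
                              starts = "ATG",
                              stops = c("TAA", "TAG", "TGA")) {
  hits <- list()
  for (s in 0:(cds_start - 3)) {
    if (!substr(seq, s + 1, s + 3) %in% starts) next
    stop_end <- NA
    positions <- seq(s + 3, nchar(seq) - 3, by = 3)
    for (t in positions) {
      if (substr(seq, t + 1, t + 3) %in% stops) { stop_end <- t + 3; break }
    }
    if (!is.na(stop_end) && stop_end <= cds_start)
      hits[[length(hits) + 1]] <- c(start = s, stop_end = stop_end)
  }
  if (!length(hits)) return(data.frame(start = integer(),
                                       stop_end = integer()))
  as.data.frame(do.call(rbind, hits))
}

# exhaustive step-fit oracle written independently (no prefix sums, no
# tie tolerance): plain argmin with deterministic first-minimum tie-break
oracle_step_fit <- function(x) {
  n <- length(x)
  sse <- vapply(1:(n - 1), function(b) {
    l <- x[1:b]; r <- x[(b + 1):n]
    sum((l - mean(l))^2) + sum((r - mean(r))^2)
  }, numeric(1))
  b <- which.min(sse)
  list(breakpoint = b, mean_left = mean(x[1:b]),
       mean_right = mean(x[(b + 1):n]), sse = sse[b],
       score = mean(x[(b + 1):n]) - mean(x[1:b]))
}
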