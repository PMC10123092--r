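#' Transcript model in transcript coordinates
#'
#' A transcript model holds the 5'UTR, CDS and 3'UTR of one transcript as
#' 0-based half-open intervals in transcript space, together with an
#' optional nucleotide sequence and a table of upstream ORFs (uORFs). The
#' CDS starts with the main-ORF (mORF) start codon and its final three
#' nucleotides are the stop codon.
#'
#' @param transcript_id single string.
#' @param utr5,cds,utr3 numeric `(start, end)` pairs, 0-based half-open.
#'   They must tile the transcript: `utr5[2] == cds[1]`, `cds[2] == utr3[1]`.
#' @param sequence optional nucleotide string of length `utr3[2]`. When
#'   present it must carry `ATG` at the CDS start.
#' @param uorfs optional uORF table as returned by [uorf_table()].
#' @return An object of class `transcript_model`.
#' @seealso [read_annotation()], [find_uorfs()]
#' @export
transcript_model <- function(transcript_id, utr5, cds, utr3,
                             sequence = NULL, uorfs = NULL) {
  if (!is.character(transcript_id) || length(transcript_id) != 1L)
    abort("'transcript_id' must be a single string")
  check_interval(utr5, "utr5"); check_interval(cds, "cds")
  check_interval(utr3, "utr3")
  if (!(utr5[1] == 0 && utr5[2] == cds[1] && cds[2] == utr3[1]))
    abort(sprintf("transcript %s: utr5/cds/utr3 must tile the transcript",
                  transcript_id))
  if (cds[2] <= cds[1] || (cds[2] - cds[1]) %% 3 != 0)
    abort(sprintf("transcript %s: CDS length must be a positive multiple of 3",
                  transcript_id))
  len <- utr3[2]
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != len)
      abort(sprintf("transcript %s: sequence length %d != annotated length %d",
                    transcript_id, nchar(sequence), len))
    if (substr(sequence, cds[1] + 1, cds[1] + 3) != "ATG")
      abort(sprintf("transcript %s: no ATG at CDS start", transcript_id))
  }
  uorfs <- uorfs %||% uorf_table()
  bad <- uorfs$stop_end > cds[1]
  if (any(bad))
    abort(sprintf("transcript %s: uORF stop beyond CDS start", transcript_id))
  structure(list(transcript_id = transcript_id, length = len,
                 utr5 = unname(utr5), cds = unname(cds), utr3 = unname(utr3),
                 sequence = sequence, uorfs = uorfs),
            class = "transcript_model")
}

#' uORF table constructor
#'
#' @param start,stop_end 0-based transcript coordinates; `stop_end` is one
#'   past the last nucleotide of the stop codon.
#' @param frame reading frame relative to the mORF start (`(start - cds
#'   start) %% 3`).
#' @param start_codon trinucleotide at `start`.
#' @param init_p optional per-uORF initiation probability (simulator truth).
#' @param translated optional logical flag set by [annotate_translated()].
#' @return data.frame with one row per uORF.
#' @export
uorf_table <- function(start = integer(), stop_end = integer(),
                       frame = integer(), start_codon = character(),
                       init_p = rep(NA_real_, length(start)),
                       translated = rep(NA, length(start))) {
  stopifnot(length(stop_end) == length(start))
  if (length(start) && any(stop_end - start < 6 | (stop_end - start) %% 3 != 0))
    abort("uORF lengths must be multiples of 3 and at least 6 nt")
  data.frame(start = as.integer(start), stop_end = as.integer(stop_end),
             frame = as.integer(frame), start_codon = as.character(start_codon),
             init_p = as.numeric(init_p), translated = as.logical(translated),
             stringsAsFactors = FALSE)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%d nt)\n", x$transcript_id, x$length))
  cat(sprintf("  5'UTR [%d,%d)  CDS [%d,%d)  3'UTR [%d,%d)\n",
              x$utr5[1], x$utr5[2], x$cds[1], x$cds[2], x$utr3[1], x$utr3[2]))
  cat(sprintf("  uORFs: %d; sequence: %s\n", nrow(x$uorfs),
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

#' Footprint track: per-transcript count vectors for one library
#'
#' @param library_id single string naming the library.
#' @param species `"40S"` (scanning/initiating) or `"80S"` (elongating).
#' @param mode `"total"` or `"selective"` (factor-IP).
#' @param counts named list of non-negative integer vectors, one per
#'   transcript, each of the transcript's length.
#' @return Object of class `footprint_track`; `library_size` is the total
#'   number of assigned reads (sum over all vectors).
#' @export
footprint_track <- function(library_id, species = c("40S", "80S"),
                            mode = c("total", "selective"), counts) {
  species <- match.arg(species); mode <- match.arg(mode)
  if (!is.list(counts) || is.null(names(counts)) || any(names(counts) == ""))
    abort("'counts' must be a named list of integer vectors")
  counts <- lapply(counts, function(v) {
    if (any(v < 0) || any(v != round(v)))
      abort("counts must be non-negative integers")
    as.integer(v)
  })
  lib_size <- sum(vapply(counts, function(v) sum(as.numeric(v)),
                         numeric(1)))
  if (lib_size <= .Machine$integer.max) lib_size <- as.integer(lib_size)
  structure(list(library_id = library_id, species = species, mode = mode,
                 counts = counts, library_size = lib_size),
            class = "footprint_track")
}

#' @export
print.footprint_track <- function(x, ...) {
  cat(sprintf("<footprint_track> %s (%s %s): %d transcripts, %s reads\n",
              x$library_id, x$species, x$mode, length(x$counts),
              format(x$library_size, big.mark = ",")))
  invisible(x)
}

#' Sum footprint counts over a transcript interval
#'
#' @param track a [footprint_track()].
#' @param transcript_id transcript name present in the track.
#' @param interval 0-based half-open `(start, end)` within the transcript.
#' @return integer count.
#' @export
region_sum <- function(track, transcript_id, interval) {
  v <- track$counts[[transcript_id]]
  if (is.null(v)) abort(sprintf("transcript '%s' not in track '%s'",
                                transcript_id, track$library_id))
  check_interval(interval)
  if (interval[1] < 0 || interval[2] > length(v))
    abort(sprintf("interval [%d,%d) outside transcript '%s' (length %d)",
                  interval[1], interval[2], transcript_id, length(v)))
  if (interval[1] == interval[2]) return(0L)
  sum(v[(interval[1] + 1):interval[2]])
}

# depth-normalized (counts-per-million) region sum
region_cpm <- function(track, transcript_id, interval) {
  if (track$library_size == 0) return(0)
  region_sum(track, transcript_id, interval) / track$library_size * 1e6
}

#' Filter raw footprint records by read length
#'
#' Mimics the gel size-selection windows used during library preparation:
#' 80S (elongating-ribosome) libraries keep 25-35 nt fragments, 40S
#' (scanning-ribosome) libraries keep 20-80 nt fragments. Bounds are
#' inclusive.
#'
#' @param reads data.frame with columns `transcript`, `position`, `length`,
#'   `count`.
#' @param species `"40S"` or `"80S"`.
#' @param windows named list giving the inclusive length window per species.
#' @return the filtered data.frame.
#' @export
filter_by_length <- function(reads, species = c("40S", "80S"),
                             windows = list(`80S` = c(25L, 35L),
                                            `40S` = c(20L, 80L))) {
  species <- match.arg(species)
  need <- c("transcript", "position", "length", "count")
  if (!all(need %in% names(reads)))
    abort("'reads' needs columns transcript, position, length, count")
  if (any(reads$length <= 0)) abort("read lengths must be positive")
  w <- windows[[species]]
  reads[reads$length >= w[1] & reads$length <= w[2], , drop = FALSE]
}

#' Assemble a footprint track from raw read records
#'
#' Each read is assigned to a single nucleotide: its 5' end plus a fixed
#' species-specific offset (P-site calibration is a property of the
#' protocol, so the offset is explicit configuration; default 0).
#'
#' @inheritParams filter_by_length
#' @param transcripts named list of [transcript_model()]s (defines lengths).
#' @param library_id,species,mode passed to [footprint_track()].
#' @param offset nt added to each read's 5' position before assignment.
#' @param drop_outside drop reads whose assigned position falls outside the
#'   transcript (default) instead of erroring.
#' @return a [footprint_track()].
#' @export
reads_to_track <- function(reads, transcripts, library_id,
                           species = c("40S", "80S"),
                           mode = c("total", "selective"),
                           offset = 0L, drop_outside = TRUE) {
  species <- match.arg(species); mode <- match.arg(mode)
  counts <- lapply(transcripts, function(tr) integer(tr$length))
  names(counts) <- vapply(transcripts, `[[`, "", "transcript_id")
  if (nrow(reads)) {
    pos <- as.integer(reads$position) + as.integer(offset)
    for (i in seq_len(nrow(reads))) {
      id <- reads$transcript[i]
      if (is.null(counts[[id]]))
        abort(sprintf("read references unknown transcript '%s'", id))
      p <- pos[i]
      if (p < 0 || p >= length(counts[[id]])) {
        if (drop_outside) next
        abort(sprintf("position %d outside transcript '%s'", p, id))
      }
      counts[[id]][p + 1] <- counts[[id]][p + 1] + as.integer(reads$count[i])
    }
  }
  footprint_track(library_id, species, mode, counts)
}

#' Detected-gene filter
#'
#' A gene counts as detected when its total 80S CDS footprint count reaches
#' `min_counts` in every supplied library; ratio statistics are unstable
#' below that depth.
#'
#' @param transcripts named list of [transcript_model()]s.
#' @param tracks a [footprint_track()] or list of them (total 80S).
#' @param min_counts minimum CDS count per library (default 32).
#' @return character vector of detected transcript ids.
#' @export
detected_genes <- function(transcripts, tracks, min_counts = 32) {
  if (inherits(tracks, "footprint_track")) tracks <- list(tracks)
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  keep <- vapply(seq_along(transcripts), function(i) {
    tr <- transcripts[[i]]
    all(vapply(tracks, function(tk)
      region_sum(tk, tr$transcript_id, tr$cds) >= min_counts, logical(1)))
  }, logical(1))
  unname(ids[keep])
}
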