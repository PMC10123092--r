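#' Read transcript annotation (GFF3 or BED12)
#'
#' GFF3 files are expected in transcript space: the seqid of every feature
#' is the transcript id, with `transcript`, `five_prime_UTR`, `CDS` and
#' optional `uORF` features (1-based inclusive coordinates, as GFF3
#' mandates). BED12 files use chrom = transcript id and thickStart/thickEnd
#' for the CDS (already 0-based half-open). Coordinates are converted to
#' the package-wide 0-based half-open transcript frame.
#'
#' Transcripts whose CDS length is not a multiple of 3 are skipped with a
#' warning rather than aborting the whole file.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed12"`.
#' @return named list of [transcript_model()]s.
#' @seealso [write_annotation()]
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  if (format == "bed12") return(read_annotation_bed12(path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  models <- list()
  for (id in unique(as.character(df$seqnames))) {
    sub <- df[df$seqnames == id, , drop = FALSE]
    trow <- sub[sub$type == "transcript", , drop = FALSE]
    crow <- sub[sub$type == "CDS", , drop = FALSE]
    if (nrow(trow) != 1L || nrow(crow) != 1L) {
      warning(sprintf("transcript '%s': missing transcript/CDS feature; skipped",
                      id))
      next
    }
    len <- trow$end
    cds <- c(crow$start - 1L, crow$end)  # GFF3 1-based inclusive -> half-open
    if ((cds[2] - cds[1]) %% 3 != 0) {
      warning(sprintf("transcript '%s': CDS length not divisible by 3; skipped",
                      id))
      next
    }
    urow <- sub[sub$type == "uORF", , drop = FALSE]
    uorfs <- if (nrow(urow)) {
      st <- as.integer(urow$start - 1L)
      en <- as.integer(urow$end)
      uorf_table(start = st, stop_end = en, frame = (st - cds[1]) %% 3,
                 start_codon = rep("ATG", length(st)))
    } else NULL
    models[[id]] <- transcript_model(id, utr5 = c(0L, cds[1]), cds = cds,
                                     utr3 = c(cds[2], len), uorfs = uorfs)
  }
  models
}

read_annotation_bed12 <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 8) abort("BED12 file needs at least 8 columns")
  models <- list()
  for (i in seq_len(nrow(bed))) {
    id <- as.character(bed[i, 4])  # name column carries transcript id
    len <- bed[i, 3] - bed[i, 2]
    cds <- c(bed[i, 7], bed[i, 8]) - bed[i, 2]
    if ((cds[2] - cds[1]) %% 3 != 0) {
      warning(sprintf("transcript '%s': CDS length not divisible by 3; skipped",
                      id))
      next
    }
    models[[id]] <- transcript_model(id, utr5 = c(0, cds[1]), cds = cds,
                                     utr3 = c(cds[2], len))
  }
  models
}

#' Write transcript annotation as GFF3
#'
#' @param transcripts named list of [transcript_model()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(transcripts, path) {
  rows <- lapply(transcripts, function(tr) {
    id <- tr$transcript_id
    feats <- data.frame(
      seqnames = id,
      start = c(1L, if (tr$utr5[2] > 0) tr$utr5[1] + 1L, tr$cds[1] + 1L,
                if (nrow(tr$uorfs)) tr$uorfs$start + 1L),
      end = c(tr$length, if (tr$utr5[2] > 0) tr$utr5[2], tr$cds[2],
              if (nrow(tr$uorfs)) tr$uorfs$stop_end),
      type = c("transcript", if (tr$utr5[2] > 0) "five_prime_UTR", "CDS",
               rep("uORF", nrow(tr$uorfs))),
      stringsAsFactors = FALSE)
    feats$ID <- paste0(id, ":", feats$type,
                       stats::ave(seq_len(nrow(feats)), feats$type,
                                  FUN = seq_along))
    feats
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               type = df$type, ID = df$ID,
                               phase = ifelse(df$type == "CDS", 0L,
                                              NA_integer_))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write transcript sequences as FASTA
#' @param transcripts named list of [transcript_model()]s with sequences.
#' @param path output file.
#' @export
write_sequences <- function(transcripts, path) {
  seqs <- vapply(transcripts, function(tr) {
    if (is.null(tr$sequence))
      abort(sprintf("transcript '%s' has no sequence", tr$transcript_id))
    tr$sequence
  }, "")
  names(seqs) <- vapply(transcripts, `[[`, "", "transcript_id")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Attach FASTA sequences to transcript models
#' @param transcripts named list of [transcript_model()]s.
#' @param path FASTA file whose names match transcript ids.
#' @export
read_sequences <- function(transcripts, path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  lapply(transcripts, function(tr) {
    i <- match(tr$transcript_id, nm)
    if (is.na(i))
      abort(sprintf("no sequence for transcript '%s'", tr$transcript_id))
    transcript_model(tr$transcript_id, tr$utr5, tr$cds, tr$utr3,
                     sequence = as.character(ss[[i]]), uorfs = tr$uorfs)
  })
}

#' Read a footprint track (bedGraph or TSV)
#'
#' bedGraph records are 0-based half-open (`transcript start end count`);
#' the TSV form has a header `transcript position count` with one
#' nucleotide per row. Records at the same position are summed.
#'
#' @param path file path.
#' @param transcripts named list of [transcript_model()]s (provides
#'   transcript lengths; every record must fall inside them).
#' @param library_id,species,mode passed to [footprint_track()].
#' @param format `"auto"` (by extension), `"bedgraph"` or `"tsv"`.
#' @return a [footprint_track()].
#' @export
read_track <- function(path, transcripts, library_id = basename(path),
                       species = c("40S", "80S"),
                       mode = c("total", "selective"),
                       format = c("auto", "bedgraph", "tsv")) {
  species <- match.arg(species); mode <- match.arg(mode)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedgraph" else "tsv"
  counts <- lapply(transcripts, function(tr) integer(tr$length))
  names(counts) <- vapply(transcripts, `[[`, "", "transcript_id")
  add <- function(id, from0, to0, value) {
    v <- counts[[id]]
    if (is.null(v)) abort(sprintf("track references unknown transcript '%s'", id))
    if (from0 < 0 || to0 > length(v))
      abort(sprintf("record [%d,%d) outside transcript '%s' (length %d)",
                    from0, to0, id, length(v)))
    counts[[id]][(from0 + 1):to0] <<- v[(from0 + 1):to0] + as.integer(value)
  }
  nonempty <- length(readLines(path, n = 1L)) > 0
  if (nonempty && format == "bedgraph") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    for (i in seq_along(gr)) {
      add(as.character(GenomicRanges::seqnames(gr)[i]),
          GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i],
          gr$score[i])
    }
  } else if (nonempty) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    for (i in seq_len(nrow(df)))
      add(df$transcript[i], df$position[i], df$position[i] + 1L, df$count[i])
  }
  footprint_track(library_id, species, mode, counts)
}

#' Write a footprint track as bedGraph
#' @param track a [footprint_track()].
#' @param path output file.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(track$counts)) {
    v <- track$counts[[id]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # already 0-based half-open
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%d", id, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}
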