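#' Collect footprint signal around anchor codons
#'
#' Builds the per-anchor matrix underlying a metagene profile: one row per
#' anchor (a start or stop codon of the mORF or of a uORF), one column per
#' offset in `window`, entries taken from the track's count vector.
#' Offsets falling outside a transcript are masked (`NA`) rather than
#' zero-filled, so short 5'UTRs do not drag the aggregate down.
#'
#' For uORF anchors, only uORFs that are AUG-initiated, flagged as
#' translated (see [annotate_translated()]) and separated from the mORF
#' start by an intercistronic distance of at least `min_intercistronic`
#' nucleotides are used; the distance filter keeps uORF-stop signal from
#' bleeding into main-start signal.
#'
#' @param track a [footprint_track()].
#' @param transcripts named list of [transcript_model()]s.
#' @param anchor one of `"morf_start"`, `"morf_stop"`, `"uorf_start"`,
#'   `"uorf_stop"`; the anchor position is the first nucleotide of the
#'   codon, at offset 0.
#' @param window integer `(from, to)` offsets relative to the anchor
#'   (inclusive). Defaults: `c(-100, 200)` for start anchors, `c(-200,
#'   100)` for stop anchors.
#' @param min_intercistronic minimum nt between uORF stop and mORF start
#'   (uORF anchors only; default 80).
#' @param require_translated require the translated flag on uORF anchors
#'   (default TRUE).
#' @param ids optional subset of transcript ids.
#' @return numeric matrix (anchors x offsets) with an `offsets` attribute.
#' @export
collect_anchored <- function(track, transcripts,
                             anchor = c("morf_start", "morf_stop",
                                        "uorf_start", "uorf_stop"),
                             window = NULL, min_intercistronic = 80,
                             require_translated = TRUE, ids = NULL) {
  anchor <- match.arg(anchor)
  window <- window %||%
    if (anchor %in% c("morf_start", "uorf_start")) c(-100L, 200L)
    else c(-200L, 100L)
  if (!is.null(ids)) transcripts <- transcripts[ids]
  offsets <- seq.int(window[1], window[2])
  rows <- list()
  filt_desc <- if (startsWith(anchor, "uorf"))
    sprintf("AUG start%s, intercistronic >= %d nt",
            if (require_translated) ", translated" else "",
            min_intercistronic)
  else "none"
  for (tr in transcripts) {
    v <- track$counts[[tr$transcript_id]]
    if (is.null(v)) next
    anchors <- switch(anchor,
      morf_start = tr$cds[1],
      morf_stop = tr$cds[2] - 3L,
      uorf_start = ,
      uorf_stop = {
        u <- tr$uorfs
        if (!nrow(u)) integer() else {
          keep <- u$start_codon == "ATG" &
            (tr$cds[1] - u$stop_end) >= min_intercistronic
          if (require_translated) keep <- keep & !is.na(u$translated) &
              u$translated
          u <- u[keep, , drop = FALSE]
          if (anchor == "uorf_start") u$start else u$stop_end - 3L
        }
      })
    for (a in anchors) {
      pos <- a + offsets
      ok <- pos >= 0 & pos < tr$length
      row <- rep(NA_real_, length(offsets))
      row[ok] <- v[pos[ok] + 1L]
      rows[[paste0(tr$transcript_id, "@", a)]] <- row
    }
  }
  if (!length(rows))
    abort(sprintf("no anchors left for '%s' after filters: %s",
                  anchor, filt_desc))
  m <- do.call(rbind, rows)
  colnames(m) <- offsets
  attr(m, "offsets") <- offsets
  m
}

#' Metagene profile around an anchor codon
#'
#' Aggregates [collect_anchored()] rows into a per-offset mean, dividing at
#' each offset by the number of transcripts actually contributing there
#' (masked offsets from short UTRs are excluded from the denominator).
#'
#' @inheritParams collect_anchored
#' @return object of class `metagene_profile` with `anchor`, `offsets`,
#'   `values`, `n` (contributing anchors per offset), `n_features`,
#'   `normalization` (empty until a normalize step is applied) and
#'   `smoothing` (NA until [smooth_metagene()] is applied).
#' @seealso [normalize_80s()], [normalize_scanning()], [smooth_metagene()]
#' @export
metagene <- function(track, transcripts, anchor = "morf_start",
                     window = NULL, min_intercistronic = 80,
                     require_translated = TRUE, ids = NULL) {
  m <- collect_anchored(track, transcripts, anchor, window,
                        min_intercistronic, require_translated, ids)
  n <- as.integer(colSums(!is.na(m)))
  values <- ifelse(n > 0, colSums(m, na.rm = TRUE) / pmax(n, 1), NA_real_)
  structure(list(anchor = anchor, offsets = attr(m, "offsets"),
                 values = unname(values), n = unname(n), n_features = nrow(m),
                 library_id = track$library_id, species = track$species,
                 library_size = track$library_size,
                 normalization = character(), smoothing = NA_integer_),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %s @ %s: offsets %d..%d, %d anchors\n",
              x$library_id, x$anchor, min(x$offsets), max(x$offsets),
              x$n_features))
  if (length(x$normalization))
    cat("  normalization:", paste(x$normalization, collapse = ", "), "\n")
  if (!is.na(x$smoothing))
    cat(sprintf("  smoothed: %d nt sliding window\n", x$smoothing))
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, xlab = "offset (nt)",
                                  ylab = "footprint signal", type = "l",
                                  ...) {
  plot(x$offsets, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' Normalize 80S metagene profiles for library sequencing depth
#'
#' Divides a profile's values by its library size, expressed per million
#' assigned reads, so traces from libraries of different depth are
#' comparable.
#'
#' @param profiles a `metagene_profile` or list of them.
#' @param library_size optional override; defaults to the size recorded in
#'   each profile.
#' @return profile(s) with the same shape, depth-normalized.
#' @export
normalize_80s <- function(profiles, library_size = NULL) {
  one <- function(p) {
    ls <- library_size %||% p$library_size
    if (is.null(ls) || ls == 0) abort("library size is zero; cannot normalize")
    p$values <- p$values / ls * 1e6
    p$normalization <- c(p$normalization, "library_size")
    p
  }
  if (inherits(profiles, "metagene_profile")) one(profiles)
  else lapply(profiles, one)
}

#' Equalize scanning-ribosome signal across 40S metagene profiles
#'
#' Rescales each 40S profile so that its summed signal over the scanning
#' window upstream of the start codon (default offsets -100..-80, i.e.
#' 80-100 nt upstream) matches the first profile's. This puts libraries on
#' a common "number of scanning ribosomes approaching the start codon"
#' scale, so downstream differences reflect initiation behaviour rather
#' than library depth.
#'
#' @param profiles list of `metagene_profile`s sharing an offset grid; the
#'   first is the reference.
#' @param scan_window inclusive offset range used for equalization
#'   (default `c(-100, -80)`).
#' @return list of rescaled profiles.
#' @export
normalize_scanning <- function(profiles, scan_window = c(-100, -80)) {
  if (inherits(profiles, "metagene_profile")) profiles <- list(profiles)
  sums <- vapply(profiles, function(p) {
    sel <- p$offsets >= scan_window[1] & p$offsets <= scan_window[2]
    if (!any(sel)) abort("scan_window outside the profile's offsets")
    s <- sum(p$values[sel], na.rm = TRUE)
    if (s == 0) abort(sprintf("library '%s': no scanning signal in window",
                              p$library_id))
    s
  }, numeric(1))
  ref <- sums[1]
  mapply(function(p, s) {
    p$values <- p$values * (ref / s)
    p$normalization <- c(p$normalization, "scanning_region")
    p
  }, profiles, sums, SIMPLIFY = FALSE)
}

#' Sliding-window smoothing of a metagene trace
#'
#' Centred moving average; a 3-nt window removes the triplet periodicity
#' of elongating-ribosome footprints. At the edges the window shrinks
#' symmetrically to what fits, so no positions are lost.
#'
#' @param x a `metagene_profile` or numeric vector.
#' @param window window width in nt (>= 1; odd widths are symmetric).
#' @return same type as `x`, smoothed.
#' @export
smooth_metagene <- function(x, window = 3) {
  if (window < 1) abort("window must be >= 1")
  smooth_vec <- function(v) {
    n <- length(v)
    half <- floor((window - 1) / 2)
    vapply(seq_len(n), function(i) {
      k <- min(half, i - 1L, n - i)
      mean(v[(i - k):(i + k)], na.rm = TRUE)
    }, numeric(1))
  }
  if (inherits(x, "metagene_profile")) {
    x$values <- smooth_vec(x$values)
    x$smoothing <- as.integer(window)
    x
  } else smooth_vec(as.numeric(x))
}
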