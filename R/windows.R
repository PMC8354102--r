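#' Transcription unit
#'
#' A transcription unit (TU) is a TSS-PAS pair with an exon mask on one
#' strand; intronic windows between TSS and PAS are the coordinate frame
#' for all gene-body analyses. Coordinates are 0-based half-open
#' internally; `tss` and `pas` are the unit's boundary coordinates in
#' genomic orientation (for a minus-strand TU, `tss > pas`).
#'
#' @param id Gene/TU identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param tss Transcription start coordinate (0-based).
#' @param pas Polyadenylation site coordinate (0-based).
#' @param exons Optional data.frame with columns `start`, `end`
#'   (0-based half-open genomic intervals).
#' @return An object of class `transcription_unit`.
#' @export
transcription_unit <- function(id, chrom, strand, tss, pas,
                               exons = data.frame(start = integer(),
                                                  end = integer())) {
  stopifnot(strand %in% c("+", "-"))
  sgn <- if (strand == "+") 1 else -1
  if ((pas - tss) * sgn <= 0)
    stop("PAS must lie downstream of TSS in transcription orientation")
  structure(list(id = id, chrom = chrom, strand = strand,
                 tss = tss, pas = pas,
                 exons = exons,
                 length_nt = abs(pas - tss)),
            class = "transcription_unit")
}

#' @export
print.transcription_unit <- function(x, ...) {
  cat(sprintf("<transcription_unit> %s %s:%d-%d (%s), %d nt, %d exon(s)\n",
              x$id, x$chrom, min(x$tss, x$pas), max(x$tss, x$pas),
              x$strand, x$length_nt, nrow(x$exons)))
  invisible(x)
}

#' Tile a transcription unit with analysis windows
#'
#' Builds non-overlapping windows in transcription orientation. For
#' `kind = "body"` windows tile TSS to PAS (window 1 starts at the TSS;
#' a partial terminal window is dropped). For `kind = "pas"` the grid
#' spans `upstream_nt` before to `downstream_nt` after the PAS (defaults
#' 5 kb / 25 kb at 250 nt, i.e. 20 upstream + 100 downstream windows).
#'
#' @param tu A [transcription_unit()].
#' @param kind `"body"`, `"pas"` or `"custom"`.
#' @param width_nt Window width in nt (default 1000 for body, 250 for pas).
#' @param upstream_nt,downstream_nt Span of the PAS grid.
#' @param start_nt,end_nt For `kind = "custom"`: span in transcription
#'   coordinates relative to the TSS.
#' @return A data.frame with columns `index`, `start`, `end` (0-based
#'   half-open genomic), and `rel` (transcription-oriented offset of the
#'   window start, in nt; for the PAS grid, relative to the PAS).
#' @export
make_windows <- function(tu, kind = c("body", "pas", "custom"),
                         width_nt = NULL,
                         upstream_nt = 5000, downstream_nt = 25000,
                         start_nt = NULL, end_nt = NULL) {
  kind <- match.arg(kind)
  if (is.null(width_nt)) width_nt <- switch(kind, body = 1000L, pas = 250L,
                                            custom = 1000L)
  sgn <- if (tu$strand == "+") 1L else -1L
  if (kind == "body") {
    span <- tu$length_nt
    n <- span %/% width_nt
    if (n == 0) {
      warning("TU ", tu$id, " shorter than one window")
      return(data.frame(index = integer(), start = integer(),
                        end = integer(), rel = integer()))
    }
    rel <- (seq_len(n) - 1L) * width_nt
  } else if (kind == "pas") {
    n_up <- upstream_nt %/% width_nt
    n_down <- downstream_nt %/% width_nt
    rel <- ((-n_up):(n_down - 1L)) * width_nt
    n <- length(rel)
  } else {
    stopifnot(!is.null(start_nt), !is.null(end_nt))
    n <- (end_nt - start_nt) %/% width_nt
    rel <- start_nt + (seq_len(n) - 1L) * width_nt
  }
  anchor <- if (kind == "pas") tu$pas else tu$tss
  g1 <- anchor + sgn * rel
  g2 <- anchor + sgn * (rel + width_nt)
  data.frame(index = seq_len(n),
             start = pmin(g1, g2),
             end = pmax(g1, g2),
             rel = rel)
}

#' Count strand-aware coverage into windows
#'
#' Sums `value * overlap_length` of bedGraph-style coverage intervals into
#' each window (uniform coverage 1.0 yields `width_nt` per window). When a
#' strand-keyed coverage list is supplied, the TU's own strand (4sU-like)
#' or both strands (occupancy-like) are used. Windows overlapping an exon
#' of the TU are flagged missing. An optional input track is subtracted
#' (background correction); negative values are retained.
#'
#' @param coverage A data.frame with columns `chrom`, `start`, `end`,
#'   `value` (0-based half-open, sorted, non-overlapping), or a list with
#'   elements `"+"` and `"-"` of such data.frames.
#' @param tu A [transcription_unit()].
#' @param windows Output of [make_windows()].
#' @param same_strand_only If `TRUE` and `coverage` is strand-keyed, only
#'   the TU's strand is counted.
#' @param input Optional coverage to subtract (same format).
#' @param mask_exons Flag exon-overlapping windows as missing (default TRUE).
#' @return A `window_vector`: data.frame with columns `index`, `rel`,
#'   `count`, `missing`, plus attributes `gene`, `kind`, `width_nt`.
#' @export
count_coverage <- function(coverage, tu, windows, same_strand_only = TRUE,
                           input = NULL, mask_exons = TRUE) {
  if (nrow(windows) == 0) {
    return(window_vector(tu$id, "custom", 0L, numeric(), logical(),
                         integer()))
  }
  counts <- coverage_sums(coverage, tu, windows, same_strand_only)
  missing <- rep(FALSE, nrow(windows))
  if (is.null(counts)) {
    warning("chromosome ", tu$chrom, " absent from coverage for TU ", tu$id)
    counts <- rep(NA_real_, nrow(windows))
    missing <- rep(TRUE, nrow(windows))
  }
  if (!is.null(input)) {
    bg <- coverage_sums(input, tu, windows, same_strand_only)
    if (!is.null(bg)) counts <- counts - bg
  }
  if (mask_exons && nrow(tu$exons) > 0) {
    win_gr <- GenomicRanges::GRanges(tu$chrom,
      IRanges::IRanges(windows$start + 1L, windows$end))
    ex_gr <- GenomicRanges::GRanges(tu$chrom,
      IRanges::IRanges(tu$exons$start + 1L, tu$exons$end))
    hit <- IRanges::overlapsAny(win_gr, ex_gr)
    missing <- missing | hit
  }
  width <- windows$end[1] - windows$start[1]
  kind <- if (!is.null(attr(windows, "kind"))) attr(windows, "kind") else
    if (any(windows$rel < 0)) "pas" else "body"
  window_vector(tu$id, kind, width, counts, missing, windows$rel)
}

# sum value * overlap over windows for one coverage track (possibly
# strand-keyed); NULL if the chromosome is absent
coverage_sums <- function(coverage, tu, windows, same_strand_only) {
  tracks <- if (is.data.frame(coverage)) list(coverage)
            else if (same_strand_only) coverage[tu$strand]
            else coverage
  total <- numeric(nrow(windows))
  seen <- FALSE
  win_gr <- GenomicRanges::GRanges(tu$chrom,
    IRanges::IRanges(windows$start + 1L, windows$end))
  for (tr in tracks) {
    if (is.null(tr) || nrow(tr) == 0) next
    tr <- tr[tr$chrom == tu$chrom, , drop = FALSE]
    if (nrow(tr) == 0) next
    seen <- TRUE
    cov_gr <- GenomicRanges::GRanges(tu$chrom,
      IRanges::IRanges(tr$start + 1L, tr$end))
    ov <- GenomicRanges::findOverlaps(win_gr, cov_gr)
    if (length(ov) == 0) next
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    olap <- pmin(windows$end[qi], tr$end[si]) -
            pmax(windows$start[qi], tr$start[si])
    contrib <- tr$value[si] * olap
    total <- total + as.numeric(tapply(contrib, factor(qi,
      levels = seq_len(nrow(windows))), sum, default = 0))
  }
  if (!seen) NULL else total
}

#' Construct a window count vector
#'
#' The universal regression input: per-gene, per-window normalized counts
#' with a missing-value mask.
#'
#' @param gene Gene id.
#' @param kind `"body"`, `"pas"` or `"custom"`.
#' @param width_nt Window width in nt.
#' @param counts Numeric vector (>= 0 where not missing, unless
#'   input-corrected).
#' @param missing Logical mask, same length.
#' @param rel Transcription-oriented window offsets (nt).
#' @return A data.frame of class `window_vector`.
#' @export
window_vector <- function(gene, kind, width_nt, counts,
                          missing = rep(FALSE, length(counts)),
                          rel = (seq_along(counts) - 1L) * width_nt) {
  stopifnot(length(counts) == length(missing))
  structure(data.frame(index = seq_along(counts), rel = rel,
                       count = counts, missing = missing),
            gene = gene, kind = kind, width_nt = width_nt,
            class = c("window_vector", "data.frame"))
}

#' Apply the termination-zone missing-data rules
#'
#' On a PAS-centered grid, in addition to the exon mask: (1) if the TU is
#' shorter than the upstream span (5 kb), all windows upstream of its TSS
#' are flagged; (2) if another TU on the same strand starts within the
#' downstream span, all windows downstream of that TSS are flagged.
#'
#' @param tu A [transcription_unit()].
#' @param neighbors List of [transcription_unit()]s (the TU catalogue; the
#'   TU itself is ignored).
#' @param wv A PAS-grid `window_vector` (column `rel` relative to the PAS).
#' @return The `window_vector` with an updated `missing` mask.
#' @export
flag_termination_missing <- function(tu, neighbors, wv) {
  stopifnot(inherits(wv, "window_vector"))
  # short TU: windows upstream of the TU itself (rel < -length)
  if (tu$length_nt < -min(wv$rel)) {
    wv$missing[wv$rel < -tu$length_nt] <- TRUE
  }
  sgn <- if (tu$strand == "+") 1 else -1
  for (nb in neighbors) {
    if (identical(nb$id, tu$id)) next
    if (nb$chrom != tu$chrom || nb$strand != tu$strand) next
    rel_tss <- (nb$tss - tu$pas) * sgn  # nt downstream of this PAS
    if (rel_tss > 0 && rel_tss <= max(wv$rel + attr(wv, "width_nt"))) {
      wv$missing[wv$rel >= rel_tss] <- TRUE
    }
  }
  wv
}

#' Spike-in size factors
#'
#' Divides each sample's spike-in read total by the median across samples;
#' normalized counts are raw counts divided by the factor.
#'
#' @param totals Named numeric vector of spike-in read totals (> 0).
#' @return Named numeric vector of per-sample divisors.
#' @examples
#' spike_size_factors(c(a = 10, b = 20, c = 40))
#' @export
spike_size_factors <- function(totals) {
  if (any(!is.finite(totals)) || any(totals <= 0))
    stop("all spike-in totals must be positive")
  totals / stats::median(totals)
}

#' Read a 4-column bedGraph file
#'
#' @param path File path.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score)
}

#' Write a bedGraph file
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(df, path) {
  gr <- GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$start + 1L, df$end), score = df$value)
  rtracklayer::export(gr, path, format = "bedGraph")
}

#' Write window vectors to a TSV table
#'
#' Long format with columns `gene`, `kind`, `width_nt`, `index`, `rel`,
#' `count`, `missing`; the inverse of [read_window_tsv()].
#'
#' @param wvs A `window_vector` or list of them.
#' @param path Output path.
#' @export
write_window_tsv <- function(wvs, path) {
  if (inherits(wvs, "window_vector")) wvs <- list(wvs)
  rows <- lapply(wvs, function(wv) {
    data.frame(gene = attr(wv, "gene"), kind = attr(wv, "kind"),
               width_nt = attr(wv, "width_nt"),
               index = wv$index, rel = wv$rel, count = wv$count,
               missing = wv$missing)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Read window vectors from a TSV table
#'
#' @param path Path written by [write_window_tsv()].
#' @return Named list of `window_vector`s.
#' @export
read_window_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, df$gene), function(d) {
    window_vector(d$gene[1], d$kind[1], d$width_nt[1], d$count,
                  as.logical(d$missing), d$rel)
  })
  out[unique(df$gene)]
}

#' Round normalized counts for integer-support likelihoods
#'
#' Negative-binomial (and, by the same policy, fold-change) likelihoods
#' have integer count arguments; normalized real-valued counts are rounded
#' half-to-even and negative (input-corrected) values censored at 0.
#'
#' @param x Numeric vector.
#' @return Non-negative integer-valued numeric vector.
#' @export
censor_counts <- function(x) {
  pmax(0, round(x))
}
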