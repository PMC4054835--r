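# Sequence-level QC: whole-transcript-amplification adaptor contamination
# scanning (ungapped identity at every offset, both strands, end overhangs
# allowed), GC/length profiling of detected vs undetected isoforms, and
# transcript coverage breadth.

#' Fraction of G/C bases in a sequence
#' @param seq Nucleotide string.
#' @return GC fraction in \[0, 1\].
#' @export
gc_content <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  sum(b %in% c("G", "C")) / length(b)
}

# does the adaptor match the read at any ungapped offset (including end
# overhangs of >= min_overlap) with identity >= min_identity?
scan_one <- function(read_int, ad_int, min_identity, min_overlap) {
  rl <- length(read_int); al <- length(ad_int)
  # offset of adaptor start relative to read start, allowing overhangs
  for (off in seq(-(al - min_overlap), rl - min_overlap)) {
    r_from <- max(1L, off + 1L)
    r_to <- min(rl, off + al)
    ov <- r_to - r_from + 1L
    if (ov < min_overlap) next
    a_from <- r_from - off
    matches <- sum(read_int[r_from:r_to] == ad_int[a_from:(a_from + ov - 1L)])
    if (matches / ov >= min_identity) return(TRUE)
  }
  FALSE
}

#' Scan reads for adaptor contamination
#'
#' A read is a hit when any ungapped alignment of the adaptor or its reverse
#' complement against the read — at any offset, including end overhangs of at
#' least `min_overlap` bases — reaches identity `>= min_identity` over the
#' overlapping region. `N` bases count as mismatches. The scan is streaming
#' and order-independent.
#'
#' @param reads A `ReadSet` data.frame (from [read_fastq()] or
#'   [simulate_reads()]).
#' @param adaptor Adaptor sequence; length must be >= `min_overlap`.
#' @param min_identity Identity threshold over the overlap (default 0.8).
#' @param min_overlap Minimum overlap length in bases (default 16).
#' @param both_strands Also scan the reverse complement (default TRUE).
#' @return List of class `AdaptorScanResult`: `n_reads`, `n_hits`,
#'   `fraction_hits`, `parameters`.
#' @export
adaptor_scan <- function(reads, adaptor = SUPPRESSION_PRIMER,
                         min_identity = 0.8, min_overlap = 16L,
                         both_strands = TRUE) {
  adaptor <- toupper(adaptor)
  if (grepl("[^ACGTUMRWSYKVHDBN]", adaptor))
    stop("adaptor contains non-IUPAC characters")
  if (nchar(adaptor) < min_overlap)
    stop("adaptor shorter than min_overlap")
  ad_f <- utf8ToInt(adaptor)
  ad_r <- utf8ToInt(reverse_complement(adaptor))
  n_hits <- 0L
  for (b in reads$bases) {
    ri <- utf8ToInt(toupper(b))
    # N never matches anything (0 cannot equal an A/C/G/T code)
    ri[ri == utf8ToInt("N")] <- 0L
    hit <- scan_one(ri, ad_f, min_identity, min_overlap) ||
      (both_strands && scan_one(ri, ad_r, min_identity, min_overlap))
    if (hit) n_hits <- n_hits + 1L
  }
  n <- nrow(reads)
  structure(list(n_reads = n, n_hits = n_hits,
                 fraction_hits = if (n == 0) 0 else n_hits / n,
                 parameters = list(adaptor = adaptor,
                                   min_identity = min_identity,
                                   min_overlap = min_overlap,
                                   strands = if (both_strands) "both" else "forward")),
            class = "AdaptorScanResult")
}

#' @export
print.AdaptorScanResult <- function(x, ...) {
  cat(sprintf("AdaptorScanResult: %d/%d reads (%.2f%%)\n",
              x$n_hits, x$n_reads, 100 * x$fraction_hits))
  invisible(x)
}

#' GC/length profile of detected vs undetected isoforms
#'
#' Partitions isoforms by a detection flag and summarizes mean GC content and
#' mean transcript length per group, with Wilcoxon rank-sum p-values for the
#' between-group location shift. Amplification bias shows up as undetected
#' isoforms being GC-richer and/or shorter.
#'
#' @param gene_meta data.frame with `transcript_length` (>= 1) and
#'   `gc_fraction` (in \[0, 1\]) per isoform.
#' @param detected_flags Logical vector, one per isoform (e.g. expression
#'   above threshold in >= 1 sample).
#' @return List with per-group summaries (`detected`, `undetected`: `n`,
#'   `mean_gc`, `mean_length`; NULL for an empty group) and `p_gc`,
#'   `p_length` (NA when a group is empty).
#' @export
gc_length_profile <- function(gene_meta, detected_flags) {
  if (nrow(gene_meta) != length(detected_flags))
    stop("flags must match gene_meta rows")
  if (any(gene_meta$transcript_length < 1)) stop("transcript_length must be >= 1")
  if (any(gene_meta$gc_fraction < 0 | gene_meta$gc_fraction > 1))
    stop("gc_fraction must lie in [0, 1]")
  summarize <- function(idx) {
    if (!any(idx)) return(NULL)
    list(n = sum(idx),
         mean_gc = mean(gene_meta$gc_fraction[idx]),
         mean_length = mean(gene_meta$transcript_length[idx]))
  }
  det <- summarize(detected_flags)
  und <- summarize(!detected_flags)
  p_gc <- p_len <- NA_real_
  if (!is.null(det) && !is.null(und)) {
    p_gc <- suppressWarnings(stats::wilcox.test(
      gene_meta$gc_fraction[detected_flags],
      gene_meta$gc_fraction[!detected_flags])$p.value)
    p_len <- suppressWarnings(stats::wilcox.test(
      gene_meta$transcript_length[detected_flags],
      gene_meta$transcript_length[!detected_flags])$p.value)
  }
  list(detected = det, undetected = und, p_gc = p_gc, p_length = p_len)
}

#' Detection flags from an expression matrix
#'
#' Default detection rule for [gc_length_profile()]: expression strictly
#' above `min_expr` in at least `min_samples` samples.
#' @param mat An [expression_matrix()].
#' @param min_expr Threshold (default 1).
#' @param min_samples Minimum samples above threshold (default 1).
#' @return Logical vector per gene.
#' @export
detection_flags <- function(mat, min_expr = 1, min_samples = 1L) {
  rowSums(mat$values > min_expr) >= min_samples
}

#' Transcript coverage breadth
#'
#' Breadth = fraction of a transcript's bases covered by at least one read;
#' the summary is the median breadth over transcripts whose expression is at
#' least `min_expr` (inclusive).
#'
#' @param coverage_table data.frame with `transcript_id`, `length`,
#'   `covered_bases` (0 <= covered <= length).
#' @param expression Per-transcript expression values aligned with the table.
#' @param min_expr Expression threshold for the "expressed" set (default 10).
#' @return List with `breadth` (per transcript) and `median_breadth` (NA with
#'   a warning when no transcript passes the threshold).
#' @export
coverage_breadth <- function(coverage_table, expression, min_expr = 10) {
  if (any(coverage_table$covered_bases > coverage_table$length))
    stop("covered_bases exceeds transcript length")
  if (any(coverage_table$covered_bases < 0)) stop("covered_bases must be >= 0")
  breadth <- coverage_table$covered_bases / coverage_table$length
  names(breadth) <- coverage_table$transcript_id
  expressed <- expression >= min_expr
  med <- if (!any(expressed)) {
    warning("no transcript passes the expression threshold")
    NA_real_
  } else stats::median(breadth[expressed])
  list(breadth = breadth, median_breadth = med, min_expr = min_expr)
}
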