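# Read counting over miRNA loci, RPM normalization, expression filter.

#' Count perfectly aligned reads over miRNA loci for one sample
#'
#' A read is assigned to a locus iff it is mapped, has edit distance 0
#' ("perfectly aligned"), lies on the same strand, and its interval is fully
#' contained in the locus interval. A read contained in more than one locus
#' contributes one count to each; the number of such ambiguous reads is
#' reported via a message.
#'
#' @param alignments Data frame of alignment records from one sample, as
#'   returned by [read_sam_minimal()].
#' @param loci Data frame of miRNA loci, as returned by [read_bed()].
#' @param sample_id Column name for the resulting one-column count table.
#' @return Integer matrix with one column (`sample_id`) and one row per
#'   locus. Attributes `n_assigned`, `n_ambiguous` and `n_unassigned` record
#'   the bookkeeping over mapped perfect reads.
#' @export
assign_reads <- function(alignments, loci, sample_id = "sample") {
  if (anyDuplicated(loci$mirna_id))
    stop_mc("assign_reads: duplicate locus ids")
  if (nrow(loci) > 0 && any(loci$start >= loci$end))
    stop_mc("assign_reads: loci must satisfy start < end")
  counts <- matrix(0L, nrow = nrow(loci), ncol = 1L,
                   dimnames = list(loci$mirna_id, sample_id))
  eligible <- alignments[alignments$mapped & alignments$edit_distance == 0L, ,
                         drop = FALSE]
  if (nrow(eligible) == 0L || nrow(loci) == 0L) {
    attr(counts, "n_assigned") <- 0L
    attr(counts, "n_ambiguous") <- 0L
    attr(counts, "n_unassigned") <- nrow(eligible)
    return(counts)
  }
  reads_gr <- GenomicRanges::GRanges(
    seqnames = eligible$chrom,
    ranges = IRanges::IRanges(start = eligible$start + 1L, end = eligible$end),
    strand = eligible$strand)
  loci_gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand)
  hits <- GenomicRanges::findOverlaps(reads_gr, loci_gr, type = "within",
                                      ignore.strand = FALSE)
  hit_tab <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(loci))
  counts[, 1L] <- as.integer(hit_tab)
  per_read <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(eligible))
  n_ambiguous <- sum(per_read > 1L)
  n_unassigned <- sum(per_read == 0L)
  if (n_ambiguous > 0L)
    mc_msg(sprintf("assign_reads: %d read(s) contained in multiple loci (counted once per locus)",
                   n_ambiguous))
  attr(counts, "n_assigned") <- sum(per_read > 0L)
  attr(counts, "n_ambiguous") <- n_ambiguous
  attr(counts, "n_unassigned") <- n_unassigned
  counts
}

#' Reads-per-million normalization
#'
#' Scales each sample column so the assigned reads of that sample sum to one
#' million: `rpm[i, s] = counts[i, s] / sum(counts[, s]) * 1e6`. The
#' denominator is by default the reads assigned to miRNA loci in that sample;
#' an externally provided per-sample total (e.g. all aligned reads) can be
#' supplied instead. A sample with zero total yields an all-zero column and a
#' warning.
#'
#' @param counts Count matrix (miRNAs x samples).
#' @param totals Optional named numeric vector of per-sample denominators;
#'   default uses each column sum.
#' @return Numeric matrix of RPM values with the same dimnames.
#' @export
rpm_normalize <- function(counts, totals = NULL) {
  check_table_matrix(counts, what = "counts", integral = TRUE)
  if (is.null(totals)) {
    totals <- colSums(counts)
  } else {
    if (is.null(names(totals)) || !all(colnames(counts) %in% names(totals)))
      stop_mc("rpm_normalize: 'totals' must be named for every sample")
    totals <- totals[colnames(counts)]
  }
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("rpm_normalize: sample(s) with zero total reads: %s",
                    paste(colnames(counts)[zero], collapse = ", ")))
    totals[zero] <- 1  # avoids 0/0; columns are all zero anyway
  }
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Mean-RPM expression filter
#'
#' Keeps a miRNA iff its mean RPM across all samples of the dataset (cases
#' and controls pooled) is strictly greater than the threshold.
#'
#' @param rpm RPM matrix (miRNAs x samples).
#' @param threshold Strict lower bound on the mean RPM (default 5).
#' @return Character vector of retained miRNA ids.
#' @export
mean_rpm_filter <- function(rpm, threshold = 5) {
  check_table_matrix(rpm, what = "rpm")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop_mc("mean_rpm_filter: threshold must be a single value >= 0")
  rownames(rpm)[rowMeans(rpm) > threshold]
}
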