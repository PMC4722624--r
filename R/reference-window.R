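#' Amplicon reference window
#'
#' A `reference_window` describes the amplified region of interest (ROI) of a
#' deep-sequencing amplicon together with its genomic coordinates and optional
#' flanking sequence. Flanks serve two purposes: they supply primer-binding
#' sequence when simulating primer-containing amplicon templates, and they
#' resolve duplicated segments whose 3' end extends past the ROI.
#'
#' All user-facing coordinates are 1-based inclusive, matching the usual
#' genomic interval notation (`chrom:start-end`). The canonical clinical
#' target is the FLT3 exon 13-15 amplicon chr13:28,608,112-28,608,312
#' (GRCh37), a 201 bp ROI with both primer binding sites excluded.
#'
#' @param chrom Chromosome / sequence name.
#' @param roi_start,roi_end 1-based inclusive genomic coordinates of the ROI.
#' @param roi_seq Nucleotide sequence of the ROI; its length must equal
#'   `roi_end - roi_start + 1`.
#' @param left_flank,right_flank Nucleotide sequence immediately up-/downstream
#'   of the ROI (may be empty strings).
#'
#' @return An object of class `reference_window`.
#' @examples
#' w <- reference_window("chr13", 28608112, 28608312, paste0(strrep("ACGT", 50), "A"))
#' roi_length(w)
#' @export
reference_window <- function(chrom, roi_start, roi_end, roi_seq,
                             left_flank = "", right_flank = "") {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  roi_start <- as.integer(roi_start)
  roi_end <- as.integer(roi_end)
  if (is.na(roi_start) || is.na(roi_end) || roi_start < 1L || roi_end < roi_start)
    stop("invalid ROI coordinates: start=", roi_start, " end=", roi_end)
  roi_seq <- toupper(roi_seq)
  left_flank <- toupper(left_flank)
  right_flank <- toupper(right_flank)
  for (s in c(roi_seq, left_flank, right_flank))
    if (grepl("[^ACGTN]", s)) stop("sequence contains characters outside ACGTN")
  if (nchar(roi_seq) != roi_end - roi_start + 1L)
    stop("roi_seq length (", nchar(roi_seq), ") does not match coordinates (",
         roi_end - roi_start + 1L, " bp)")
  structure(
    list(chrom = chrom, roi_start = roi_start, roi_end = roi_end,
         roi_seq = roi_seq, left_flank = left_flank, right_flank = right_flank),
    class = "reference_window")
}

#' @export
print.reference_window <- function(x, ...) {
  cat(sprintf("reference_window: %s:%d-%d (%d bp ROI; flanks %d/%d bp)\n",
              x$chrom, x$roi_start, x$roi_end, roi_length(x),
              nchar(x$left_flank), nchar(x$right_flank)))
  invisible(x)
}

#' ROI length of a reference window
#' @param window A [reference_window()].
#' @return Integer ROI length in bp.
#' @export
roi_length <- function(window) {
  stopifnot(inherits(window, "reference_window"))
  window$roi_end - window$roi_start + 1L
}

#' Parse a genomic region string
#'
#' Accepts `"chrom:start-end"` with optional thousands separators
#' (`"chr13:28,608,112-28,608,312"`).
#'
#' @param region Region string.
#' @return A list with elements `chrom`, `start`, `end`.
#' @export
parse_region <- function(region) {
  stopifnot(is.character(region), length(region) == 1L)
  cleaned <- gsub(",", "", region, fixed = TRUE)
  m <- regmatches(cleaned, regexec("^(.+):([0-9]+)-([0-9]+)$", cleaned))[[1]]
  if (length(m) != 4L)
    stop("malformed region string: '", region, "' (expected chrom:start-end)")
  out <- list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  if (out$start < 1L || out$end < out$start)
    stop("malformed region string: '", region, "' (start/end out of order)")
  out
}

#' Load a reference window from a FASTA file
#'
#' Extracts the ROI named by `region` from a (multi-record) FASTA file,
#' together with up to `flank` bp of sequence on each side. Flanks are
#' truncated at the sequence ends rather than raising an error.
#'
#' @param fasta Path to a FASTA file.
#' @param region Region string, e.g. `"chr13:28,608,112-28,608,312"`.
#' @param flank Non-negative number of flanking bases to retain per side.
#' @return A [reference_window()].
#' @examples
#' fa <- system.file("extdata", "synthetic_flt3_amplicon.fa", package = "itdscan")
#' load_reference_window(fa, "FLT3amp_synthetic:301-501", flank = 300)
#' @export
load_reference_window <- function(fasta, region, flank = 0L) {
  flank <- as.integer(flank)
  stopifnot(length(flank) == 1L, !is.na(flank), flank >= 0L)
  reg <- parse_region(region)
  seqs <- Biostrings::readDNAStringSet(fasta)
  ## FASTA headers may carry descriptions after the first whitespace
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!reg$chrom %in% names(seqs))
    stop("sequence '", reg$chrom, "' not found in ", fasta)
  chromseq <- seqs[[reg$chrom]]
  if (reg$end > length(chromseq))
    stop("region ", region, " extends past end of sequence (",
         length(chromseq), " bp)")
  lf_start <- max(1L, reg$start - flank)
  rf_end <- min(length(chromseq), reg$end + flank)
  reference_window(
    chrom = reg$chrom, roi_start = reg$start, roi_end = reg$end,
    roi_seq = as.character(Biostrings::subseq(chromseq, reg$start, reg$end)),
    left_flank = if (reg$start > 1L)
      as.character(Biostrings::subseq(chromseq, lf_start, reg$start - 1L)) else "",
    right_flank = if (reg$end < length(chromseq))
      as.character(Biostrings::subseq(chromseq, reg$end + 1L, rf_end)) else "")
}

#' Write a reference window back to FASTA
#'
#' Writes the stored sequence (flanks + ROI) as a single FASTA record named
#' after the window's chromosome. Loading and re-writing preserves the
#' sequence bytes up to case normalisation.
#'
#' @param window A [reference_window()].
#' @param path Output FASTA path.
#' @param flanks Include the stored flanking sequence (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_window_fasta <- function(window, path, flanks = TRUE) {
  stopifnot(inherits(window, "reference_window"))
  seq <- if (flanks)
    paste0(window$left_flank, window$roi_seq, window$right_flank)
  else window$roi_seq
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- window$chrom
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Convert between ROI-relative and genomic coordinates
#'
#' `roi_to_genomic()` maps a 1-based position within the ROI to its genomic
#' coordinate; `genomic_to_roi()` is its inverse. The two compose to the
#' identity on `1..roi_length(window)`.
#'
#' @param window A [reference_window()].
#' @param roi_pos Position(s) within the ROI, 1-based.
#' @param genomic_pos Genomic position(s) within the ROI.
#' @return Integer vector of converted positions.
#' @examples
#' w <- reference_window("chr13", 28608112, 28608312, strrep("A", 201))
#' roi_to_genomic(w, 201)  # 28608312
#' @export
roi_to_genomic <- function(window, roi_pos) {
  stopifnot(inherits(window, "reference_window"))
  roi_pos <- as.integer(roi_pos)
  if (any(is.na(roi_pos)) || any(roi_pos < 1L) || any(roi_pos > roi_length(window)))
    stop("roi_pos out of range 1..", roi_length(window))
  window$roi_start + roi_pos - 1L
}

#' @rdname roi_to_genomic
#' @export
genomic_to_roi <- function(window, genomic_pos) {
  stopifnot(inherits(window, "reference_window"))
  genomic_pos <- as.integer(genomic_pos)
  if (any(is.na(genomic_pos)) || any(genomic_pos < window$roi_start) ||
      any(genomic_pos > window$roi_end))
    stop("genomic_pos outside ROI ", window$roi_start, "..", window$roi_end)
  genomic_pos - window$roi_start + 1L
}

## ROI sequence extended by the right flank; used when a duplicated segment
## runs past the ROI end. Positions are ROI-relative (1 = roi_start).
extended_roi_seq <- function(window) {
  paste0(window$roi_seq, window$right_flank)
}

#' Generate a synthetic amplicon reference
#'
#' Builds a deterministic, repeat-free random reference for testing and
#' simulation: a central ROI with flanking sequence on both sides, rejected
#' and re-drawn until no 15-mer occurs twice (so that a seed-and-extend
#' aligner cannot be confused by spurious repeats). This is a stand-in
#' sequence for workflows where the human reference is not available; it is
#' synthetic and carries no biological meaning.
#'
#' @param roi_len ROI length in bp (default 201, the clinical FLT3 amplicon
#'   ROI length).
#' @param flank Flank length per side in bp.
#' @param seed Integer seed for the deterministic draw.
#' @param chrom Sequence name.
#' @return A [reference_window()] whose flanks both have length `flank`.
#' @export
synthetic_reference_window <- function(roi_len = 201L, flank = 300L,
                                       seed = 20160122L,
                                       chrom = "FLT3amp_synthetic") {
  total <- 2L * flank + roi_len
  seq <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    k <- 15L
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE), collapse = "")
      kmers <- substring(s, seq_len(total - k + 1L), k:total)
      if (!anyDuplicated(kmers)) break
    }
    s
  })
  reference_window(
    chrom = chrom, roi_start = flank + 1L, roi_end = flank + roi_len,
    roi_seq = substr(seq, flank + 1L, flank + roi_len),
    left_flank = substr(seq, 1L, flank),
    right_flank = substr(seq, flank + roi_len + 1L, total))
}
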