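#' Specification of one simulated ITD allele
#'
#' Describes a single internal-tandem-duplication allele over a reference
#' window together with the library parameters used to simulate reads from
#' it. The duplicated segment is the `length` bases starting at ROI position
#' `start`; its tandem copy sits immediately downstream.
#'
#' Reads are simulated from the primer-defined mutant amplicon, i.e. the
#' template carries `primer_5p` bases of upstream flank and `primer_3p`
#' bases of downstream flank around the rearranged ROI (see the methods
#' vignette for how these defaults were derived from the assay's amplicon
#' architecture). Setting both to 0 gives ROI-only templates.
#'
#' @param start 1-based ROI position of the first base of the duplicated
#'   segment.
#' @param length Duplication length in bp.
#' @param burden Allelic burden (fraction of templates carrying the ITD) in
#'   `[0, 1]`; the study default is 0.5.
#' @param n_pairs Total read pairs to simulate (ITD + wild type); the study
#'   default is 2000 (sequencing depth 2000x).
#' @param read_length Read length per mate in bp (default 275; 2 x 275 bp
#'   chemistry).
#' @param base_quality Uniform Phred base quality for all simulated bases
#'   (default 30). Detection ignores base qualities.
#' @param primer_5p,primer_3p Primer flank lengths (bp) prepended/appended to
#'   the template from the window flanks (defaults 15 and 26).
#' @return An object of class `itd_spec`.
#' @examples
#' itd_spec(start = 101, length = 30)
#' @export
itd_spec <- function(start, length, burden = 0.5, n_pairs = 2000L,
                     read_length = 275L, base_quality = 30L,
                     primer_5p = 15L, primer_3p = 26L) {
  start <- as.integer(start); length <- as.integer(length)
  n_pairs <- as.integer(n_pairs); read_length <- as.integer(read_length)
  stopifnot(length(start) == 1L, length(length) == 1L, !is.na(start), !is.na(length))
  if (start < 1L) stop("start must be >= 1")
  if (length < 1L) stop("length must be >= 1")
  if (!is.numeric(burden) || is.na(burden) || burden < 0 || burden > 1)
    stop("burden must be a fraction in [0, 1]")
  if (is.na(n_pairs) || n_pairs < 1L) stop("n_pairs must be a positive integer")
  if (is.na(read_length) || read_length < 1L) stop("read_length must be positive")
  structure(
    list(start = start, length = length, burden = burden, n_pairs = n_pairs,
         read_length = read_length, base_quality = as.integer(base_quality),
         primer_5p = as.integer(primer_5p), primer_3p = as.integer(primer_3p)),
    class = "itd_spec")
}

#' @export
print.itd_spec <- function(x, ...) {
  cat(sprintf("itd_spec: start=%d length=%d burden=%.3g n_pairs=%d (2 x %d bp)\n",
              x$start, x$length, x$burden, x$n_pairs, x$read_length))
  invisible(x)
}

#' Construct an ITD allele sequence
#'
#' Returns the ROI sequence rearranged by a tandem duplication of the
#' `length` bases starting at ROI position `start`. Because the amplicon is
#' primer-defined, the mutant amplicon ROI runs from the amplicon start
#' through the end of the duplicated segment (which may extend into the
#' downstream flank) and then from the segment start through the ROI end:
#' `ref[1 .. start+length-1] + ref[start .. roi_len]` in ROI coordinates,
#' with positions beyond the ROI end resolved from the right flank. The
#' result always has length `roi_length(window) + length`, and the duplicated
#' segment occurs twice in tandem around the junction.
#'
#' @param window A [reference_window()]; its right flank must cover
#'   `start + length - 1 - roi_length(window)` bases when the segment
#'   extends past the ROI end.
#' @param start 1-based ROI position of the first duplicated base.
#' @param length Duplication length in bp.
#' @return The mutant ROI sequence (character scalar).
#' @examples
#' w <- synthetic_reference_window()
#' allele <- build_itd_allele(w, start = 101, length = 30)
#' nchar(allele)  # 231
#' substr(allele, 101, 130) == substr(allele, 131, 160)
#' @export
build_itd_allele <- function(window, start, length) {
  stopifnot(inherits(window, "reference_window"))
  start <- as.integer(start); length <- as.integer(length)
  n <- roi_length(window)
  if (start < 1L || start > n) stop("start outside ROI (1..", n, ")")
  if (length < 1L) stop("length must be >= 1")
  ext <- extended_roi_seq(window)
  seg_end <- start + length - 1L
  if (seg_end > nchar(ext))
    stop("duplicated segment [", start, ", ", seg_end, "] extends ",
         seg_end - nchar(ext), " bp past the available right flank")
  segment <- substr(ext, start, seg_end)
  if (grepl("N", segment, fixed = TRUE))
    stop("duplicated segment contains N; refusing to build an ambiguous allele")
  paste0(substr(ext, 1L, seg_end), substr(ext, start, n))
}

revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

#' Simulate error-free read pairs from an amplicon template
#'
#' Implements the fixed-start amplicon model: mate 1 is the first
#' `min(read_length, nchar(template))` bases of the template; mate 2 is the
#' reverse complement of the last `min(read_length, nchar(template))` bases.
#' Reads carry no errors and all pairs from one template are identical, so
#' the simulation is fully deterministic.
#'
#' @param template Template (amplicon) sequence.
#' @param n_pairs Number of identical pairs to emit.
#' @param read_length Read length per mate in bp.
#' @param base_quality Uniform Phred quality applied to every base.
#' @return A list with elements `seq1`, `seq2` (mate sequences), `qual1`,
#'   `qual2` (quality strings) and `n_pairs`.
#' @export
simulate_read_pairs <- function(template, n_pairs, read_length = 275L,
                                base_quality = 30L) {
  stopifnot(is.character(template), length(template) == 1L, nzchar(template))
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs <= 0L) stop("n_pairs must be a positive integer")
  tlen <- nchar(template)
  rl <- min(as.integer(read_length), tlen)
  seq1 <- substr(template, 1L, rl)
  seq2 <- revcomp(substr(template, tlen - rl + 1L, tlen))
  q <- strrep(rawToChar(as.raw(33L + as.integer(base_quality))), rl)
  list(seq1 = seq1, seq2 = seq2, qual1 = q, qual2 = q, n_pairs = n_pairs)
}

## primer-containing amplicon template around a (possibly mutant) ROI sequence
amplicon_template <- function(window, roi_allele = NULL, primer_5p = 15L,
                              primer_3p = 26L) {
  stopifnot(inherits(window, "reference_window"))
  primer_5p <- as.integer(primer_5p); primer_3p <- as.integer(primer_3p)
  if (primer_5p > nchar(window$left_flank))
    stop("primer_5p (", primer_5p, ") exceeds left flank (",
         nchar(window$left_flank), " bp)")
  if (primer_3p > nchar(window$right_flank))
    stop("primer_3p (", primer_3p, ") exceeds right flank (",
         nchar(window$right_flank), " bp)")
  core <- if (is.null(roi_allele)) window$roi_seq else roi_allele
  lf <- if (primer_5p > 0L)
    substr(window$left_flank, nchar(window$left_flank) - primer_5p + 1L,
           nchar(window$left_flank)) else ""
  rf <- if (primer_3p > 0L) substr(window$right_flank, 1L, primer_3p) else ""
  paste0(lf, core, rf)
}

## number of ITD pairs for a given burden: round half up, floored at 1 when
## burden > 0 so the single-read clone scenario is constructible
n_itd_pairs <- function(n_pairs, burden) {
  if (burden <= 0) return(0L)
  max(1L, as.integer(floor(n_pairs * burden + 0.5)))
}

write_fastq <- function(names, seqs, quals, path, append = FALSE) {
  rec <- as.vector(rbind(paste0("@", names), seqs, "+", quals))
  con <- file(path, open = if (append) "ab" else "wb")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Simulate one (start, length) combination to FASTQ
#'
#' Simulates `round(n_pairs * burden)` ITD read pairs (at least 1 when
#' `burden > 0`) and the remaining wild-type pairs from the primer-defined
#' amplicon templates, writing a FASTQ pair, and returns the truth record for
#' downstream scoring. Read names encode the combination id, the allele of
#' origin and the pair index (`"<id>:itd:0001"`), so pooled multi-combination
#' runs can be demultiplexed by name after alignment. Everything is
#' deterministic: re-running produces byte-identical FASTQ.
#'
#' @param window A [reference_window()].
#' @param spec An [itd_spec()].
#' @param fastq1,fastq2 Output FASTQ paths for mate 1 / mate 2.
#' @param id Combination identifier used in read names; default
#'   `"c<start>_<length>"`.
#' @param append Append to existing FASTQ files instead of overwriting.
#' @return A one-row `data.frame` with columns `combination_id`, `start`,
#'   `length`, `burden`, `n_itd_pairs`, `n_wt_pairs`.
#' @examples
#' w <- synthetic_reference_window()
#' fq1 <- tempfile(fileext = "_1.fq"); fq2 <- tempfile(fileext = "_2.fq")
#' simulate_combination(w, itd_spec(101, 30, n_pairs = 10), fq1, fq2)
#' @export
simulate_combination <- function(window, spec, fastq1, fastq2,
                                 id = NULL, append = FALSE) {
  stopifnot(inherits(window, "reference_window"), inherits(spec, "itd_spec"))
  if (is.null(id)) id <- sprintf("c%d_%d", spec$start, spec$length)
  n_itd <- n_itd_pairs(spec$n_pairs, spec$burden)
  n_wt <- spec$n_pairs - n_itd

  chunks1 <- character(0); chunks2 <- character(0)
  nm <- character(0); q1 <- character(0); q2 <- character(0)
  if (n_itd > 0L) {
    allele <- build_itd_allele(window, spec$start, spec$length)
    tpl <- amplicon_template(window, allele, spec$primer_5p, spec$primer_3p)
    rp <- simulate_read_pairs(tpl, n_itd, spec$read_length, spec$base_quality)
    nm <- c(nm, sprintf("%s:itd:%04d", id, seq_len(n_itd)))
    chunks1 <- c(chunks1, rep(rp$seq1, n_itd)); q1 <- c(q1, rep(rp$qual1, n_itd))
    chunks2 <- c(chunks2, rep(rp$seq2, n_itd)); q2 <- c(q2, rep(rp$qual2, n_itd))
  }
  if (n_wt > 0L) {
    tpl <- amplicon_template(window, NULL, spec$primer_5p, spec$primer_3p)
    rp <- simulate_read_pairs(tpl, n_wt, spec$read_length, spec$base_quality)
    nm <- c(nm, sprintf("%s:wt:%04d", id, seq_len(n_wt)))
    chunks1 <- c(chunks1, rep(rp$seq1, n_wt)); q1 <- c(q1, rep(rp$qual1, n_wt))
    chunks2 <- c(chunks2, rep(rp$seq2, n_wt)); q2 <- c(q2, rep(rp$qual2, n_wt))
  }
  write_fastq(nm, chunks1, q1, fastq1, append = append)
  write_fastq(nm, chunks2, q2, fastq2, append = append)
  data.frame(combination_id = id, start = spec$start, length = spec$length,
             burden = spec$burden, n_itd_pairs = n_itd, n_wt_pairs = n_wt,
             stringsAsFactors = FALSE)
}

#' Enumerate the exhaustive (start, length) simulation grid
#'
#' Returns the full Cartesian product of duplication start positions
#' `1..roi_length(window)` and lengths `1..max_length`, row-major by start
#' then length, each with a unique combination id that reconstructs
#' (start, length) bijectively. For the 201 bp clinical amplicon with
#' `max_length = 201` this yields 40,401 combinations.
#'
#' @param window A [reference_window()].
#' @param max_length Largest duplication length to enumerate (default: the
#'   ROI length).
#' @param starts,lengths Optional integer vectors restricting the grid (used
#'   for sub-sampled runs); defaults cover the full ranges.
#' @return A `data.frame` with columns `combination_id`, `start`, `length`.
#' @examples
#' w <- synthetic_reference_window()
#' nrow(enumerate_grid(w))  # 40401
#' @export
enumerate_grid <- function(window, max_length = roi_length(window),
                           starts = NULL, lengths = NULL) {
  stopifnot(inherits(window, "reference_window"))
  max_length <- as.integer(max_length)
  if (is.na(max_length) || max_length < 1L) stop("max_length must be >= 1")
  if (is.null(starts)) starts <- seq_len(roi_length(window))
  if (is.null(lengths)) lengths <- seq_len(max_length)
  starts <- as.integer(starts); lengths <- as.integer(lengths)
  stopifnot(all(starts >= 1L), all(starts <= roi_length(window)),
            all(lengths >= 1L))
  g <- expand.grid(length = lengths, start = starts,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("start", "length")]
  data.frame(combination_id = sprintf("c%d_%d", g$start, g$length),
             start = g$start, length = g$length, stringsAsFactors = FALSE)
}
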