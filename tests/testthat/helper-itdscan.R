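## Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

test_window <- function() {
  if (is.null(.fixtures$window))
    .fixtures$window <- synthetic_reference_window()
  .fixtures$window
}

## reference FASTA (with flanks) for the aligner, indexed lazily
test_reference <- function() {
  if (is.null(.fixtures$reference)) {
    fa <- file.path(tempdir(), "itdscan_test_ref.fa")
    write_window_fasta(test_window(), fa)
    .fixtures$reference <- fa
  }
  .fixtures$reference
}

## simulate one combination, align it, return the BAM path
sim_align <- function(start, length, burden = 0.5, n_pairs = 200L, ...) {
  fq1 <- tempfile(fileext = "_1.fq")
  fq2 <- tempfile(fileext = "_2.fq")
  on.exit(unlink(c(fq1, fq2)))
  simulate_combination(test_window(),
                       itd_spec(start, length, burden = burden,
                                n_pairs = n_pairs, ...),
                       fq1, fq2)
  align_read_pairs(fq1, fq2, test_reference())
}

## minimal SAM file from a table of records
write_test_sam <- function(records, chrom = "ref", chrom_len = 1000L) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- vapply(records, function(r) {
    seq <- if (is.null(r$seq)) "*" else r$seq
    qual <- if (seq == "*") "*" else strrep("I", nchar(seq))
    line <- paste(r$qname, r$flag, chrom, r$pos, if (is.null(r$mapq)) 60 else r$mapq,
                  r$cigar, "*", 0, 0, seq, qual, sep = "\t")
    if (!is.null(r$sa)) line <- paste0(line, "\tSA:Z:", r$sa)
    line
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

## brute-force CIGAR walker: reference-consumed width and query interval
walk_cigar <- function(cigar) {
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1]]
  lens <- as.integer(sub("([0-9]+).*", "\\1",
                         regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]))
  ops <- sub("[0-9]+", "", regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]])
  ref <- 0L; q <- 0L; qstart <- NA_integer_; qend <- NA_integer_
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("M", "D", "N", "=", "X")) ref <- ref + lens[i]
    if (ops[i] %in% c("M", "I", "S", "H", "=", "X")) {
      if (ops[i] %in% c("M", "I", "=", "X")) {
        if (is.na(qstart)) qstart <- q + 1L
        qend <- q + lens[i]
      }
      q <- q + lens[i]
    }
  }
  list(ref_width = ref, qstart = qstart, qend = qend)
}
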