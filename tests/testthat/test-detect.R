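test_that("length extrapolation is the inclusive clip-to-realignment distance", {
  expect_identical(infer_itd_length(28608261, 28608232), 30L)
  expect_identical(infer_itd_length(500, 500), 1L)
  ## realignment downstream of the clip point is not an ITD
  expect_identical(infer_itd_length(500, 501), NA_integer_)
  expect_identical(infer_itd_length(c(500, 510), c(401, 481)),
                   c(100L, 30L))
})

test_that("an in-envelope simulated ITD yields one exact call with burden recovery", {
  w <- test_window()
  bam <- sim_align(101, 100, burden = 0.5, n_pairs = 200)
  calls <- detect_itd(bam, w)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$length, 100L)
  ## left-aligned start within the repeat ambiguity window of ROI position 101
  expect_lte(abs(calls$position - roi_to_genomic(w, 101)), 100L)
  expect_identical(calls$support_forward, 100L)
  expect_identical(calls$support_reverse, 100L)
  expect_identical(calls$depth, 400L)
  expect_equal(calls$vaf, 0.5)
  ## the duplicate sequence is resolved from the reference
  expect_identical(nchar(calls$inserted_seq), 100L)
  full <- paste0(w$left_flank, w$roi_seq, w$right_flank)
  i <- calls$position - (w$roi_start - nchar(w$left_flank)) + 1L
  expect_identical(calls$inserted_seq, substr(full, i, i + 99L))
})

test_that("wild-type-only alignments produce zero calls", {
  w <- test_window()
  bam <- sim_align(101, 100, burden = 0, n_pairs = 100)
  calls <- detect_itd(bam, w)
  expect_identical(nrow(calls), 0L)
})

test_that("a single ITD read pair is sufficient for a call", {
  w <- test_window()
  bam <- sim_align(101, 100, burden = 1 / 200, n_pairs = 200)
  calls <- detect_itd(bam, w)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$length, 100L)
  expect_identical(calls$support_forward + calls$support_reverse, 2L)
  expect_equal(calls$vaf, 2 / 400)
})

test_that("two ITD clones in one sample are reported side by side", {
  w <- test_window()
  fq1 <- tempfile(); fq2 <- tempfile()
  ## 63 bp and 54 bp clones at different burdens over a shared wild-type pool
  simulate_combination(w, itd_spec(150, 63, burden = 0.5, n_pairs = 200),
                       fq1, fq2)
  simulate_combination(w, itd_spec(170, 54, burden = 0.1, n_pairs = 200),
                       fq1, fq2, append = TRUE)
  bam <- align_read_pairs(fq1, fq2, test_reference())
  calls <- detect_itd(bam, w)
  expect_setequal(calls$length, c(63L, 54L))
  c63 <- calls[calls$length == 63L, ]
  c54 <- calls[calls$length == 54L, ]
  expect_lte(abs(c63$position - roi_to_genomic(w, 150)), 63L)
  expect_lte(abs(c54$position - roi_to_genomic(w, 170)), 54L)
  ## support tracks the clone burdens (100 vs 20 carrier pairs)
  expect_gt(c63$support_forward + c63$support_reverse,
            c54$support_forward + c54$support_reverse)
})

test_that("pure insertions are recovered from read-pair clip geometry", {
  w <- test_window()
  ## a 120 bp insert of non-reference sequence after ROI position 100
  set.seed(99)
  insert <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                  collapse = "")
  lp <- substr(w$left_flank, nchar(w$left_flank) - 14L, nchar(w$left_flank))
  rp <- substr(w$right_flank, 1L, 26L)
  tpl <- paste0(lp, substr(w$roi_seq, 1, 100), insert,
                substr(w$roi_seq, 101, 201), rp)
  pairs <- simulate_read_pairs(tpl, 50)
  fq1 <- tempfile(); fq2 <- tempfile()
  writeLines(as.vector(rbind(paste0("@ins:", 1:50), pairs$seq1, "+",
                             pairs$qual1)), fq1)
  writeLines(as.vector(rbind(paste0("@ins:", 1:50), pairs$seq2, "+",
                             pairs$qual2)), fq2)
  bam <- align_read_pairs(fq1, fq2, test_reference())
  calls <- detect_itd(bam, w)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$length, 120L)
  expect_identical(calls$method, "pair_geometry")
  expect_lte(abs(calls$position - roi_to_genomic(w, 100)), 2L)
  ## insertion breakpoints are ambiguous under micro-homology; the reported
  ## (position, sequence) must reconstruct the true mutant locus
  full <- paste0(w$left_flank, w$roi_seq, w$right_flank)
  off <- w$roi_start - nchar(w$left_flank)
  i <- calls$position - off + 1L
  rebuilt <- paste0(substr(full, 1, i), calls$inserted_seq,
                    substr(full, i + 1L, nchar(full)))
  truth <- paste0(substr(full, 1, 400), insert,
                  substr(full, 401, nchar(full)))
  expect_identical(rebuilt, truth)
})

test_that("clips pointing away from each other are not an insertion signature", {
  ## mate1 left-clips and mate2 right-clips (outward): no pair evidence
  sam <- write_test_sam(list(
    list(qname = "p", flag = 99, pos = 200, cigar = "40S60M",
         seq = strrep("A", 100)),
    list(qname = "p", flag = 147, pos = 240, cigar = "60M40S",
         seq = strrep("C", 100))), chrom_len = 1000)
  aln <- read_alignments(sam)
  ev <- detect_pure_insertion(aln)
  expect_identical(nrow(ev), 0L)
})

test_that("evidence merges per direction and preserves read identity", {
  ev <- data.frame(
    qname = c("a", "b"), mate = c(1L, 2L),
    direction = c("forward", "reverse"),
    method = "softclip_realign", side = c("right", "left"),
    clip_point = c(500L, 401L), realign_edge = c(401L, 500L),
    length = 100L, position = 401L, rname = "FLT3amp_synthetic",
    insert_seq = NA_character_, low_confidence = FALSE,
    stringsAsFactors = FALSE)
  calls <- aggregate_itd_calls(ev, window = test_window())
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$support_forward, 1L)
  expect_identical(calls$support_reverse, 1L)
  expect_true(is.na(calls$depth))
  ## same mate voting twice (left and right route) still counts once
  ev2 <- rbind(ev, ev[1, ])
  calls2 <- aggregate_itd_calls(ev2, window = test_window())
  expect_identical(calls2$support_forward, 1L)
})

test_that("detection is deterministic for identical input", {
  w <- test_window()
  bam <- sim_align(150, 63, n_pairs = 50)
  expect_identical(detect_itd(bam, w), detect_itd(bam, w))
})
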