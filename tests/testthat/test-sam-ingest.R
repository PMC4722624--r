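test_that("roles, mates and clip geometry are derived from flags and CIGAR", {
  sam <- write_test_sam(list(
    list(qname = "plain", flag = 99, pos = 100, cigar = "201M",
         seq = strrep("A", 201)),
    list(qname = "clipped", flag = 0, pos = 100, cigar = "150M125S",
         seq = strrep("A", 275), sa = "ref,50,+,150S125M,60,0;"),
    list(qname = "clipped", flag = 2048, pos = 50, cigar = "150H125M",
         seq = strrep("A", 125)),
    list(qname = "adapter", flag = 16, pos = 100, cigar = "5S270M",
         seq = strrep("A", 275)),
    list(qname = "secondary", flag = 256, pos = 300, cigar = "50M"),
    list(qname = "lost", flag = 4, pos = 0, cigar = "*")))
  aln <- read_alignments(sam)
  expect_identical(nrow(aln), 6L)
  expect_setequal(aln$role[aln$qname == "clipped"],
                  c("primary", "supplementary"))
  expect_identical(aln$role[aln$qname == "secondary"], "secondary")
  expect_identical(aln$role[aln$qname == "lost"], "unmapped")
  expect_identical(aln$mate[aln$qname == "plain"], 1L)
  expect_identical(aln$strand[aln$qname == "adapter"], "-")

  pri <- aln[aln$qname == "clipped" & aln$role == "primary", ]
  expect_identical(pri$end, 100L + 150L - 1L)
  expect_identical(pri$soft_right, 125L)
  expect_identical(pri$qstart, 1L)
  expect_identical(pri$qend, 150L)
  sup <- aln[aln$qname == "clipped" & aln$role == "supplementary", ]
  ## hard clips count toward original-read query coordinates
  expect_identical(sup$qstart, 151L)
  expect_identical(sup$qend, 275L)
  expect_identical(sup$soft_right, 0L)
  expect_true(!is.na(pri$sa))
  expect_match(pri$sa, "150S125M")
})

test_that("soft-clip extraction applies the clip threshold and skips hard clips", {
  sam <- write_test_sam(list(
    list(qname = "r1", flag = 0, pos = 28608112 - 28600000,
         cigar = "150M125S", seq = strrep("A", 275)),
    list(qname = "r2", flag = 0, pos = 100, cigar = "5S270M",
         seq = strrep("C", 275)),
    list(qname = "r3", flag = 0, pos = 100, cigar = "201M",
         seq = strrep("G", 201)),
    list(qname = "r4", flag = 2048, pos = 400, cigar = "150H125M",
         seq = strrep("T", 125))), chrom_len = 100000)
  aln <- read_alignments(sam)
  clips <- extract_soft_clips(aln, min_clip = 10)
  ## only r1 qualifies: r2's clip is adapter-scale, r3 unclipped, r4 hard-clipped
  expect_identical(clips$qname, "r1")
  expect_identical(clips$side, "right")
  expect_identical(clips$clip_point, 28608112L - 28600000L + 149L)
  expect_identical(clips$clip_length, 125L)
  expect_identical(clips$clipped_seq, strrep("A", 125))
  ## threshold boundary: min_clip = 5 admits the adapter clip on the left
  clips5 <- extract_soft_clips(aln, min_clip = 5)
  expect_setequal(clips5$qname, c("r1", "r2"))
  expect_identical(clips5$side[clips5$qname == "r2"], "left")
  expect_identical(clips5$clip_point[clips5$qname == "r2"], 100L)
})

test_that("reference arithmetic agrees with a brute-force CIGAR walker", {
  set.seed(7)
  recs <- list()
  for (i in 1:40) {
    ops <- c(sprintf("%dS", sample(0:30, 1)),
             sprintf("%dM", sample(1:120, 1)),
             sprintf("%dI", sample(0:10, 1)),
             sprintf("%dM", sample(1:80, 1)),
             sprintf("%dD", sample(0:15, 1)),
             sprintf("%dM", sample(1:60, 1)),
             sprintf("%dS", sample(0:40, 1)))
    ops <- ops[!grepl("^0", ops)]
    cigar <- paste(ops, collapse = "")
    qlen <- sum(as.integer(unlist(regmatches(cigar,
      gregexpr("[0-9]+(?=[MIS])", cigar, perl = TRUE)))))
    recs[[i]] <- list(qname = paste0("w", i), flag = 0,
                      pos = sample(1:500, 1), cigar = cigar,
                      seq = strrep("A", qlen))
  }
  aln <- read_alignments(write_test_sam(recs, chrom_len = 5000))
  for (i in seq_len(nrow(aln))) {
    ww <- walk_cigar(aln$cigar[i])
    expect_identical(aln$end[i], aln$pos[i] + ww$ref_width - 1L)
    expect_identical(aln$qstart[i], ww$qstart)
    expect_identical(aln$qend[i], ww$qend)
  }
})

test_that("grouping by read separates primary and auxiliary records", {
  sam <- write_test_sam(list(
    list(qname = "solo", flag = 0, pos = 10, cigar = "50M", seq = strrep("A", 50)),
    list(qname = "pair", flag = 99, pos = 10, cigar = "50M", seq = strrep("A", 50)),
    list(qname = "pair", flag = 147, pos = 60, cigar = "50M", seq = strrep("A", 50)),
    list(qname = "split", flag = 0, pos = 10, cigar = "30M20S", seq = strrep("A", 50)),
    list(qname = "split", flag = 2048, pos = 100, cigar = "30H20M",
         seq = strrep("A", 20))))
  aln <- read_alignments(sam)
  grp <- group_by_read(aln)
  expect_setequal(names(grp), c("solo", "pair", "split"))
  expect_identical(nrow(grp$solo$primary), 1L)
  expect_identical(nrow(grp$solo$auxiliary), 0L)
  expect_identical(sort(grp$pair$primary$mate), c(1L, 2L))
  expect_identical(nrow(grp$split$auxiliary), 1L)
  ## every record appears exactly once
  expect_identical(sum(vapply(grp, function(g)
    nrow(g$primary) + nrow(g$auxiliary), 1L)), nrow(aln))
})

test_that("region restriction keeps only overlapping records", {
  sam <- write_test_sam(list(
    list(qname = "in", flag = 0, pos = 100, cigar = "50M", seq = strrep("A", 50)),
    list(qname = "edge", flag = 0, pos = 141, cigar = "50M", seq = strrep("A", 50)),
    list(qname = "out", flag = 0, pos = 300, cigar = "50M", seq = strrep("A", 50))))
  aln <- read_alignments(sam, region = "ref:120-150")
  expect_setequal(aln$qname, c("in", "edge"))
  empty <- read_alignments(sam, region = "ref:900-950")
  expect_identical(nrow(empty), 0L)
})
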