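## independent oracle: build the mutant ROI base by base from the genomic
## model (amplicon start .. segment end, then segment start .. ROI end)
naive_allele <- function(window, p, L) {
  ext <- strsplit(paste0(window$roi_seq, window$right_flank), "")[[1]]
  n <- roi_length(window)
  paste(c(ext[1:(p + L - 1)], ext[p:n]), collapse = "")
}

test_that("allele construction matches a direct string-construction oracle", {
  w <- test_window()
  set.seed(42)
  cases <- cbind(p = sample(201, 25), L = sample(201, 25, replace = TRUE))
  for (i in seq_len(nrow(cases))) {
    p <- cases[i, "p"]; L <- cases[i, "L"]
    a <- build_itd_allele(w, p, L)
    expect_identical(a, naive_allele(w, p, L))
    expect_identical(nchar(a), 201L + as.integer(L))
    ## tandem-repeat identity: the segment occurs twice in tandem (the
    ## second copy is truncated at the amplicon end when p + L - 1 > 201)
    k <- min(L, 202L - p)
    expect_identical(substr(a, p, p + k - 1), substr(a, p + L, p + L + k - 1))
  }
})

test_that("allele boundary cases behave as specified", {
  w <- test_window()
  a11 <- build_itd_allele(w, 1, 1)
  expect_identical(nchar(a11), 202L)
  expect_identical(substr(a11, 1, 1), substr(a11, 2, 2))

  a <- build_itd_allele(w, 101, 30)
  expect_identical(nchar(a), 231L)
  expect_identical(substr(a, 101, 130), substr(a, 131, 160))

  afull <- build_itd_allele(w, 1, 201)
  expect_identical(afull, paste0(w$roi_seq, w$roi_seq))

  ## insufficient right flank is a hard error
  thin <- reference_window(w$chrom, w$roi_start, w$roi_end, w$roi_seq,
                           right_flank = "ACGT")
  expect_error(build_itd_allele(thin, 200, 50), "past the available right flank")
  ## N inside the duplicated segment is refused
  wn <- reference_window("x", 1, 201,
                         paste0(strrep("A", 100), "N", strrep("C", 100)))
  expect_error(build_itd_allele(wn, 95, 10), "contains N")
})

test_that("read pairs follow the fixed-start amplicon model", {
  w <- test_window()
  short <- substr(w$roi_seq, 1, 201)
  rp <- simulate_read_pairs(short, 5, read_length = 275)
  expect_identical(nchar(rp$seq1), 201L)
  expect_identical(nchar(rp$seq2), 201L)

  tpl <- build_itd_allele(w, 1, 201)  # 402 bp
  rp <- simulate_read_pairs(tpl, 3, read_length = 275)
  expect_identical(rp$seq1, substr(tpl, 1, 275))
  expect_identical(
    rp$seq2,
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(tpl, 128, 402)))))
  expect_identical(nchar(rp$qual1), nchar(rp$seq1))
  expect_error(simulate_read_pairs(tpl, 0), "positive")
})

test_that("combination simulation honours burden, rounding and determinism", {
  w <- test_window()
  fq1 <- tempfile(); fq2 <- tempfile()
  tr <- simulate_combination(w, itd_spec(101, 100, burden = 0.5, n_pairs = 20),
                             fq1, fq2)
  expect_identical(tr$n_itd_pairs, 10L)
  expect_identical(tr$n_wt_pairs, 10L)
  l1 <- readLines(fq1)
  expect_length(l1, 80L)  # 4 lines x 20 records
  nm <- sub("^@", "", l1[seq(1, 80, 4)])
  expect_identical(sum(grepl(":itd:", nm)), 10L)
  expect_identical(sum(grepl(":wt:", nm)), 10L)
  expect_true(all(startsWith(nm, "c101_100:")))

  ## byte-identical re-run
  fq1b <- tempfile(); fq2b <- tempfile()
  simulate_combination(w, itd_spec(101, 100, burden = 0.5, n_pairs = 20),
                       fq1b, fq2b)
  expect_identical(readLines(fq1b), l1)
  expect_identical(readLines(fq2b), readLines(fq2))

  ## burden 0: all wild type
  tr0 <- simulate_combination(w, itd_spec(101, 100, burden = 0, n_pairs = 20),
                              fq1, fq2)
  expect_identical(tr0$n_itd_pairs, 0L)
  expect_identical(tr0$n_wt_pairs, 20L)

  ## single-read clone: one pair in 2000, via round-half-up with floor 1
  tr1 <- simulate_combination(w, itd_spec(101, 100, burden = 1 / 2000,
                                          n_pairs = 2000), fq1, fq2)
  expect_identical(tr1$n_itd_pairs, 1L)
  expect_identical(tr1$n_wt_pairs, 1999L)
})

test_that("grid enumeration is the exhaustive bijective product", {
  w <- test_window()
  g <- enumerate_grid(w)
  expect_identical(nrow(g), 40401L)
  expect_identical(anyDuplicated(g$combination_id), 0L)
  ## ids reconstruct (start, length)
  parsed <- regmatches(g$combination_id,
                       regexec("^c([0-9]+)_([0-9]+)$", g$combination_id))
  expect_true(all(vapply(parsed, function(x) as.integer(x[2]), 1L) == g$start))
  expect_true(all(vapply(parsed, function(x) as.integer(x[3]), 1L) == g$length))

  g1 <- enumerate_grid(w, max_length = 1)
  expect_identical(nrow(g1), 201L)
  expect_error(enumerate_grid(w, max_length = 0), "max_length")
})
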