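## ITD detection from soft-clip geometry.
##
## An internal tandem duplication turns one locus of the read into two
## tandem copies. When the read cannot be aligned with a simple insertion,
## the aligner clips the extra bases (CIGAR S) and realigns them to the same
## locus as a secondary/supplementary record. The duplication length is the
## distance between the point of soft-clipping and the junction-side
## boundary of the realignment; the aggregation is performed per read and
## per direction so that a single supporting read is sufficient.

## full known sequence of the window and the genomic position of its first base
window_full_seq <- function(window) {
  paste0(window$left_flank, window$roi_seq, window$right_flank)
}
window_seq_offset <- function(window) {
  window$roi_start - nchar(window$left_flank)   # genomic pos of fullseq[1]
}
window_base <- function(window, gpos) {
  i <- gpos - window_seq_offset(window) + 1L
  full <- window_full_seq(window)
  out <- rep(NA_character_, length(i))
  ok <- i >= 1L & i <= nchar(full)
  out[ok] <- substring(full, i[ok], i[ok])
  out
}

#' Extrapolate ITD length from clip point and realignment start
#'
#' The duplication length is the distance between the reference position of
#' the last aligned base before a terminal soft clip (`clip_point`, c) and
#' the reference position where the clipped bases realign
#' (`realign_start`, s): `L = c - s + 1`. A realignment downstream of the
#' clip point is not an ITD signature and yields `NA`.
#'
#' The evidence collector additionally corrects for chance micro-homology at
#' the duplication junction, where the aligner extends the realignment a few
#' bases past the clip boundary (see [collect_itd_evidence()]).
#'
#' @param clip_point Reference position(s) of the aligned base adjacent to
#'   the soft clip.
#' @param realign_start Reference position(s) of the start of the
#'   realignment of the clipped bases.
#' @return Integer vector of inferred lengths (`NA` where the geometry is
#'   not a tandem duplication).
#' @examples
#' infer_itd_length(28608261, 28608232)  # 30 bp
#' @export
infer_itd_length <- function(clip_point, realign_start) {
  clip_point <- as.integer(clip_point)
  realign_start <- as.integer(realign_start)
  len <- clip_point - realign_start + 1L
  len[!is.na(len) & len < 1L] <- NA_integer_
  len
}

empty_evidence <- function() {
  data.frame(qname = character(), mate = integer(), direction = character(),
             method = character(), side = character(), clip_point = integer(),
             realign_edge = integer(), length = integer(), position = integer(),
             rname = character(), insert_seq = character(),
             low_confidence = logical(), stringsAsFactors = FALSE)
}

#' Collect per-read ITD evidence from soft-clip realignments
#'
#' Searches primary alignments for terminal soft clips of at least
#' `min_clip` bases and correlates each with secondary/supplementary
#' realignments of the same read and mate on the same strand of the same
#' reference. For a right clip ending at reference position c whose clipped
#' bases realign starting at s (s <= c), the inferred length is `c - s + 1`;
#' left clips are handled mirror-wise using the realignment end. When the
#' realignment was extended across the duplication junction by chance
#' micro-homology, the overlap between the two alignments' query intervals
#' is subtracted, so the inferred length is exact for true tandem
#' duplications. The analysis is per read and per direction, so a single
#' supporting read yields evidence.
#'
#' Two QC requirements guard against junction-crossing alignment artifacts:
#' the aligned block adjacent to the clip must be an M run of at least
#' `min_anchor` bases, on both the primary and the realignment. Inferred
#' lengths below `min_clip` are discarded as well: a duplication that short
#' is represented by the aligner as a CIGAR insertion rather than a clip, so
#' sub-`min_clip` "evidence" can only arise from chance micro-homology at an
#' unrelated breakpoint (e.g. a pure insertion), not from a genuine
#' clip-realignment geometry.
#'
#' @param alignments Record table from [read_alignments()].
#' @param window Optional [reference_window()]; realignments outside the
#'   window's reference span are ignored.
#' @param min_clip Minimum soft-clip length (default 10 bp).
#' @param min_anchor Minimum clip-adjacent matched block (default 15 bp).
#' @param min_mapq Minimum mapping quality of the primary alignment
#'   (default 1); realignment records are not MAPQ-filtered (they are often
#'   MAPQ 0).
#' @return A `data.frame` of evidence items, one row per qualifying
#'   (read, mate) x realignment, with columns `qname`, `mate`, `direction`,
#'   `method` (`"softclip_realign"`), `side`, `clip_point`, `realign_edge`,
#'   `length`, `position` (duplication start, before left-alignment),
#'   `rname`, `insert_seq` (`NA`; resolved from the reference at call
#'   aggregation), `low_confidence`.
#' @export
collect_itd_evidence <- function(alignments, window = NULL, min_clip = 10L,
                                 min_anchor = 15L, min_mapq = 1L) {
  if (nrow(alignments) == 0L) return(empty_evidence())
  a <- data.table::as.data.table(alignments)
  pri <- a[role == "primary" & !is.na(pos) & mapq >= min_mapq]
  aux <- a[role %in% c("secondary", "supplementary") & !is.na(pos)]
  if (!is.null(window)) {
    lo <- window_seq_offset(window)
    hi <- window$roi_end + nchar(window$right_flank)
    aux <- aux[rname == window$chrom & pos >= lo & end <= hi]
  }
  if (nrow(pri) == 0L || nrow(aux) == 0L) return(empty_evidence())
  data.table::setkey(aux, qname, mate)
  pieces <- list()

  r <- pri[soft_right >= min_clip & anchor_right >= min_anchor]
  if (nrow(r)) {
    cand <- aux[r, on = c("qname", "mate"), allow.cartesian = TRUE, nomatch = NULL]
    ## i.* columns are the primary's; plain columns the realignment's
    cand <- cand[strand == i.strand & rname == i.rname & pos <= i.end &
                 anchor_left >= min_anchor]
    if (nrow(cand)) {
      cand[, o := pmax(0L, i.qend - qstart + 1L)]
      cand[, len := i.end - pos + 1L - o]
      cand <- cand[len >= min_clip]
      if (nrow(cand))
        pieces$right <- cand[, .(qname, mate, direction = ifelse(i.strand == "+",
                                                                 "forward", "reverse"),
                                 method = "softclip_realign", side = "right",
                                 clip_point = i.end, realign_edge = pos,
                                 length = len, position = pos, rname,
                                 insert_seq = NA_character_,
                                 low_confidence = FALSE)]
    }
  }

  l <- pri[soft_left >= min_clip & anchor_left >= min_anchor]
  if (nrow(l)) {
    cand <- aux[l, on = c("qname", "mate"), allow.cartesian = TRUE, nomatch = NULL]
    cand <- cand[strand == i.strand & rname == i.rname & end >= i.pos &
                 anchor_right >= min_anchor]
    if (nrow(cand)) {
      cand[, o := pmax(0L, qend - i.qstart + 1L)]
      cand[, len := end - i.pos + 1L - o]
      cand <- cand[len >= min_clip]
      if (nrow(cand))
        pieces$left <- cand[, .(qname, mate, direction = ifelse(i.strand == "+",
                                                                "forward", "reverse"),
                                method = "softclip_realign", side = "left",
                                clip_point = i.pos, realign_edge = end,
                                length = len, position = i.pos, rname,
                                insert_seq = NA_character_,
                                low_confidence = FALSE)]
    }
  }

  if (!length(pieces)) return(empty_evidence())
  ev <- unique(data.table::rbindlist(pieces))
  data.table::setDF(ev)
  ev
}

## longest o such that the first o bases of x equal the last o bases of y
prefix_suffix_overlap <- function(x, y) {
  nx <- nchar(x); ny <- nchar(y)
  for (o in seq.int(min(nx, ny), 1L)) {
    if (substr(x, 1L, o) == substr(y, ny - o + 1L, ny)) return(o)
  }
  0L
}

#' Detect pure insertions from read-pair clip geometry
#'
#' A special ITD type consists entirely of inserted sequence of unknown
#' origin; the clipped bases then have no realignment to the locus, so the
#' soft-clip/realignment route is silent. Such insertions are identified by
#' comparing the points of soft-clipping within a read pair: one mate
#' right-clips at reference position c1, the other left-clips at c2, and the
#' two breakpoints coincide (`c2` within `c1 +/- 1` of the expected `c1 + 1`).
#' The insertion length is recovered as the longest overlap between the
#' clipped sequences (prefix of the right-clipped bases vs suffix of the
#' left-clipped bases), which equals the insert when both mates span it.
#' When only one mate is informative (the other does not cover the
#' breakpoint), the right-clip length is used as a lower-confidence estimate.
#'
#' Pairs that already have soft-clip/realignment evidence are skipped.
#'
#' @param alignments Record table from [read_alignments()].
#' @param evidence Evidence from [collect_itd_evidence()] on the same
#'   records (used to skip pairs already explained by realignment).
#' @param min_clip Minimum clip length and minimum recoverable insert
#'   (default 10 bp).
#' @param slack Allowed breakpoint disagreement in bp (default 1).
#' @return Evidence rows with `method = "pair_geometry"` (see
#'   [collect_itd_evidence()] for columns); possibly zero rows.
#' @export
detect_pure_insertion <- function(alignments, evidence = NULL, min_clip = 10L,
                                  slack = 1L) {
  pri <- alignments[alignments$role == "primary" & !is.na(alignments$pos), ,
                    drop = FALSE]
  if (nrow(pri) == 0L) return(empty_evidence())
  skip <- if (!is.null(evidence)) unique(evidence$qname) else character(0)
  pri <- pri[!pri$qname %in% skip, , drop = FALSE]
  rc <- pri[!is.na(pri$soft_right) & pri$soft_right >= min_clip &
              !is.na(pri$seq), , drop = FALSE]
  if (nrow(rc) == 0L) return(empty_evidence())
  mate_key <- paste0(pri$qname, "/", pri$mate)
  other_idx <- match(paste0(rc$qname, "/", ifelse(rc$mate == 1L, 2L, 1L)),
                     mate_key)
  out <- list()
  for (i in seq_len(nrow(rc))) {
    if (is.na(other_idx[i])) next
    m1 <- rc[i, ]
    m2 <- pri[other_idx[i], ]
    if (m2$strand == m1$strand || m2$rname != m1$rname) next
    c1 <- m1$end
    k1 <- m1$soft_right
    clip1 <- substr(m1$seq, nchar(m1$seq) - k1 + 1L, nchar(m1$seq))
    if (!is.na(m2$soft_left) && m2$soft_left >= min_clip && !is.na(m2$seq)) {
      c2 <- m2$pos
      ## for a clean insertion the left clip starts right after the right
      ## clip point (c2 == c1 + 1); chance micro-homology lets either
      ## primary consume insert bases, shifting the breakpoints toward each
      ## other by delta reference bases, which must be added back
      delta <- c1 + 1L - c2
      if (delta < 0L || delta > slack) next
      k2 <- m2$soft_left
      clip2 <- substr(m2$seq, 1L, k2)
      o <- prefix_suffix_overlap(clip1, clip2)
      if (o < min_clip) next
      len <- o + delta
      out[[length(out) + 1L]] <- data.frame(
        qname = m1$qname, mate = m1$mate,
        direction = if (m1$strand == "+") "forward" else "reverse",
        method = "pair_geometry", side = "pair",
        clip_point = c1, realign_edge = NA_integer_,
        length = len, position = c1, rname = m1$rname,
        insert_seq = substr(clip1, 1L, len), low_confidence = FALSE,
        stringsAsFactors = FALSE)
    } else if (m2$pos > c1 || m2$end < c1) {
      ## other mate does not cover the breakpoint: clip length is all we have
      out[[length(out) + 1L]] <- data.frame(
        qname = m1$qname, mate = m1$mate,
        direction = if (m1$strand == "+") "forward" else "reverse",
        method = "pair_geometry", side = "pair",
        clip_point = c1, realign_edge = NA_integer_,
        length = k1, position = c1, rname = m1$rname,
        insert_seq = clip1, low_confidence = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_evidence())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## shift a duplication start to its leftmost equivalent position
left_align_position <- function(window, position, length) {
  if (is.null(window)) return(position)
  p <- position
  repeat {
    prev <- window_base(window, p - 1L)
    last <- window_base(window, p + length - 1L)
    if (is.na(prev) || is.na(last) || prev != last) break
    p <- p - 1L
  }
  p
}

empty_calls <- function() {
  data.frame(rname = character(), position = integer(), length = integer(),
             inserted_seq = character(), method = character(),
             support_forward = integer(), support_reverse = integer(),
             depth = integer(), vaf = numeric(), low_confidence = logical(),
             stringsAsFactors = FALSE)
}

#' Aggregate per-read evidence into ITD calls
#'
#' Evidence items with the same left-aligned duplication start and length
#' merge into one call; support is counted per direction (each read counted
#' at most once per direction per call). Distinct (position, length) pairs
#' yield distinct calls, so multiple ITD clones in one sample are reported
#' side by side. Depth is the number of primary alignments overlapping the
#' call position and `vaf = (support_forward + support_reverse) / depth`.
#'
#' Tandem duplications are coordinate-ambiguous; calls are reported at the
#' leftmost equivalent start, matching VCF left-alignment conventions and
#' making the merge well-defined.
#'
#' @param evidence Evidence rows from [collect_itd_evidence()] and/or
#'   [detect_pure_insertion()].
#' @param alignments Optional record table; needed to compute depth.
#' @param window Optional [reference_window()]; needed for left-alignment
#'   and to resolve the inserted duplicate sequence from the reference.
#' @return A `data.frame` of calls sorted by position then length, with
#'   columns `rname`, `position`, `length`, `inserted_seq`, `method`,
#'   `support_forward`, `support_reverse`, `depth`, `vaf`, `low_confidence`.
#' @export
aggregate_itd_calls <- function(evidence, alignments = NULL, window = NULL) {
  if (is.null(evidence) || nrow(evidence) == 0L) return(empty_calls())
  ev <- data.table::as.data.table(evidence)
  ## left-align per unique (position, length); only duplication evidence is
  ## shiftable (its insert equals reference), not arbitrary-sequence inserts
  key <- unique(ev[, .(position, length, method)])
  key[, la := ifelse(method == "softclip_realign",
                     mapply(function(p, l) left_align_position(window, p, l),
                            position, length),
                     position)]
  ev <- merge(ev, key, by = c("position", "length", "method"))
  ## one vote per read mate and direction per (site, length)
  ev <- unique(ev, by = c("qname", "mate", "direction", "la", "length"))
  calls <- ev[, .(
    rname = rname[1L],
    support_forward = sum(direction == "forward"),
    support_reverse = sum(direction == "reverse"),
    method = paste(sort(unique(method)), collapse = ","),
    insert_seq = {
      s <- insert_seq[!is.na(insert_seq)]
      if (length(s)) s[1L] else NA_character_
    },
    low_confidence = all(low_confidence)
  ), by = .(position = la, length)]

  ## resolve duplicate sequence from the reference for realignment calls
  if (!is.null(window)) {
    need <- is.na(calls$insert_seq)
    if (any(need)) {
      full <- window_full_seq(window)
      off <- window_seq_offset(window)
      i1 <- calls$position[need] - off + 1L
      i2 <- i1 + calls$length[need] - 1L
      ok <- i1 >= 1L & i2 <= nchar(full)
      seqs <- rep(NA_character_, sum(need))
      seqs[ok] <- substring(full, i1[ok], i2[ok])
      calls$insert_seq[need] <- seqs
    }
  }

  ## depth at call position from primary alignments
  if (!is.null(alignments) && nrow(alignments)) {
    pri <- alignments[alignments$role == "primary" & !is.na(alignments$pos), ,
                      drop = FALSE]
    calls[, depth := vapply(position, function(p)
      sum(pri$pos <= p & pri$end >= p, na.rm = TRUE), integer(1))]
  } else {
    calls[, depth := NA_integer_]
  }
  calls[, vaf := (support_forward + support_reverse) / depth]
  data.table::setorder(calls, position, length)
  out <- data.frame(
    rname = calls$rname, position = calls$position, length = calls$length,
    inserted_seq = calls$insert_seq, method = calls$method,
    support_forward = calls$support_forward,
    support_reverse = calls$support_reverse,
    depth = calls$depth, vaf = calls$vaf,
    low_confidence = calls$low_confidence, stringsAsFactors = FALSE)
  out
}

#' Detect ITDs in a SAM/BAM file
#'
#' End-to-end detection: read alignments (optionally restricted to a
#' region), collect soft-clip/realignment evidence, detect pure insertions
#' from pair clip geometry, and aggregate into calls. Deterministic for a
#' fixed input; calls are sorted by position then length. No reporting
#' threshold is applied here: every call with at least one supporting read
#' is returned (clinical thresholds are annotation labels; see
#' [apply_reporting_policy()]).
#'
#' @param path SAM/BAM file, or a record table from [read_alignments()].
#' @param window A [reference_window()].
#' @param region Optional region string restricting the analysis; defaults
#'   to the window's ROI extended by its flanks.
#' @param min_clip,min_anchor,min_mapq See [collect_itd_evidence()].
#' @param pure_insertion Also run the read-pair clip-geometry route
#'   (default `TRUE`).
#' @return Calls as from [aggregate_itd_calls()].
#' @examples
#' \dontrun{calls <- detect_itd("sample.bam", window)}
#' @export
detect_itd <- function(path, window, region = NULL, min_clip = 10L,
                       min_anchor = 15L, min_mapq = 1L,
                       pure_insertion = TRUE) {
  stopifnot(inherits(window, "reference_window"))
  aln <- if (is.data.frame(path)) path else read_alignments(path, region)
  ev <- collect_itd_evidence(aln, window, min_clip = min_clip,
                             min_anchor = min_anchor, min_mapq = min_mapq)
  if (pure_insertion) {
    pe <- detect_pure_insertion(aln, evidence = ev, min_clip = min_clip)
    ev <- rbind(ev, pe)
  }
  aggregate_itd_calls(ev, alignments = aln, window = window)
}
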