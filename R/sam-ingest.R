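## Alignment ingestion: SAM/BAM -> aligner-agnostic record table.
##
## Records keep both reference coordinates (pos/end, 1-based inclusive, SAM
## convention) and query coordinates along the original read (qstart/qend,
## counting soft- AND hard-clipped bases), because ITD length inference needs
## to reconcile where the primary alignment and the realignment of clipped
## bases sit on the same read.

## per-CIGAR metrics, one pass over exploded operations
cigar_stats <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  n <- length(cigar)
  rw <- qw <- lclip <- rclip <- lsoft <- rsoft <- lanchor <- ranchor <-
    integer(n)
  for (i in seq_len(n)) {
    op <- ops[[i]]; len <- lens[[i]]
    rw[i] <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    qw[i] <- sum(len[op %in% c("M", "I", "=", "X")])
    k <- length(op)
    j1 <- 1L
    if (op[j1] %in% c("S", "H")) {
      lclip[i] <- len[j1]
      if (op[j1] == "S") lsoft[i] <- len[j1]
      j1 <- j1 + 1L
      ## an S may follow an H (e.g. 10H5S...)
      if (j1 <= k && op[j1] == "S") {
        lclip[i] <- lclip[i] + len[j1]
        lsoft[i] <- lsoft[i] + len[j1]
        j1 <- j1 + 1L
      }
    }
    j2 <- k
    if (op[j2] %in% c("S", "H")) {
      rclip[i] <- len[j2]
      if (op[j2] == "S") rsoft[i] <- len[j2]
      j2 <- j2 - 1L
      if (j2 >= 1L && op[j2] == "S") {
        rclip[i] <- rclip[i] + len[j2]
        rsoft[i] <- rsoft[i] + len[j2]
        j2 <- j2 - 1L
      }
    }
    if (j1 <= k && op[j1] == "M") lanchor[i] <- len[j1]
    if (j2 >= 1L && op[j2] == "M") ranchor[i] <- len[j2]
  }
  list(rw = rw, qw = qw, lclip = lclip, rclip = rclip,
       lsoft = lsoft, rsoft = rsoft, lanchor = lanchor, ranchor = ranchor)
}

as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  ## SAM input: convert (sort + index) via Rsamtools
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
}

#' Read SAM/BAM alignments into an alignment record table
#'
#' Parses every record of a SAM or BAM file (SAM files are converted on the
#' fly) into a flat `data.frame`, one row per alignment record, with the
#' record role (`primary`, `secondary`, `supplementary`, `unmapped`) derived
#' from the flag bits and clip/anchor geometry precomputed from the CIGAR.
#'
#' @param path SAM or BAM file.
#' @param region Optional region string (`"chrom:start-end"`); only records
#'   overlapping the region are returned.
#' @return A `data.frame` with columns `qname`, `flag`, `mate` (1/2),
#'   `strand` (`"+"`/`"-"`), `role`, `rname`, `pos`, `end`, `mapq`, `cigar`,
#'   `seq` (stored sequence; `NA` when absent), `sa` (SA tag or `NA`),
#'   `clip_left`, `clip_right` (terminal clip lengths, soft + hard),
#'   `soft_left`, `soft_right` (soft-clip only), `anchor_left`,
#'   `anchor_right` (aligned M-run adjacent to each end), `qstart`, `qend`
#'   (aligned query interval in original-read coordinates).
#' @examples
#' \dontrun{aln <- read_alignments("sample.bam", "chr13:28607161-28609590")}
#' @export
read_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- as_bam(path)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  p <- Rsamtools::ScanBamParam(what = what, tag = "SA")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  df <- data.frame(
    qname = res$qname,
    flag = res$flag,
    rname = as.character(res$rname),
    pos = res$pos,
    mapq = res$mapq,
    cigar = res$cigar,
    seq = as.character(res$seq),
    stringsAsFactors = FALSE)
  df$sa <- if (is.null(res$tag$SA)) NA_character_ else res$tag$SA
  df$seq[!nzchar(df$seq) | df$seq == "*"] <- NA_character_
  df$mate <- ifelse(bitwAnd(df$flag, 0x40L) > 0L, 1L,
                    ifelse(bitwAnd(df$flag, 0x80L) > 0L, 2L, 1L))
  df$strand <- ifelse(bitwAnd(df$flag, 0x10L) > 0L, "-", "+")
  df$role <- ifelse(bitwAnd(df$flag, 0x4L) > 0L, "unmapped",
             ifelse(bitwAnd(df$flag, 0x800L) > 0L, "supplementary",
             ifelse(bitwAnd(df$flag, 0x100L) > 0L, "secondary", "primary")))
  mapped <- df$role != "unmapped" & !is.na(df$cigar) & df$cigar != "*"
  cs <- cigar_stats(df$cigar[mapped])
  df$end <- df$clip_left <- df$clip_right <- df$soft_left <- df$soft_right <-
    df$anchor_left <- df$anchor_right <- df$qstart <- df$qend <- NA_integer_
  df$end[mapped] <- df$pos[mapped] + cs$rw - 1L
  df$clip_left[mapped] <- cs$lclip
  df$clip_right[mapped] <- cs$rclip
  df$soft_left[mapped] <- cs$lsoft
  df$soft_right[mapped] <- cs$rsoft
  df$anchor_left[mapped] <- cs$lanchor
  df$anchor_right[mapped] <- cs$ranchor
  df$qstart[mapped] <- cs$lclip + 1L
  df$qend[mapped] <- cs$lclip + cs$qw
  if (!is.null(region)) {
    reg <- parse_region(region)
    keep <- df$role != "unmapped" & df$rname == reg$chrom &
      df$pos <= reg$end & df$end >= reg$start
    keep[is.na(keep)] <- FALSE
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Extract qualifying terminal soft clips
#'
#' Returns one row per terminal soft-clip (CIGAR `S`) of length at least
#' `min_clip`, with the reference position of the aligned base adjacent to
#' the clip (`clip_point`: the first aligned base for left clips, the last
#' aligned base for right clips) and the clipped bases where the stored
#' sequence is available. Hard clips never qualify. The `min_clip` threshold
#' separates ITD-scale clips from the consistently short clips produced by
#' read-through into universal adapters.
#'
#' @param alignments A record table from [read_alignments()] (or a subset).
#' @param min_clip Minimum clip length in bp (default 10).
#' @return A `data.frame` with columns `qname`, `mate`, `strand`, `side`
#'   (`"left"`/`"right"`), `clip_point`, `clip_length`, `clipped_seq`.
#' @export
extract_soft_clips <- function(alignments, min_clip = 10L) {
  min_clip <- as.integer(min_clip)
  a <- alignments[alignments$role != "unmapped" & !is.na(alignments$pos), ,
                  drop = FALSE]
  out <- list()
  l <- a[!is.na(a$soft_left) & a$soft_left >= min_clip, , drop = FALSE]
  if (nrow(l)) {
    seq_ok <- !is.na(l$seq) & l$clip_left == l$soft_left
    out$left <- data.frame(
      qname = l$qname, mate = l$mate, strand = l$strand, side = "left",
      clip_point = l$pos, clip_length = l$soft_left,
      clipped_seq = ifelse(seq_ok, substr(l$seq, 1L, l$soft_left),
                           NA_character_),
      stringsAsFactors = FALSE)
  }
  r <- a[!is.na(a$soft_right) & a$soft_right >= min_clip, , drop = FALSE]
  if (nrow(r)) {
    len <- nchar(r$seq)
    seq_ok <- !is.na(r$seq) & r$clip_right == r$soft_right
    out$right <- data.frame(
      qname = r$qname, mate = r$mate, strand = r$strand, side = "right",
      clip_point = r$end, clip_length = r$soft_right,
      clipped_seq = ifelse(seq_ok,
                           substr(r$seq, len - r$soft_right + 1L, len),
                           NA_character_),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(qname = character(), mate = integer(),
                      strand = character(), side = character(),
                      clip_point = integer(), clip_length = integer(),
                      clipped_seq = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group alignment records by read
#'
#' Splits a record table by read name, separating the primary records from
#' auxiliary (secondary/supplementary) realignment records, which represent
#' the realignment of soft-clipped bases. Every input record appears exactly
#' once.
#'
#' @param alignments A record table from [read_alignments()].
#' @return A named list (one element per read name), each a list with
#'   elements `primary` and `auxiliary` (both `data.frame`s).
#' @export
group_by_read <- function(alignments) {
  idx <- split(seq_len(nrow(alignments)), alignments$qname)
  lapply(idx, function(i) {
    rec <- alignments[i, , drop = FALSE]
    list(primary = rec[rec$role %in% c("primary", "unmapped"), , drop = FALSE],
         auxiliary = rec[rec$role %in% c("secondary", "supplementary"), ,
                         drop = FALSE])
  })
}
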