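#' Clinical reporting policy
#'
#' The panel's reporting thresholds: a variant is reportable when its allele
#' fraction is at least `min_vaf` at a sequencing depth of at least
#' `min_depth` (defaults 10% and 500-fold; regions below 500-fold depth are
#' regarded as sub-optimal). Thresholds are inclusive.
#'
#' @param min_vaf Minimum reportable variant allele fraction (default 0.10).
#' @param min_depth Minimum sequencing depth (default 500).
#' @return An object of class `reporting_policy`.
#' @examples
#' reporting_policy()
#' @export
reporting_policy <- function(min_vaf = 0.10, min_depth = 500L) {
  stopifnot(is.numeric(min_vaf), length(min_vaf) == 1L,
            min_vaf >= 0, min_vaf <= 1)
  min_depth <- as.integer(min_depth)
  stopifnot(!is.na(min_depth), min_depth >= 0L)
  structure(list(min_vaf = min_vaf, min_depth = min_depth),
            class = "reporting_policy")
}

#' @export
print.reporting_policy <- function(x, ...) {
  cat(sprintf("reporting_policy: VAF >= %.3g, depth >= %d\n",
              x$min_vaf, x$min_depth))
  invisible(x)
}

#' Annotate calls with reporting filters
#'
#' Pure annotation: calls are labelled, never dropped, preserving the
#' practice of inspecting sub-threshold signal. A call passing both
#' thresholds gets `"PASS"`; otherwise the applicable labels `"LowVAF"`
#' and/or `"LowDepth"`, semicolon-separated. Calls with unknown VAF or depth
#' are labelled `"."`.
#'
#' @param calls Calls from [detect_itd()]/[aggregate_itd_calls()].
#' @param policy A [reporting_policy()].
#' @return `calls` with a `filter` column added/replaced.
#' @export
apply_reporting_policy <- function(calls, policy = reporting_policy()) {
  stopifnot(inherits(policy, "reporting_policy"))
  if (nrow(calls) == 0L) {
    calls$filter <- character(0)
    return(calls)
  }
  lab <- character(nrow(calls))
  low_vaf <- !is.na(calls$vaf) & calls$vaf < policy$min_vaf
  low_dp <- !is.na(calls$depth) & calls$depth < policy$min_depth
  unknown <- is.na(calls$vaf) | is.na(calls$depth)
  lab[] <- "PASS"
  lab[low_vaf & !low_dp] <- "LowVAF"
  lab[!low_vaf & low_dp] <- "LowDepth"
  lab[low_vaf & low_dp] <- "LowVAF;LowDepth"
  lab[unknown] <- "."
  calls$filter <- lab
  calls
}

#' Write ITD calls to VCF
#'
#' Serialises calls as VCF 4.2. Each tandem duplication is written as an
#' insertion at the base before the (left-aligned) duplication start, with
#' the duplicate sequence in the ALT allele when it could be resolved, and
#' as a symbolic `<DUP:TANDEM>` allele otherwise. INFO carries the
#' duplication length (`SVLEN`), per-direction support (`SUPF`, `SUPR`),
#' depth (`DP`) and the evidence method; the per-sample FORMAT carries the
#' variant allele fraction (`VF`). FILTER holds the reporting-policy labels
#' (see [apply_reporting_policy()]); thresholds are inclusive and recorded
#' in the header.
#'
#' @param calls Calls from [detect_itd()].
#' @param window The [reference_window()] the calls refer to.
#' @param path Output VCF path.
#' @param policy A [reporting_policy()] (applied unless `calls` already has
#'   a `filter` column).
#' @param sample_name Sample column name (default `"SAMPLE"`).
#' @return `path`, invisibly.
#' @export
write_itd_vcf <- function(calls, window, path, policy = reporting_policy(),
                          sample_name = "SAMPLE") {
  stopifnot(inherits(window, "reference_window"))
  if (!"filter" %in% names(calls))
    calls <- apply_reporting_policy(calls, policy)
  off <- window_seq_offset(window)
  hi <- window$roi_end + nchar(window$right_flank)
  if (nrow(calls) && (any(calls$position < off) || any(calls$position > hi)))
    stop("call position outside the reference window span ", off, "..", hi)

  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=itdscan ", as.character(utils::packageVersion("itdscan"))),
    sprintf("##contig=<ID=%s>", window$chrom),
    sprintf("##region=<ROI=%s:%d-%d>", window$chrom, window$roi_start,
            window$roi_end),
    "##ALT=<ID=DUP:TANDEM,Description=\"Tandem duplication\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Duplication length in bp\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the duplicated segment\">",
    "##INFO=<ID=SUPF,Number=1,Type=Integer,Description=\"Supporting reads, forward direction\">",
    "##INFO=<ID=SUPR,Number=1,Type=Integer,Description=\"Supporting reads, reverse direction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at the call position\">",
    "##INFO=<ID=METHOD,Number=1,Type=String,Description=\"Evidence method (softclip_realign and/or pair_geometry)\">",
    "##INFO=<ID=LOWCONF,Number=0,Type=Flag,Description=\"Length inferred from a single clip only\">",
    "##FORMAT=<ID=VF,Number=1,Type=Float,Description=\"Variant allele fraction (supporting reads / depth)\">",
    sprintf("##FILTER=<ID=LowVAF,Description=\"Variant allele fraction below %.3g (threshold inclusive)\">",
            policy$min_vaf),
    sprintf("##FILTER=<ID=LowDepth,Description=\"Depth below %d-fold (threshold inclusive)\">",
            policy$min_depth),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name))

  lines <- hdr
  if (nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      cl <- calls[i, ]
      have_seq <- !is.na(cl$inserted_seq)
      anchor_prev <- cl$position - 1L >= off
      if (anchor_prev) {
        pos <- cl$position - 1L
        ref <- window_base(window, pos)
        alt <- if (have_seq) paste0(ref, cl$inserted_seq) else "<DUP:TANDEM>"
      } else {
        ## duplication at the first known base: anchor on it, insert before
        pos <- cl$position
        ref <- window_base(window, pos)
        alt <- if (have_seq) paste0(cl$inserted_seq, ref) else "<DUP:TANDEM>"
      }
      info <- sprintf("SVLEN=%d;END=%d;SUPF=%d;SUPR=%d;DP=%s;METHOD=%s",
                      cl$length, cl$position + cl$length - 1L,
                      cl$support_forward, cl$support_reverse,
                      if (is.na(cl$depth)) "." else as.character(cl$depth),
                      cl$method)
      if (isTRUE(cl$low_confidence)) info <- paste0(info, ";LOWCONF")
      lines <- c(lines, sprintf(
        "%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tVF\t%s",
        cl$rname, pos, ref, alt, cl$filter, info,
        if (is.na(cl$vaf)) "." else sprintf("%.6g", cl$vaf)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
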