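## External aligner integration. The detection envelope is a property of the
## caller *given* a BWA-MEM-style soft-clipping, supplementary-emitting
## aligner; the aligner itself is invoked, never reimplemented. The command
## is a template with {reference}, {fastq1}, {fastq2} placeholders (the
## spelling {reference_fasta} is accepted too) and must write SAM to
## standard output.

#' Default aligner command template
#' @return The default command template string (`bwa mem` with default
#'   parameters).
#' @export
default_aligner <- function() "bwa mem {reference} {fastq1} {fastq2}"

fill_aligner_template <- function(template, reference, fastq1, fastq2) {
  cmd <- gsub("{reference_fasta}", reference, template, fixed = TRUE)
  cmd <- gsub("{reference}", reference, cmd, fixed = TRUE)
  cmd <- gsub("{fastq1}", fastq1, cmd, fixed = TRUE)
  gsub("{fastq2}", fastq2, cmd, fixed = TRUE)
}

#' Report the version of the external aligner
#'
#' @param program Aligner executable (default `"bwa"`).
#' @return Version string, or `NA` if it cannot be determined.
#' @export
aligner_version <- function(program = "bwa") {
  if (Sys.which(program) == "") return(NA_character_)
  out <- suppressWarnings(system2(program, stdout = TRUE, stderr = TRUE))
  v <- grep("^Version:", out, value = TRUE)
  if (!length(v)) return(NA_character_)
  sub("^Version:\\s*", "", v[1])
}

#' Index a reference FASTA for bwa
#'
#' @param reference Path to the reference FASTA.
#' @return `reference`, invisibly.
#' @export
bwa_index <- function(reference) {
  if (Sys.which("bwa") == "") stop("bwa executable not found on PATH")
  if (!file.exists(paste0(reference, ".bwt"))) {
    log <- system2("bwa", c("index", shQuote(reference)),
                   stdout = TRUE, stderr = TRUE)
    if (!file.exists(paste0(reference, ".bwt")))
      stop("bwa index failed:\n", paste(log, collapse = "\n"))
  }
  invisible(reference)
}

#' Align a FASTQ pair with the external aligner
#'
#' Runs the aligner command template, captures the SAM output, and converts
#' it to a sorted, indexed BAM. With the default template the reference is
#' bwa-indexed automatically if needed.
#'
#' @param fastq1,fastq2 FASTQ paths (mate 1 / mate 2).
#' @param reference Reference FASTA path.
#' @param aligner_command Command template; see [default_aligner()].
#' @param output Output BAM path (without or with `.bam` extension);
#'   default a temporary file.
#' @return Path to the sorted BAM file.
#' @export
align_read_pairs <- function(fastq1, fastq2, reference,
                             aligner_command = default_aligner(),
                             output = tempfile()) {
  stopifnot(file.exists(fastq1), file.exists(fastq2), file.exists(reference))
  if (startsWith(aligner_command, "bwa ")) bwa_index(reference)
  cmd <- fill_aligner_template(aligner_command, shQuote(reference),
                               shQuote(fastq1), shQuote(fastq2))
  sam <- tempfile(fileext = ".sam")
  errf <- tempfile(fileext = ".err")
  status <- system2("sh", c("-c", shQuote(cmd)), stdout = sam, stderr = errf)
  if (status != 0L)
    stop("aligner command failed (exit ", status, "): ", cmd, "\n",
         paste(readLines(errf, warn = FALSE), collapse = "\n"))
  dest <- sub("\\.bam$", "", output)
  bam <- Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(c(sam, errf))
  bam
}
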