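# Sequence I/O: FASTQ read pairs in, assembled transcripts (FASTA) out.

#' Construct a set of paired-end fragments
#'
#' @param fragment_id Character vector of unique fragment identifiers.
#' @param mate1,mate2 Character vectors of mate sequences over
#'   `{A,C,G,T,N}`.
#' @param stranded Logical; strand-specific library (mate1 on the
#'   transcript strand, mate2 on the opposite strand).
#' @return An object of class `read_pairs`.
#' @export
read_pairs <- function(fragment_id, mate1, mate2, stranded = TRUE) {
  stopifnot(length(fragment_id) == length(mate1),
            length(mate1) == length(mate2))
  if (anyDuplicated(fragment_id)) {
    stop("fragment identifiers must be unique within a dataset")
  }
  if (length(mate1)) {
    bad <- grepl("[^ACGTN]", mate1) | grepl("[^ACGTN]", mate2) |
      nchar(mate1) == 0L | nchar(mate2) == 0L
    if (any(bad)) {
      stop("mate sequences must be non-empty strings over {A,C,G,T,N}; ",
           "first offending fragment: ", fragment_id[which(bad)[1]])
    }
  }
  structure(
    list(fragment_id = as.character(fragment_id),
         mate1 = toupper(mate1), mate2 = toupper(mate2),
         stranded = isTRUE(stranded)),
    class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat("read_pairs:", length(x$fragment_id), "fragments |",
      if (x$stranded) "stranded" else "unstranded", "\n")
  invisible(x)
}

#' @export
length.read_pairs <- function(x) length(x$fragment_id)

#' Read paired-end FASTQ files
#'
#' Reads four-line FASTQ records either from two parallel files (mate1
#' file / mate2 file, records in the same order) or from a single
#' interleaved file (mates alternating). Quality strings are validated
#' (same length as the sequence) but discarded: downstream error handling
#' is k-mer-frequency based. Gzip-compressed files are handled
#' transparently.
#'
#' @param path FASTQ file with first mates (or the interleaved file).
#' @param paired_path FASTQ file with second mates; `NULL` when
#'   `interleaved = TRUE`.
#' @param interleaved Logical; single file with alternating mates.
#' @param stranded Logical flag recorded on the returned object.
#' @return A `read_pairs` object.
#' @export
read_fastq <- function(path, paired_path = NULL, interleaved = FALSE,
                       stranded = TRUE) {
  if (interleaved) {
    rec <- parse_fastq(path)
    if (length(rec$id) %% 2L != 0L) {
      stop("pairing error in ", path, ": odd number of records in ",
           "interleaved file")
    }
    odd <- seq(1L, length(rec$id), by = 2L)
    return(read_pairs(strip_mate_suffix(rec$id[odd]),
                      rec$seq[odd], rec$seq[odd + 1L], stranded))
  }
  if (is.null(paired_path)) {
    stop("paired_path is required unless interleaved = TRUE ",
         "(paired-end input is integral to contig extension)")
  }
  r1 <- parse_fastq(path)
  r2 <- parse_fastq(paired_path)
  if (length(r1$id) != length(r2$id)) {
    stop("pairing error: ", path, " has ", length(r1$id), " records but ",
         paired_path, " has ", length(r2$id))
  }
  read_pairs(strip_mate_suffix(r1$id), r1$seq, r2$seq, stranded)
}

strip_mate_suffix <- function(id) sub("/[12]$", "", id)

# Minimal validating FASTQ parser. Biostrings reads FASTQ but does not
# report the line number of a malformed record, which this pipeline
# promises in its error messages.
parse_fastq <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("format error in ", path, ": truncated record at line ",
         4L * (length(lines) %/% 4L) + 1L)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(list(id = character(0), seq = character(0)))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) {
    stop("format error in ", path, ": missing '@' at line ", 4L * (bad[1] - 1L) + 1L)
  }
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad)) {
    stop("format error in ", path, ": missing '+' at line ", 4L * (bad[1] - 1L) + 3L)
  }
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad)) {
    stop("format error in ", path, ": sequence/quality length mismatch at line ",
         4L * (bad[1] - 1L) + 4L)
  }
  list(id = sub("^@", "", sub("\\s.*$", "", hdr)), seq = seqs)
}

#' Write assembled transcripts to FASTA
#'
#' One record per transcript; the header encodes `transcript_id` plus
#' `graph=`, `abundance=` and `posterior=` key=value tokens; sequences are
#' wrapped at 60 columns.
#'
#' @param transcripts A data frame with columns `transcript_id`,
#'   `sequence`, `graph_id`, `abundance`, `posterior_expression` (as
#'   returned by [run_pipeline()] / [call_transcripts()]).
#' @param path Output FASTA path.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicate transcript_id values; refusing to write")
  }
  if (nrow(transcripts) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(transcripts$sequence)
  names(seqs) <- sprintf(
    "%s graph=%s abundance=%.6f posterior=%.4f",
    transcripts$transcript_id, transcripts$graph_id,
    transcripts$abundance, transcripts$posterior_expression)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a transcripts FASTA written by [write_transcripts_fasta()]
#'
#' @param path FASTA path.
#' @return Data frame with the same columns as the writer consumed.
#' @export
read_transcripts_fasta <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(transcript_id = character(0), sequence = character(0),
                      graph_id = character(0), abundance = numeric(0),
                      posterior_expression = numeric(0)))
  }
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  token <- function(key) sub(paste0(".*", key, "=(\\S+).*"), "\\1", hdr)
  data.frame(
    transcript_id = sub("\\s.*$", "", hdr),
    sequence = as.character(ss),
    graph_id = token("graph"),
    abundance = as.numeric(token("abundance")),
    posterior_expression = as.numeric(token("posterior")),
    row.names = NULL)
}
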