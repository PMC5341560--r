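# FASTA / FASTQ input and output.
#
# Sequence sets are plain tibbles with columns:
#   id     -- unique identifier (first whitespace-delimited token of header)
#   seq    -- uppercase nucleotide string over {A,C,G,T,N}
#   length -- nchar(seq)
#   role   -- one of "long_read", "contig", "short_read"

SEQ_ROLES <- c("long_read", "contig", "short_read")

#' Build a sequence tibble from a character vector
#'
#' @param seqs named character vector of nucleotide sequences (names become
#'   ids) or an unnamed vector together with `ids`.
#' @param role sequence role: `"long_read"`, `"contig"` or `"short_read"`.
#' @param ids optional character vector of ids overriding `names(seqs)`.
#' @return a tibble with columns `id`, `seq`, `length`, `role`.
#' @export
as_seq_tbl <- function(seqs, role = "long_read", ids = names(seqs)) {
  role <- match.arg(role, SEQ_ROLES)
  if (length(seqs) == 0) {
    return(tibble::tibble(id = character(0), seq = character(0),
                          length = integer(0), role = character(0)))
  }
  abort_if(is.null(ids), "sequence ids are required")
  abort_if(anyDuplicated(ids) > 0, "duplicate sequence id: %s",
           ids[duplicated(ids)][1])
  seqs <- toupper(unname(seqs))
  abort_if(any(nchar(seqs) == 0), "empty sequence for id %s",
           ids[nchar(seqs) == 0][1])
  bad <- grepl("[^ACGTN]", seqs)
  abort_if(any(bad), "non-ACGTN characters in sequence %s", ids[bad][1])
  tibble::tibble(id = as.character(ids), seq = seqs,
                 length = nchar(seqs), role = role)
}

#' Read a FASTA file into a sequence tibble
#'
#' Multi-line records are joined, sequences are uppercased, and record order
#' is preserved.  Duplicated ids and empty sequences are format errors.
#'
#' @param path path to a FASTA file.
#' @param role role to assign to every record (see [as_seq_tbl()]).
#' @return a sequence tibble.
#' @export
read_fasta <- function(path, role = "long_read") {
  abort_if(!file.exists(path), "file not found: %s", path)
  first <- readLines(path, n = 1L)
  abort_if(length(first) == 1L && !startsWith(first, ">"),
           "not FASTA: %s does not start with '>'", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  as_seq_tbl(setNames(as.character(ss), ids), role = role)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs a sequence tibble (see [as_seq_tbl()]).
#' @param path output path.
#' @param width line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  role <- if (nrow(seqs) > 0) seqs$role[1] else "long_read"
  seqs <- as_seq_tbl(seqs$seq, role = role,
                     ids = seqs$id)  # re-validate before serialising
  con <- file(path, "wb")  # LF line endings everywhere
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$seq[i]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a sequence tibble
#'
#' Qualities are discarded; the pipeline consumes sequence content only.
#'
#' @inheritParams read_fasta
#' @return a sequence tibble.
#' @export
read_fastq <- function(path, role = "short_read") {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(ss))
  as_seq_tbl(setNames(as.character(ss), ids), role = role)
}

#' Write a sequence tibble to FASTQ with placeholder qualities
#'
#' @inheritParams write_fasta
#' @param qual constant Phred character used for every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, qual = "I") {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(c(paste0("@", seqs$id[i]), seqs$seq[i], "+",
                 strrep(qual, nchar(seqs$seq[i]))), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
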