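# PSL (BLAT dialect) parsing and writing.
#
# 21 tab-separated columns:
#   matches misMatches repMatches nCount qNumInsert qBaseInsert tNumInsert
#   tBaseInsert strand qName qSize qStart qEnd tName tSize tStart tEnd
#   blockCount blockSizes qStarts tStarts
#
# On read, repMatches is folded into matches and nCount into mismatches
# (identity here never distinguishes repeat matches, and aligned Ns score
# as mismatches), which keeps sum(blockSizes) == matches + mismatches.
# qStart/qEnd in the file are plus-strand coordinates; the internal model
# keeps query coordinates in the alignment frame (see alignments.R), so for
# minus-strand records they are converted on read and back on write.

PSL_HEADER_TOKEN <- "psLayout"

parse_int_list <- function(x, line) {
  v <- suppressWarnings(as.integer(strsplit(sub(",$", "", x), ",")[[1]]))
  abort_if(anyNA(v), "PSL line %d: malformed comma list '%s'", line, x)
  v
}

#' Parse a PSL alignment file
#'
#' Accepts the optional 5-line `psLayout` header (auto-detected unless
#' `has_header` is given).  Every record is validated against the alignment
#' model invariants; violations are format errors naming the invariant and
#' line.
#'
#' @param path path to a 21-column PSL file.
#' @param has_header logical or `NULL` (auto-detect).
#' @return an alignment tibble.
#' @export
read_psl <- function(path, has_header = NULL) {
  lines <- readLines(path)
  if (is.null(has_header)) {
    has_header <- length(lines) > 0 && startsWith(lines[1], PSL_HEADER_TOKEN)
  }
  offset <- 0L
  if (isTRUE(has_header)) {
    abort_if(length(lines) < 5, "PSL header declared but file has < 5 lines")
    offset <- 5L
    lines <- lines[-(1:5)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_alignments())

  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    lineno <- i + offset
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    abort_if(length(f) != 21,
             "PSL line %d: expected 21 columns, found %d", lineno, length(f))
    num <- suppressWarnings(as.integer(f[c(1:8, 11:13, 15:18)]))
    abort_if(anyNA(num), "PSL line %d: non-integer numeric field", lineno)
    strand <- f[9]
    abort_if(!strand %in% c("+", "-"),
             "PSL line %d: invariant 'strand in {+,-}' violated", lineno)
    sizes <- parse_int_list(f[19], lineno)
    qs <- parse_int_list(f[20], lineno)
    ts <- parse_int_list(f[21], lineno)
    abort_if(length(sizes) != num[15] || length(qs) != num[15] ||
               length(ts) != num[15],
             "PSL line %d: blockCount disagrees with block lists", lineno)
    q_size <- num[9]
    # file qStart/qEnd are plus-strand; internal frame follows qStarts
    q_start <- if (strand == "+") num[10] else q_size - num[11]
    q_end <- if (strand == "+") num[11] else q_size - num[10]
    rows[[i]] <- tibble::tibble(
      query_id = f[10], target_id = f[14], strand = strand,
      matches = num[1] + num[3], mismatches = num[2] + num[4],
      q_num_insert = num[5], q_base_insert = num[6],
      t_num_insert = num[7], t_base_insert = num[8],
      q_size = q_size, q_start = q_start, q_end = q_end,
      t_size = num[12], t_start = num[13], t_end = num[14],
      blocks = list(block_tbl(sizes, qs, ts))
    )
  }
  out <- dplyr::bind_rows(rows)
  validate_alignments(out)
  out
}

#' Write an alignment tibble to PSL
#'
#' Records are validated first; invalid records refuse to serialise.
#' `repMatches` and `nCount` are written as 0 (folded on read).
#'
#' @param aln an alignment tibble.
#' @param path output path.
#' @param header write the 5-line psLayout header?
#' @return `path`, invisibly.
#' @export
write_psl <- function(aln, path, header = FALSE) {
  validate_alignments(aln)
  con <- file(path, "wb")
  on.exit(close(con))
  if (header) {
    writeLines(c(
      "psLayout version 3",
      "",
      "match\tmis- \trep. \tN's\tQ gap\tQ gap\tT gap\tT gap\tstrand\tQ        \tQ   \tQ    \tQ  \tT        \tT   \tT    \tT  \tblock\tblockSizes \tqStarts\t tStarts",
      "     \tmatch\tmatch\t   \tcount\tbases\tcount\tbases\t      \tname     \tsize\tstart\tend\tname     \tsize\tstart\tend\tcount",
      strrep("-", 120)), con)
  }
  for (i in seq_len(nrow(aln))) {
    r <- aln[i, ]
    b <- r$blocks[[1]]
    q_start_file <- if (r$strand == "+") r$q_start else r$q_size - r$q_end
    q_end_file <- if (r$strand == "+") r$q_end else r$q_size - r$q_start
    writeLines(paste(
      r$matches, r$mismatches, 0L, 0L,
      r$q_num_insert, r$q_base_insert, r$t_num_insert, r$t_base_insert,
      r$strand, r$query_id, r$q_size, q_start_file, q_end_file,
      r$target_id, r$t_size, r$t_start, r$t_end,
      nrow(b),
      paste0(paste(b$size, collapse = ","), ","),
      paste0(paste(b$q_start, collapse = ","), ","),
      paste0(paste(b$t_start, collapse = ","), ","),
      sep = "\t"), con)
  }
  invisible(path)
}
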