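# PAF parsing and writing (cg:Z CIGAR tag required).
#
# The 12 mandatory columns plus tags.  Blocks are reconstructed from the
# CIGAR: M/=/X runs advance both sequences (each maximal run of them is one
# block), I runs advance the query only, D/N runs the target only.  The
# CIGAR is stored in the alignment frame (target-forward), matching the
# internal block representation; qstart/qend in the file are plus-strand
# and converted exactly as for PSL.

cigar_ops <- function(cg) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
  abort_if(m[1] == -1 || sum(attr(m, "match.length")) != nchar(cg),
           "malformed CIGAR '%s'", cg)
  toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
  tibble::tibble(len = as.integer(sub(".$", "", toks)),
                 op = sub("^\\d+", "", toks))
}

cigar_to_blocks <- function(cg) {
  ops <- cigar_ops(cg)
  abort_if(any(ops$op %in% c("S", "H", "P")),
           "clipped/padded CIGAR ops not supported in PAF records")
  # merge adjacent aligned runs (M/=/X) into one block
  aligned <- ops$op %in% c("M", "=", "X")
  q <- 0L; t <- 0L
  size <- integer(0); qs <- integer(0); ts <- integer(0)
  i <- 1L
  while (i <= nrow(ops)) {
    if (aligned[i]) {
      j <- i
      while (j < nrow(ops) && aligned[j + 1L]) j <- j + 1L
      blk <- sum(ops$len[i:j])
      size <- c(size, blk); qs <- c(qs, q); ts <- c(ts, t)
      q <- q + blk; t <- t + blk
      i <- j + 1L
    } else if (ops$op[i] == "I") {
      q <- q + ops$len[i]; i <- i + 1L
    } else {  # D or N
      t <- t + ops$len[i]; i <- i + 1L
    }
  }
  list(blocks = block_tbl(size, qs, ts),
       q_len = q, t_len = t,
       q_num = sum(ops$op == "I"), q_base = sum(ops$len[ops$op == "I"]),
       t_num = sum(ops$op %in% c("D", "N")),
       t_base = sum(ops$len[ops$op %in% c("D", "N")]))
}

#' Parse a PAF alignment file
#'
#' Requires the `cg:Z` CIGAR tag on every line (blocks cannot be
#' reconstructed without it); its absence is an unsupported-input error.
#' Matches are taken from the residue-match column; mismatches are the
#' aligned bases (CIGAR M/=/X) minus matches.
#'
#' @param path path to a PAF file.
#' @return an alignment tibble.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_alignments())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    abort_if(length(f) < 12, "PAF line %d: fewer than 12 columns", i)
    tags <- f[-(1:12)]
    cg <- tags[startsWith(tags, "cg:Z:")]
    abort_if(length(cg) != 1,
             "PAF line %d: cg:Z CIGAR tag required to reconstruct blocks", i)
    parts <- cigar_to_blocks(sub("^cg:Z:", "", cg))
    strand <- f[5]
    q_size <- as.integer(f[2])
    q_start_file <- as.integer(f[3]); q_end_file <- as.integer(f[4])
    q_start <- if (strand == "+") q_start_file else q_size - q_end_file
    q_end <- if (strand == "+") q_end_file else q_size - q_start_file
    matches <- as.integer(f[10])
    aligned <- sum(parts$blocks$size)
    abort_if(matches > aligned,
             "PAF line %d: residue matches exceed aligned bases in CIGAR", i)
    b <- parts$blocks
    b$q_start <- b$q_start + q_start
    b$t_start <- b$t_start + as.integer(f[8])
    rows[[i]] <- tibble::tibble(
      query_id = f[1], target_id = f[6], strand = strand,
      matches = matches, mismatches = aligned - matches,
      q_num_insert = parts$q_num, q_base_insert = parts$q_base,
      t_num_insert = parts$t_num, t_base_insert = parts$t_base,
      q_size = q_size, q_start = q_start, q_end = q_end,
      t_size = as.integer(f[7]), t_start = as.integer(f[8]),
      t_end = as.integer(f[9]),
      blocks = list(b)
    )
  }
  out <- dplyr::bind_rows(rows)
  validate_alignments(out)
  out
}

blocks_to_cigar <- function(b) {
  ops <- character(0)
  for (i in seq_len(nrow(b))) {
    if (i > 1) {
      dq <- b$q_start[i] - (b$q_start[i - 1] + b$size[i - 1])
      dt <- b$t_start[i] - (b$t_start[i - 1] + b$size[i - 1])
      if (dq > 0) ops <- c(ops, paste0(dq, "I"))
      if (dt > 0) ops <- c(ops, paste0(dt, "D"))
    }
    ops <- c(ops, paste0(b$size[i], "M"))
  }
  paste(ops, collapse = "")
}

#' Write an alignment tibble to PAF with a cg:Z CIGAR tag
#'
#' @param aln an alignment tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  validate_alignments(aln)
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    r <- aln[i, ]
    b <- r$blocks[[1]]
    b0 <- b
    b0$q_start <- b0$q_start - r$q_start
    b0$t_start <- b0$t_start - r$t_start
    q_start_file <- if (r$strand == "+") r$q_start else r$q_size - r$q_end
    q_end_file <- if (r$strand == "+") r$q_end else r$q_size - r$q_start
    nm <- r$mismatches + r$q_base_insert + r$t_base_insert
    writeLines(paste(
      r$query_id, r$q_size, q_start_file, q_end_file, r$strand,
      r$target_id, r$t_size, r$t_start, r$t_end,
      r$matches, sum(b$size) + r$q_base_insert + r$t_base_insert, 255,
      paste0("NM:i:", nm), paste0("cg:Z:", blocks_to_cigar(b0)),
      sep = "\t"), con)
  }
  invisible(path)
}

#' Convert between PSL and PAF alignment files
#'
#' Format is inferred from the file extensions (`.psl` / `.paf`).
#'
#' @param infile input alignment file.
#' @param outfile output alignment file.
#' @return `outfile`, invisibly.
#' @export
convert_alignments <- function(infile, outfile) {
  ext <- function(p) tolower(sub("^.*\\.", "", p))
  aln <- switch(ext(infile),
                psl = read_psl(infile),
                paf = read_paf(infile),
                stop("unsupported input extension: ", infile))
  switch(ext(outfile),
         psl = write_psl(aln, outfile),
         paf = write_paf(aln, outfile),
         stop("unsupported output extension: ", outfile))
  invisible(outfile)
}
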