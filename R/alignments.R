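# The block-structured alignment model every stage consumes.
#
# Alignments are tibbles with one row per pairwise alignment:
#   query_id, target_id  -- sequence ids
#   strand               -- "+" or "-"
#   matches, mismatches  -- identical / differing aligned bases (N counts
#                           as mismatch)
#   q_num_insert, q_base_insert -- gap openings / gapped bases on the query
#                           side (query bases absent from the target)
#   t_num_insert, t_base_insert -- ditto on the target side
#   q_size, q_start, q_end -- query length and aligned span
#   t_size, t_start, t_end -- target length and aligned span
#   blocks               -- list-column of tibbles (size, q_start, t_start)
#
# Coordinates are 0-based half-open.  For minus-strand alignments the query
# coordinates (q_start/q_end and block q_start) are expressed on the
# reverse-complemented query -- the frame in which the alignment was made
# and the frame PSL's qStarts column uses -- so that blocks are strictly
# increasing in both query and target for every record.

ALN_COLS <- c("query_id", "target_id", "strand", "matches", "mismatches",
              "q_num_insert", "q_base_insert", "t_num_insert",
              "t_base_insert", "q_size", "q_start", "q_end",
              "t_size", "t_start", "t_end", "blocks")

#' Construct an empty alignment tibble
#'
#' @return a zero-row tibble with the alignment columns.
#' @export
empty_alignments <- function() {
  tibble::tibble(
    query_id = character(0), target_id = character(0), strand = character(0),
    matches = integer(0), mismatches = integer(0),
    q_num_insert = integer(0), q_base_insert = integer(0),
    t_num_insert = integer(0), t_base_insert = integer(0),
    q_size = integer(0), q_start = integer(0), q_end = integer(0),
    t_size = integer(0), t_start = integer(0), t_end = integer(0),
    blocks = list()
  )
}

block_tbl <- function(size, q_start, t_start) {
  tibble::tibble(size = as.integer(size), q_start = as.integer(q_start),
                 t_start = as.integer(t_start))
}

#' Validate an alignment tibble against the model invariants
#'
#' Checks, for every record: blocks sorted and non-overlapping in both
#' coordinates; block sizes summing to `matches + mismatches`; aligned spans
#' consistent with block sizes plus gapped bases; coordinates within
#' `[0, size]`.  The first violated invariant is reported by name.
#'
#' @param aln an alignment tibble.
#' @return `aln`, invisibly, if all invariants hold.
#' @export
validate_alignments <- function(aln) {
  abort_if(!all(ALN_COLS %in% names(aln)),
           "missing alignment columns: %s",
           paste(setdiff(ALN_COLS, names(aln)), collapse = ", "))
  for (i in seq_len(nrow(aln))) {
    r <- aln[i, ]
    b <- r$blocks[[1]]
    who <- sprintf("alignment %s -> %s (row %d)", r$query_id, r$target_id, i)
    abort_if(nrow(b) < 1, "%s: invariant 'at least one block' violated", who)
    q_ends <- b$q_start + b$size
    t_ends <- b$t_start + b$size
    abort_if(nrow(b) > 1 &&
               (any(diff(b$q_start) <= 0) || any(diff(b$t_start) <= 0) ||
                any(b$q_start[-1] < q_ends[-nrow(b)]) ||
                any(b$t_start[-1] < t_ends[-nrow(b)])),
             "%s: invariant 'blocks sorted, non-overlapping, strictly increasing' violated",
             who)
    abort_if(sum(b$size) != r$matches + r$mismatches,
             "%s: invariant 'sum(block_size) == matches + mismatches' violated",
             who)
    abort_if(r$q_end - r$q_start != sum(b$size) + r$q_base_insert,
             "%s: invariant 'q span == blocks + q_base_insert' violated", who)
    abort_if(r$t_end - r$t_start != sum(b$size) + r$t_base_insert,
             "%s: invariant 't span == blocks + t_base_insert' violated", who)
    abort_if(!(r$q_start >= 0 && r$q_start < r$q_end && r$q_end <= r$q_size),
             "%s: invariant '0 <= q_start < q_end <= q_size' violated", who)
    abort_if(!(r$t_start >= 0 && r$t_start < r$t_end && r$t_end <= r$t_size),
             "%s: invariant '0 <= t_start < t_end <= t_size' violated", who)
    abort_if(b$q_start[1] != r$q_start || b$t_start[1] != r$t_start ||
               q_ends[nrow(b)] != r$q_end || t_ends[nrow(b)] != r$t_end,
             "%s: invariant 'blocks span q/t start..end' violated", who)
    abort_if(!r$strand %in% c("+", "-"),
             "%s: invariant 'strand in {+,-}' violated", who)
  }
  invisible(aln)
}
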