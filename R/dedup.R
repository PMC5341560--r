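# Redundancy removal among corrected long reads.
#
# A read B is a duplicate of a longer read A when B maps to A essentially
# end-to-end (no overhangs), at similarity above 0.99, with no gaps in the
# alignment.  Removing all such B yields the duplication-removed corrected
# long-read (DRCLR) set used as the downstream isoform library.

#' Duplicate-calling parameters
#'
#' @param min_similarity similarity (matches / contained-read length) that
#'   must be strictly exceeded; default 0.99.
#' @param max_overhang maximum unaligned bases allowed at either end of the
#'   contained read; the literal reading of "no overhangs" is 0.
#' @param max_gap_openings maximum gap openings (query- plus target-side)
#'   allowed in the containment alignment; the literal reading of "no gaps"
#'   is 0.
#' @param collapse_equal also remove exact duplicates of equal length
#'   (keeping the lexicographically smaller id).  The strict containment
#'   rule requires A strictly longer than B, so this is off by default.
#' @return a list of class `iso_dedup_params`.
#' @export
dedup_params <- function(min_similarity = 0.99, max_overhang = 0L,
                         max_gap_openings = 0L, collapse_equal = FALSE) {
  abort_if(min_similarity <= 0 || min_similarity > 1,
           "min_similarity must be in (0, 1]")
  abort_if(max_overhang < 0, "max_overhang must be >= 0")
  structure(list(min_similarity = min_similarity,
                 max_overhang = as.integer(max_overhang),
                 max_gap_openings = as.integer(max_gap_openings),
                 collapse_equal = collapse_equal),
            class = "iso_dedup_params")
}

#' Similarity of a read to its alignment target
#'
#' Identical aligned nucleotides over the full mapped-read length:
#' `matches / query_len`.
#'
#' @param aln a one-row alignment tibble (query = the mapped read).
#' @param query_len the read's length; must equal `aln$q_size`.
#' @return similarity in `[0, 1]`.
#' @export
similarity <- function(aln, query_len = aln$q_size) {
  abort_if(any(query_len != aln$q_size),
           "query_len (%s) disagrees with alignment q_size (%s)",
           query_len[1], aln$q_size[1])
  aln$matches / query_len
}

#' Is read B a duplicate of read A?
#'
#' All of the following must hold: A strictly longer than B; B's unaligned
#' overhangs within `max_overhang` on both ends; similarity strictly above
#' `min_similarity`; total gap openings within `max_gap_openings`.
#'
#' @param aln_b_to_a a one-row alignment tibble with query = B, target = A.
#' @param len_a,len_b read lengths (bp).
#' @param params a [dedup_params()] object.
#' @return logical.
#' @export
is_duplicate <- function(aln_b_to_a, len_a, len_b, params = dedup_params()) {
  r <- aln_b_to_a
  len_a > len_b &&
    r$q_start <= params$max_overhang &&
    (r$q_size - r$q_end) <= params$max_overhang &&
    similarity(r, len_b) > params$min_similarity &&
    (r$q_num_insert + r$t_num_insert) <= params$max_gap_openings
}

#' Remove duplicate long reads
#'
#' Reads are visited in decreasing length (ties broken by ascending id).  A
#' read is removed when [is_duplicate()] holds against any longer read that
#' was itself retained; the removal log records which retained read
#' absorbed it.  With `params$collapse_equal`, equal-length reads related
#' by a perfect gapless overhang-free alignment are additionally collapsed
#' onto the smaller id.
#'
#' @param reads a sequence tibble of corrected long reads.
#' @param alignments all-vs-all (or seed-filtered) alignments among
#'   `reads`; every referenced id must exist in `reads`.
#' @param params a [dedup_params()] object.
#' @return a list with `retained` (sequence tibble, the DRCLR set, input
#'   order preserved) and `log` (tibble: removed_id, kept_id, similarity,
#'   len_removed, len_kept).
#' @export
remove_duplicates <- function(reads, alignments, params = dedup_params()) {
  unknown <- setdiff(unique(c(alignments$query_id, alignments$target_id)),
                     reads$id)
  abort_if(length(unknown) > 0,
           "alignment references unknown read id: %s", unknown[1])
  len <- setNames(reads$length, reads$id)
  ord <- reads$id[order(-reads$length, reads$id)]
  # best alignment per (query, target) pair by matches
  aln <- dplyr::slice_max(
    dplyr::group_by(alignments, .data$query_id, .data$target_id),
    .data$matches, n = 1, with_ties = FALSE)
  aln <- dplyr::ungroup(aln)
  by_query <- split(seq_len(nrow(aln)), aln$query_id)

  retained <- character(0)
  retained_set <- new.env(parent = emptyenv())
  log_rows <- list()
  for (b in ord) {
    removed <- FALSE
    idx <- by_query[[b]]
    if (!is.null(idx)) {
      for (i in idx) {
        a <- aln$target_id[i]
        if (!is.null(retained_set[[a]])) {
          dup <- is_duplicate(aln[i, ], len[[a]], len[[b]], params) ||
            (isTRUE(params$collapse_equal) && len[[a]] == len[[b]] && a < b &&
               is_duplicate(aln[i, ], len[[a]] + 1L, len[[b]], params))
          if (dup) {
            log_rows[[length(log_rows) + 1]] <- tibble::tibble(
              removed_id = b, kept_id = a,
              similarity = similarity(aln[i, ], len[[b]]),
              len_removed = len[[b]], len_kept = len[[a]])
            removed <- TRUE
            break
          }
        }
      }
    }
    if (!removed) {
      retained <- c(retained, b)
      retained_set[[b]] <- TRUE
    }
  }
  list(retained = reads[reads$id %in% retained, ],
       log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
         tibble::tibble(removed_id = character(0), kept_id = character(0),
                        similarity = numeric(0), len_removed = integer(0),
                        len_kept = integer(0)))
}
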