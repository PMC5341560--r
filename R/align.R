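# Internal pairwise aligner: affine-gap, global in the query, local in the
# target, emitting block-structured alignment records.  A desk-scale
# stand-in for an external spliced aligner; real-data runs can supply PSL
# or PAF from BLAT/minimap2 at every downstream stage instead.

#' Alignment scoring parameters
#'
#' Defaults (+1 match, -2 mismatch, gap open 4, gap extend 0.25) make a
#' 50 bp gap cost 16.5 -- far cheaper than 50 mismatches -- so skipped
#' exons surface as gaps rather than noisy diagonals.
#'
#' @param match_score score for an identical aligned pair.
#' @param mismatch_penalty penalty (positive) for a mismatching pair; `N`
#'   scores as a mismatch.
#' @param gap_open gap opening cost (positive); a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param gap_extend per-base gap extension cost (positive).
#' @param min_seed_len k-mer length used to pre-filter target candidates in
#'   [align_all()]; must be >= 8.
#' @param free_query_ends if `TRUE`, unaligned query ends are unpenalised
#'   (for fragment-like queries); long reads are near-full-length, so the
#'   default is `FALSE`.
#' @param both_strands also try the reverse-complemented query and keep the
#'   better alignment.
#' @param banded restrict the dynamic programme to diagonals within
#'   `band_pad` of the shared-k-mer diagonal range (seed-and-extend).
#'   With no shared k-mer the pair is reported unaligned.  Set to `FALSE`
#'   for the exact full programme.
#' @param band_pad diagonal slack (bp) around the seed diagonals.
#' @param max_cells dynamic-programming budget in matrix cells; exceeding
#'   it is an error advising external alignment.
#' @return a list of class `iso_align_params`.
#' @export
align_params <- function(match_score = 1, mismatch_penalty = 2,
                         gap_open = 4, gap_extend = 0.25,
                         min_seed_len = 12L, free_query_ends = FALSE,
                         both_strands = TRUE, banded = TRUE,
                         band_pad = 120L, max_cells = 1e8) {
  abort_if(mismatch_penalty < 0 || gap_open < 0 || gap_extend < 0,
           "penalties must be >= 0")
  abort_if(min_seed_len < 8, "min_seed_len must be >= 8")
  structure(list(match_score = match_score,
                 mismatch_penalty = mismatch_penalty,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_seed_len = as.integer(min_seed_len),
                 free_query_ends = free_query_ends,
                 both_strands = both_strands, banded = banded,
                 band_pad = as.integer(band_pad), max_cells = max_cells),
            class = "iso_align_params")
}

align_one_strand <- function(qseq, tseq, params) {
  .align_affine(qseq, tseq, params$match_score, params$mismatch_penalty,
                params$gap_open, params$gap_extend,
                params$free_query_ends, params$max_cells,
                isTRUE(params$banded), params$band_pad,
                params$min_seed_len)
}

raw_to_row <- function(raw, query_id, target_id, strand, q_size, t_size) {
  tibble::tibble(
    query_id = query_id, target_id = target_id, strand = strand,
    matches = raw$matches, mismatches = raw$mismatches,
    q_num_insert = raw$q_num_insert, q_base_insert = raw$q_base_insert,
    t_num_insert = raw$t_num_insert, t_base_insert = raw$t_base_insert,
    q_size = q_size, q_start = raw$q_start, q_end = raw$q_end,
    t_size = t_size, t_start = raw$t_start, t_end = raw$t_end,
    blocks = list(block_tbl(raw$block_size, raw$block_q_start,
                            raw$block_t_start)),
    score = raw$score
  )
}

#' Align one query against one target
#'
#' Computes the optimal affine-gap alignment, global in the query (or with
#' free query ends) and local in the target.  Maximal runs of aligned
#' columns become blocks; gaps appear between blocks.  Both strands are
#' tried when `params$both_strands` is `TRUE`; for minus-strand hits the
#' query coordinates are reported in the alignment frame (on the
#' reverse-complemented query).
#'
#' @param query,target single rows of a sequence tibble (or any list with
#'   `id` and `seq`).
#' @param params an [align_params()] object.
#' @return a one-row alignment tibble with an extra `score` column, or
#'   `NULL` when no alignment scores above zero.
#' @export
align_pair <- function(query, target, params = align_params()) {
  abort_if(nchar(query$seq[1]) == 0 || nchar(target$seq[1]) == 0,
           "empty sequence")
  qseq <- query$seq[1]; tseq <- target$seq[1]
  fwd <- align_one_strand(qseq, tseq, params)
  rev <- if (isTRUE(params$both_strands)) {
    align_one_strand(revcomp(qseq), tseq, params)
  }
  pick_fwd <- !is.null(fwd) && (is.null(rev) || fwd$score >= rev$score)
  if (pick_fwd) {
    raw_to_row(fwd, query$id[1], target$id[1], "+",
               nchar(qseq), nchar(tseq))
  } else if (!is.null(rev)) {
    raw_to_row(rev, query$id[1], target$id[1], "-",
               nchar(qseq), nchar(tseq))
  } else {
    NULL
  }
}

# k-mer candidate pairs: queries x targets sharing at least one seed
seed_candidates <- function(queries, targets, k, both_strands) {
  t_idx <- tibble::tibble(
    target_id = rep(targets$id, vapply(targets$seq, function(s)
      max(0L, nchar(s) - k + 1L), integer(1))),
    kmer = unlist(lapply(targets$seq, seq_kmers, k = k), use.names = FALSE)
  )
  t_idx <- dplyr::distinct(t_idx)
  q_seqs <- queries$seq
  if (both_strands) q_seqs <- paste0(q_seqs, "N", revcomp(queries$seq))
  q_idx <- tibble::tibble(
    query_id = rep(queries$id, vapply(q_seqs, function(s)
      max(0L, nchar(s) - k + 1L), integer(1))),
    kmer = unlist(lapply(q_seqs, seq_kmers, k = k), use.names = FALSE)
  )
  q_idx <- dplyr::filter(dplyr::distinct(q_idx), !grepl("N", .data$kmer))
  dplyr::distinct(dplyr::inner_join(q_idx, t_idx, by = "kmer",
                                    relationship = "many-to-many")[,
                  c("query_id", "target_id")])
}

#' Align every query against candidate targets
#'
#' Targets sharing at least one seed k-mer with a query are aligned to it;
#' alignments with identity (`matches / q_size`) below `min_identity` are
#' dropped.  Output order is deterministic (query id, then target id).
#'
#' @param queries,targets sequence tibbles.
#' @param params an [align_params()] object.
#' @param min_identity minimum `matches / query length` to keep.
#' @param exclude_self drop query/target pairs with identical ids (for
#'   all-vs-all runs of one library against itself).
#' @return an alignment tibble with a `score` column.
#' @export
align_all <- function(queries, targets, params = align_params(),
                      min_identity = 0, exclude_self = TRUE) {
  abort_if(nrow(queries) == 0 || nrow(targets) == 0, "empty library")
  cand <- seed_candidates(queries, targets, params$min_seed_len,
                          isTRUE(params$both_strands))
  if (exclude_self) cand <- dplyr::filter(cand, .data$query_id != .data$target_id)
  if (nrow(cand) == 0) return(empty_alignments())
  cand <- dplyr::arrange(cand, .data$query_id, .data$target_id)
  qmap <- setNames(seq_len(nrow(queries)), queries$id)
  tmap <- setNames(seq_len(nrow(targets)), targets$id)
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    qr <- queries[qmap[[cand$query_id[i]]], ]
    tr <- targets[tmap[[cand$target_id[i]]], ]
    hit <- align_pair(qr, tr, params)
    if (!is.null(hit) && hit$matches / hit$q_size >= min_identity) {
      rows[[i]] <- hit
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty_alignments())
  dplyr::arrange(out, .data$query_id, .data$target_id)
}

#' Identity of an alignment record
#'
#' The fraction of identically aligned nucleotides over the full query
#' (mapped isoform) length: `matches / q_size`.
#'
#' @param aln an alignment tibble.
#' @return numeric vector of identities in `[0, 1]`.
#' @export
alignment_identity <- function(aln) {
  aln$matches / aln$q_size
}
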