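# Alternative-splicing detection from alignment gaps.
#
# A splice is an alignment gap longer than `min_gap` (default 50 bp,
# strictly greater) between a long read and its gene's longest contig.
# Target-side gaps (contig bases the read skips) are "exclusion" events --
# skipped exons or exon parts; query-side gaps (read bases absent from the
# contig) are "insertion" events.  The ordered set of a read's events is
# its splice signature; distinct signatures (different gap sites or
# lengths) define distinct isoform classes.

#' Extract splice events from alignments
#'
#' For each pair of adjacent blocks, emits an exclusion event when the
#' target-side jump exceeds `min_gap` and an insertion event when the
#' query-side jump exceeds `min_gap` (both strictly; a gap of exactly
#' `min_gap` bp is not a splice).
#'
#' Spurious micro-matches inside a long gap (a handful of bases of an
#' error-bearing read coinciding with gap-interior sequence) would split
#' one splice gap into two; internal blocks shorter than `min_block` are
#' therefore dropped before gaps are measured, merging the flanking gaps.
#'
#' @param aln an alignment tibble (typically reads vs the longest contig).
#' @param min_gap minimum gap length in bp, exclusive.
#' @param min_block internal alignment blocks shorter than this are
#'   treated as alignment noise (0 disables).
#' @return a tibble with one row per event: `query_id`, `target_id`,
#'   `kind` (`"exclusion"`/`"insertion"`), `t_start`, `t_end` (contig
#'   coordinates; equal at the anchor for insertions), `length`.
#' @export
extract_gaps <- function(aln, min_gap = 50L, min_block = 10L) {
  rows <- purrr::pmap(
    list(aln$query_id, aln$target_id, aln$blocks),
    function(qid, tid, b) {
      while (nrow(b) >= 3 && min_block > 0) {
        dq <- b$q_start[-1] - (b$q_start[-nrow(b)] + b$size[-nrow(b)])
        dt <- b$t_start[-1] - (b$t_start[-nrow(b)] + b$size[-nrow(b)])
        jump <- pmax(dq, dt)
        # a micro-island: tiny block sitting between two real gaps (a
        # block merely chipped off a junction by a 1 bp indel is kept)
        island <- which(b$size[-c(1, nrow(b))] < min_block &
                          jump[-length(jump)] >= min_block &
                          jump[-1] >= min_block)
        if (length(island) == 0) break
        b <- b[-(island[1] + 1L), , drop = FALSE]
      }
      if (nrow(b) < 2) return(NULL)
      q_ends <- b$q_start + b$size
      t_ends <- b$t_start + b$size
      dq <- b$q_start[-1] - q_ends[-nrow(b)]
      dt <- b$t_start[-1] - t_ends[-nrow(b)]
      out <- list()
      excl <- which(dt > min_gap)
      if (length(excl)) {
        out$excl <- tibble::tibble(
          query_id = qid, target_id = tid, kind = "exclusion",
          t_start = t_ends[excl], t_end = b$t_start[excl + 1],
          length = dt[excl])
      }
      ins <- which(dq > min_gap)
      if (length(ins)) {
        out$ins <- tibble::tibble(
          query_id = qid, target_id = tid, kind = "insertion",
          t_start = t_ends[ins], t_end = t_ends[ins],
          length = dq[ins])
      }
      if (length(out)) dplyr::bind_rows(out) else NULL
    })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(query_id = character(0), target_id = character(0),
                          kind = character(0), t_start = integer(0),
                          t_end = integer(0), length = integer(0)))
  }
  dplyr::arrange(out, .data$query_id, .data$t_start)
}

# Snap coordinates within `round_bp` of each other to the modal value of
# their run (ties -> smallest), for clustering signatures from error-
# bearing reads.  round_bp = 0 is the identity map.
snap_coords <- function(x, round_bp) {
  if (length(x) == 0 || round_bp <= 0) return(x)
  ux <- sort(unique(x))
  grp <- cumsum(c(1, diff(ux) > round_bp))
  snapped <- vapply(split(ux, grp), function(vals) {
    counts <- table(factor(x[x %in% vals], levels = vals))
    as.numeric(names(counts)[which.max(counts)])
  }, numeric(1))
  map <- setNames(snapped[grp], ux)
  unname(map[as.character(x)])
}

event_key <- function(kind, t_start, t_end, length) {
  ifelse(kind == "exclusion",
         sprintf("excl:%d-%d", as.integer(t_start), as.integer(t_end)),
         sprintf("ins:%d+%d", as.integer(t_start), as.integer(length)))
}

#' Canonical splice signatures per read
#'
#' Events are (optionally) coordinate-snapped per target within `round_bp`
#' and concatenated in target order into one canonical signature string per
#' read; the empty string is the gapless (all-exon-compatible) class.
#'
#' @param aln alignments of reads to their gene's longest contig.
#' @param min_gap,min_block see [extract_gaps()].
#' @param round_bp coordinate tolerance for merging gap endpoints from
#'   error-bearing reads (0 = exact).
#' @return a tibble: `query_id`, `target_id`, `signature`, `n_events`.
#' @export
splice_signature <- function(aln, min_gap = 50L, round_bp = 0L,
                             min_block = 10L) {
  ev <- extract_gaps(aln, min_gap, min_block)
  if (nrow(ev) > 0 && round_bp > 0) {
    ev <- dplyr::group_by(ev, .data$target_id)
    ev <- dplyr::mutate(ev,
                        t_start = snap_coords(.data$t_start, round_bp),
                        t_end = snap_coords(.data$t_end, round_bp),
                        length = .data$t_end - .data$t_start)
    ev <- dplyr::ungroup(ev)
    ins <- ev$kind == "insertion"
    ev$length[ins] <- snap_coords(ev$length[ins], round_bp)
    ev$t_end[ins] <- ev$t_start[ins]
  }
  sig <- dplyr::summarise(
    dplyr::group_by(ev, .data$query_id, .data$target_id),
    signature = paste(event_key(.data$kind, .data$t_start, .data$t_end,
                                .data$length)[order(.data$t_start,
                                                    .data$kind)],
                      collapse = ";"),
    n_events = dplyr::n(), .groups = "drop")
  all_pairs <- dplyr::distinct(aln[, c("query_id", "target_id")])
  out <- dplyr::left_join(all_pairs, sig, by = c("query_id", "target_id"))
  out$signature[is.na(out$signature)] <- ""
  out$n_events[is.na(out$n_events)] <- 0L
  dplyr::arrange(out, .data$query_id)
}

#' Catalogue isoform classes per gene
#'
#' Groups qualifying read alignments against each gene's longest contig by
#' canonical signature.  Reads belonging to a gene but failing to align to
#' its longest contig at qualifying identity are excluded and reported in
#' `attr(, "diagnostics")`.
#'
#' @param groups output of [select_longest_contig()].
#' @param reference output of [build_reference()].
#' @param alignments alignments of long reads to contigs (alignments whose
#'   target is a gene's longest contig are used).
#' @param min_gap,round_bp,min_block see [splice_signature()].
#' @param min_identity qualifying identity for read-to-reference
#'   alignments.
#' @return a tibble of class `iso_catalog`: one row per (gene, signature)
#'   with `gene_id`, `contig_id`, `signature`, `n_events`, `support`
#'   (number of reads) and `read_ids` (list-column).
#' @export
catalog_splicing <- function(groups, reference, alignments,
                             min_gap = 50L, round_bp = 5L,
                             min_identity = 0.99, min_block = 10L) {
  aln <- best_per_pair(alignments)
  aln <- aln[qualifies(aln, min_identity), ]
  gene_of_contig <- setNames(reference$gene_id, reference$contig_id)
  reads_of_gene <- setNames(groups$read_ids, groups$gene_id)
  rows <- list()
  dropped <- list()
  for (g in seq_len(nrow(reference))) {
    gene <- reference$gene_id[g]
    contig <- reference$contig_id[g]
    gene_reads <- reads_of_gene[[gene]] %||% character(0)
    sub <- aln[aln$target_id == contig & aln$query_id %in% gene_reads, ]
    lost <- setdiff(gene_reads, sub$query_id)
    if (length(lost)) {
      dropped[[gene]] <- tibble::tibble(gene_id = gene, read_id = lost)
    }
    if (nrow(sub) == 0) next
    sig <- splice_signature(sub, min_gap = min_gap, round_bp = round_bp,
                            min_block = min_block)
    cls <- dplyr::summarise(
      dplyr::group_by(sig, .data$signature),
      n_events = .data$n_events[1],
      support = dplyr::n(),
      read_ids = list(sort(.data$query_id)), .groups = "drop")
    cls <- dplyr::mutate(cls, gene_id = gene, contig_id = contig,
                         .before = 1)
    rows[[gene]] <- cls
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene_id = character(0), contig_id = character(0),
                          signature = character(0), n_events = integer(0),
                          support = integer(0), read_ids = list())
  }
  out <- dplyr::arrange(out, .data$gene_id, .data$signature)
  attr(out, "diagnostics") <- dplyr::bind_rows(dropped)
  class(out) <- c("iso_catalog", class(out))
  out
}

#' Summarise an isoform catalogue
#'
#' @param catalog output of [catalog_splicing()].
#' @return a list of class `iso_catalog_summary`: `histogram` (tibble:
#'   n_isoforms, n_genes), `gene_lists` (genes with >= 2, 3, 4 classes),
#'   `n_genes`, and `n_isoforms_excluding_gapless` per gene.
#' @export
summarize_catalog <- function(catalog) {
  per_gene <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(catalog), .data$gene_id),
    n_isoforms = dplyr::n(),
    n_isoforms_nongapless = sum(.data$signature != ""), .groups = "drop")
  hist <- dplyr::count(per_gene, .data$n_isoforms, name = "n_genes")
  gene_lists <- lapply(c(2, 3, 4), function(k)
    sort(per_gene$gene_id[per_gene$n_isoforms >= k]))
  names(gene_lists) <- c("ge2", "ge3", "ge4")
  structure(list(histogram = hist, per_gene = per_gene,
                 gene_lists = gene_lists, n_genes = nrow(per_gene)),
            class = "iso_catalog_summary")
}

#' @export
print.iso_catalog_summary <- function(x, ...) {
  cat(sprintf("Isoform catalogue over %d genes\n", x$n_genes))
  print(x$histogram)
  cat(sprintf("  genes with >= 2 classes: %d; >= 3: %d; >= 4: %d\n",
              length(x$gene_lists$ge2), length(x$gene_lists$ge3),
              length(x$gene_lists$ge4)))
  invisible(x)
}

#' Verify exclusion junctions against merged short-read fragments
#'
#' For each exclusion event, builds the junction sequence (`flank` bp left
#' of the gap start joined to `flank` bp right of the gap end on the
#' longest contig) and counts fragments containing it, exactly or with up
#' to `max_mismatch` mismatches.
#'
#' @param events an event tibble as produced by [extract_gaps()] (or a
#'   catalogue expanded to events) with `target_id` naming reference
#'   contigs via their `contig_id`.
#' @param reference output of [build_reference()].
#' @param fragments sequence tibble of merged fragments.
#' @param flank flank length in bp on each side of the junction.
#' @param max_mismatch mismatches tolerated over the whole junction probe.
#' @return `events` with `support` (fragment count) and `verified` added.
#' @export
verify_junctions <- function(events, reference, fragments, flank = 25L,
                             max_mismatch = 0L) {
  events <- events[events$kind == "exclusion", ]
  cseq <- setNames(reference$seq, reference$contig_id)
  frag_set <- Biostrings::DNAStringSet(fragments$seq)
  support <- integer(nrow(events))
  for (i in seq_len(nrow(events))) {
    s <- cseq[[events$target_id[i]]]
    left_from <- max(1L, events$t_start[i] - flank + 1L)
    right_to <- min(nchar(s), events$t_end[i] + flank)
    if (left_from > events$t_start[i] || right_to <= events$t_end[i]) {
      warning("flank truncated at contig bounds for event ",
              events$target_id[i], ":", events$t_start[i])
    }
    probe <- paste0(substr(s, left_from, events$t_start[i]),
                    substr(s, events$t_end[i] + 1L, right_to))
    n <- sum(Biostrings::vcountPattern(probe, frag_set,
                                       max.mismatch = max_mismatch) > 0)
    support[i] <- n
  }
  events$support <- support
  events$verified <- support >= 1L
  events
}
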