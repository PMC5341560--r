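# Gene grouping and per-gene longest-contig reference selection.
#
# Long reads (the true expressed isoforms) and assembled contigs (true and
# false candidate isoforms) are grouped into genes; within each gene the
# reference is the longest contig that (A) is at least as long as every
# mapped long read of the gene and (B) is mapped by at least one long read
# at high identity (>= 99% by default).  That contig is taken to carry the
# gene's full exon complement and becomes the splice-detection reference.

#' Does an alignment qualify as a high-identity mapping?
#'
#' @param aln an alignment tibble (query = long read, target = contig).
#' @param min_identity identity threshold; the boundary is included
#'   (`>=`).
#' @return logical vector.
#' @export
qualifies <- function(aln, min_identity = 0.99) {
  alignment_identity(aln) >= min_identity
}

# best qualifying alignment per (read, contig) pair
best_per_pair <- function(alignments) {
  if (nrow(alignments) == 0) return(alignments)
  aln <- dplyr::group_by(alignments, .data$query_id, .data$target_id)
  dplyr::ungroup(dplyr::slice_max(aln, .data$matches, n = 1,
                                  with_ties = FALSE))
}

trinity_gene_prefix <- function(contig_id) {
  sub("_i\\d+$", "", contig_id)
}

#' Group long reads and contigs into genes
#'
#' In `components` mode genes are the connected components of the
#' bipartite graph whose edges are qualifying read-to-contig alignments;
#' contigs (or reads) touching no qualifying alignment form singleton
#' groups, reported as unmapped.  In `trinity_names` mode contigs sharing
#' the Trinity gene prefix (text before the final `_i<k>` token) form a
#' gene and each read joins the gene of its best-identity alignment.
#' Gene ids are deterministic: the smallest member id.
#'
#' @param alignments read-to-contig alignments, already filtered to the
#'   qualifying identity (see [qualifies()] and [align_all()]).
#' @param contigs,long_reads sequence tibbles.
#' @param mode `"components"` or `"trinity_names"`.
#' @return a tibble with one row per gene: `gene_id`, `contig_ids`
#'   (list-column), `read_ids` (list-column), `n_contigs`, `n_reads`.
#' @export
group_genes <- function(alignments, contigs, long_reads,
                        mode = c("components", "trinity_names")) {
  mode <- match.arg(mode)
  aln <- best_per_pair(alignments)
  if (mode == "components") {
    read_v <- paste0("R\r", long_reads$id)
    contig_v <- paste0("C\r", contigs$id)
    g <- igraph::make_empty_graph(directed = FALSE)
    g <- igraph::add_vertices(g, length(read_v) + length(contig_v),
                              name = c(read_v, contig_v))
    if (nrow(aln) > 0) {
      g <- igraph::add_edges(g, rbind(match(paste0("R\r", aln$query_id),
                                            c(read_v, contig_v)),
                                      match(paste0("C\r", aln$target_id),
                                            c(read_v, contig_v))))
    }
    comp <- igraph::components(g)
    members <- split(c(long_reads$id, contigs$id), comp$membership)
    kinds <- split(rep(c("read", "contig"),
                       c(nrow(long_reads), nrow(contigs))), comp$membership)
    rows <- purrr::map2(members, kinds, function(ids, kind) {
      tibble::tibble(gene_id = min(ids),
                     contig_ids = list(sort(ids[kind == "contig"])),
                     read_ids = list(sort(ids[kind == "read"])))
    })
    out <- dplyr::bind_rows(rows)
  } else {
    gene_of_contig <- trinity_gene_prefix(contigs$id)
    read_best <- dplyr::slice_max(
      dplyr::group_by(aln, .data$query_id),
      .data$matches / .data$q_size, n = 1, with_ties = FALSE)
    read_best <- dplyr::ungroup(read_best)
    read_gene <- setNames(trinity_gene_prefix(read_best$target_id),
                          read_best$query_id)
    genes <- sort(unique(c(gene_of_contig, unname(read_gene))))
    rows <- lapply(genes, function(gn) {
      c_ids <- sort(contigs$id[gene_of_contig == gn])
      r_ids <- sort(names(read_gene)[read_gene == gn])
      tibble::tibble(gene_id = min(c(c_ids, r_ids, gn)),
                     contig_ids = list(c_ids), read_ids = list(r_ids))
    })
    out <- dplyr::bind_rows(rows)
  }
  out <- dplyr::mutate(out,
                       n_contigs = lengths(.data$contig_ids),
                       n_reads = lengths(.data$read_ids))
  dplyr::arrange(out, .data$gene_id)
}

#' Select each gene's longest qualifying contig
#'
#' Candidate contigs of a gene are those with at least one qualifying
#' alignment from a group read and with length at least the maximum length
#' over the gene's mapped reads.  A read's length estimates its isoform's
#' length only up to its residual error, so the comparison grants the
#' same slack the identity threshold already grants a qualifying read:
#' `length >= max_read * min_identity`.  Among candidates the longest
#' wins, ties broken by ascending contig id; genes with reads but no
#' candidate are left unresolved (`NA`).
#'
#' @param groups output of [group_genes()].
#' @param alignments read-to-contig alignments (need not be pre-filtered;
#'   the identity test is applied here).
#' @param contigs,long_reads sequence tibbles.
#' @param min_identity qualifying identity threshold.
#' @return `groups` with columns `longest_contig_id` (character or `NA`)
#'   and `max_read_len` added.
#' @export
select_longest_contig <- function(groups, alignments, contigs, long_reads,
                                  min_identity = 0.99) {
  aln <- best_per_pair(alignments)
  aln <- aln[qualifies(aln, min_identity), ]
  clen <- setNames(contigs$length, contigs$id)
  rlen <- setNames(long_reads$length, long_reads$id)
  pick <- function(contig_ids, read_ids) {
    if (length(read_ids) == 0) {
      return(tibble::tibble(longest_contig_id = NA_character_,
                            max_read_len = NA_integer_))
    }
    sub <- aln[aln$query_id %in% read_ids & aln$target_id %in% contig_ids, ]
    mapped_reads <- unique(sub$query_id)
    if (length(mapped_reads) == 0) {
      return(tibble::tibble(longest_contig_id = NA_character_,
                            max_read_len = NA_integer_))
    }
    max_read <- max(rlen[mapped_reads])
    cand <- unique(sub$target_id)
    cand <- cand[clen[cand] >= max_read * min_identity]
    if (length(cand) == 0) {
      return(tibble::tibble(longest_contig_id = NA_character_,
                            max_read_len = as.integer(max_read)))
    }
    cand <- cand[order(-clen[cand], cand)]
    tibble::tibble(longest_contig_id = cand[1],
                   max_read_len = as.integer(max_read))
  }
  sel <- purrr::map2(groups$contig_ids, groups$read_ids, pick)
  dplyr::bind_cols(groups, dplyr::bind_rows(sel))
}

#' Build the longest-contig reference set
#'
#' One longest contig per resolved gene.  FASTA-ready ids carry
#' `gene_id|contig_id`.  A contig claimed by two genes (possible under
#' `trinity_names` grouping) is a consistency error.
#'
#' @param groups output of [select_longest_contig()].
#' @param contigs sequence tibble the contig sequences are drawn from.
#' @return a tibble of class `iso_reference`: `gene_id`, `contig_id`,
#'   `ref_id` (`gene|contig`), `length`, `seq`; unresolved genes (with
#'   reads but no qualifying contig) in `attr(, "unresolved")`.
#' @export
build_reference <- function(groups, contigs) {
  resolved <- groups[!is.na(groups$longest_contig_id), ]
  dup <- resolved$longest_contig_id[duplicated(resolved$longest_contig_id)]
  abort_if(length(dup) > 0,
           "contig %s claimed as longest by more than one gene", dup[1])
  cseq <- setNames(contigs$seq, contigs$id)
  out <- tibble::tibble(
    gene_id = resolved$gene_id,
    contig_id = resolved$longest_contig_id,
    ref_id = paste0(resolved$gene_id, "|", resolved$longest_contig_id),
    length = nchar(cseq[resolved$longest_contig_id]),
    seq = unname(cseq[resolved$longest_contig_id]))
  unresolved <- groups$gene_id[is.na(groups$longest_contig_id) &
                                 groups$n_reads > 0]
  attr(out, "unresolved") <- unresolved
  class(out) <- c("iso_reference", class(out))
  out
}

#' Per-read identity histogram and mapped/unmapped partition
#'
#' Bins each read's best identity against any contig, and counts contigs
#' with and without at least one qualifying long-read mapping.
#'
#' @param alignments read-to-contig alignments.
#' @param long_reads,contigs sequence tibbles.
#' @param breaks identity bin edges (the final edge is inclusive).
#' @param min_identity qualifying threshold for the contig partition.
#' @return a list of class `iso_mapping_report`: `read_identity` (tibble:
#'   bin, n), `reads` (tibble: read_id, best_identity, mapped), `contigs`
#'   (tibble: status, n).
#' @export
mapping_report <- function(alignments, long_reads, contigs,
                           breaks = c(0, 0.95, 0.99, 1),
                           min_identity = 0.99) {
  best <- dplyr::summarise(
    dplyr::group_by(alignments, .data$query_id),
    best_identity = max(.data$matches / .data$q_size), .groups = "drop")
  reads <- dplyr::left_join(long_reads[, "id"], best,
                            by = c(id = "query_id"))
  reads$mapped <- !is.na(reads$best_identity)
  mapped <- reads[reads$mapped, ]
  bin <- cut(mapped$best_identity, breaks = breaks, include.lowest = TRUE,
             right = FALSE)
  # top bin is closed: identity == max break belongs to the last bin
  bin[mapped$best_identity >= breaks[length(breaks)]] <-
    levels(bin)[length(levels(bin))]
  hist <- dplyr::count(tibble::tibble(bin = bin), .data$bin, .drop = FALSE)
  qual_targets <- unique(alignments$target_id[qualifies(alignments,
                                                        min_identity)])
  contig_part <- tibble::tibble(
    status = c("mapped", "unmapped"),
    n = c(sum(contigs$id %in% qual_targets),
          sum(!contigs$id %in% qual_targets)))
  structure(list(read_identity = tibble::as_tibble(hist),
                 reads = tibble::as_tibble(reads),
                 contigs = contig_part),
            class = "iso_mapping_report")
}

#' @export
print.iso_mapping_report <- function(x, ...) {
  cat("Long-read to contig mapping report\n")
  cat(sprintf("  reads mapped: %d / %d\n", sum(x$reads$mapped),
              nrow(x$reads)))
  print(x$read_identity)
  cat("  contigs:\n")
  print(x$contigs)
  invisible(x)
}
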