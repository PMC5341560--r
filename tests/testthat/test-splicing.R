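# Splice-gap extraction, signature canonicalisation, cataloguing and
# junction verification.

mk_gap_aln <- function(blocks, q_size, t_size, query_id = "r",
                       target_id = "c") {
  b <- blocks
  q_span <- sum(b$size) + sum(pmax(b$q_start[-1] -
    (b$q_start[-nrow(b)] + b$size[-nrow(b)]), 0))
  t_span <- sum(b$size) + sum(pmax(b$t_start[-1] -
    (b$t_start[-nrow(b)] + b$size[-nrow(b)]), 0))
  dq <- if (nrow(b) > 1) b$q_start[-1] - (b$q_start[-nrow(b)] +
                                            b$size[-nrow(b)]) else integer(0)
  dt <- if (nrow(b) > 1) b$t_start[-1] - (b$t_start[-nrow(b)] +
                                            b$size[-nrow(b)]) else integer(0)
  tibble::tibble(query_id = query_id, target_id = target_id, strand = "+",
                 matches = sum(b$size), mismatches = 0L,
                 q_num_insert = sum(dq > 0), q_base_insert = sum(dq),
                 t_num_insert = sum(dt > 0), t_base_insert = sum(dt),
                 q_size = as.integer(q_size),
                 q_start = b$q_start[1],
                 q_end = b$q_start[nrow(b)] + b$size[nrow(b)],
                 t_size = as.integer(t_size),
                 t_start = b$t_start[1],
                 t_end = b$t_start[nrow(b)] + b$size[nrow(b)],
                 blocks = list(b))
}

test_that("gap extraction does the coordinate arithmetic and is strict at 50 bp", {
  a <- mk_gap_aln(block_tbl(c(100L, 120L), c(0L, 100L), c(0L, 180L)),
                  q_size = 220, t_size = 300)
  ev <- extract_gaps(a, 50)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "exclusion")
  expect_equal(ev$t_start, 100L)
  expect_equal(ev$t_end, 180L)
  expect_equal(ev$length, 80L)

  # single block: nothing
  single <- mk_gap_aln(block_tbl(200L, 0L, 0L), 200, 200)
  expect_equal(nrow(extract_gaps(single, 50)), 0L)

  # a gap of exactly 50 bp is not a splice; 51 bp is
  at50 <- mk_gap_aln(block_tbl(c(100L, 100L), c(0L, 100L), c(0L, 150L)),
                     q_size = 200, t_size = 250)
  expect_equal(nrow(extract_gaps(at50, 50)), 0L)
  at51 <- mk_gap_aln(block_tbl(c(100L, 100L), c(0L, 100L), c(0L, 151L)),
                     q_size = 200, t_size = 251)
  expect_equal(nrow(extract_gaps(at51, 50)), 1L)

  # query-side gap becomes an insertion event anchored on the target
  ins <- mk_gap_aln(block_tbl(c(100L, 100L), c(0L, 160L), c(0L, 100L)),
                    q_size = 260, t_size = 200)
  ev2 <- extract_gaps(ins, 50)
  expect_equal(ev2$kind, "insertion")
  expect_equal(ev2$t_start, 100L)
  expect_equal(ev2$length, 60L)
})

test_that("signatures separate gaps by site and by length", {
  a <- mk_gap_aln(block_tbl(c(100L, 100L), c(0L, 100L), c(0L, 180L)),
                  q_size = 200, t_size = 280, query_id = "r1")
  b <- mk_gap_aln(block_tbl(c(150L, 50L), c(0L, 150L), c(0L, 230L)),
                  q_size = 200, t_size = 280, query_id = "r2")
  c_ <- mk_gap_aln(block_tbl(c(100L, 100L), c(0L, 100L), c(0L, 200L)),
                   q_size = 200, t_size = 300, query_id = "r3")
  sig <- splice_signature(dplyr::bind_rows(a, b, c_), min_gap = 50)
  expect_equal(length(unique(sig$signature)), 3L)
  # same alignment twice -> same signature
  a2 <- a; a2$query_id <- "r4"
  sig2 <- splice_signature(dplyr::bind_rows(a, a2), min_gap = 50)
  expect_equal(sig2$signature[1], sig2$signature[2])
  # gapless alignment carries the empty signature
  g <- mk_gap_aln(block_tbl(200L, 0L, 0L), 200, 200, query_id = "r5")
  sig3 <- splice_signature(g)
  expect_equal(sig3$signature, "")
})

test_that("coordinate snapping merges nearby endpoints to the modal value", {
  x <- c(100L, 100L, 103L, 100L, 480L, 482L, 482L)
  snapped <- isomapr:::snap_coords(x, 5)
  expect_equal(snapped, c(100, 100, 100, 100, 482, 482, 482))
  expect_equal(isomapr:::snap_coords(x, 0), x)
})

test_that("the catalogue matches brute-force grouping by exact event tuples", {
  groups <- fx_groups0()
  ref <- build_reference(groups, fx_contigs()$contigs)
  aln <- fx_aln0()
  catalog <- catalog_splicing(groups, ref, aln, min_gap = 50,
                              round_bp = 0, min_identity = 0.99)
  # brute force: per gene, group qualifying read->longest alignments by
  # their literal event tuples
  best <- aln |>
    dplyr::group_by(query_id, target_id) |>
    dplyr::slice_max(matches, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(matches / q_size >= 0.99)
  for (g in seq_len(nrow(ref))) {
    contig <- ref$contig_id[g]
    gene_reads <- groups$read_ids[[which(groups$gene_id == ref$gene_id[g])]]
    sub <- best[best$target_id == contig & best$query_id %in% gene_reads, ]
    keys <- vapply(seq_len(nrow(sub)), function(i) {
      ev <- extract_gaps(sub[i, ], 50)
      paste(sprintf("%s:%d-%d", ev$kind, ev$t_start, ev$t_end),
            collapse = ";")
    }, character(1))
    want <- sort(table(keys), decreasing = TRUE)
    got <- catalog[catalog$gene_id == ref$gene_id[g], ]
    expect_equal(nrow(got), length(unique(keys)))
    expect_setequal(got$support, as.integer(table(keys)))
  }
})

test_that("recovered signatures are in bijection with planted structures above the gap threshold", {
  groups <- fx_groups0()
  ref <- build_reference(groups, fx_contigs()$contigs)
  catalog <- catalog_splicing(groups, ref, fx_aln0(), min_gap = 50,
                              round_bp = 0, min_identity = 0.99)
  models <- fx_models()
  manifest <- fx_reads0()$manifest
  # gap coordinates are defined up to junction sequence ambiguity; the
  # canonical (left-normalised) placement is the expected one
  full_seq <- setNames(
    models$isoforms$seq[is.na(models$isoforms$skipped_exon)],
    models$isoforms$gene_id[is.na(models$isoforms$skipped_exon)])
  events <- models$events
  for (gene in models$genes$gene_id) {
    iso <- models$isoforms[models$isoforms$gene_id == gene, ]
    # expected classes per gene: isoforms collapse when their skipped
    # segment is <= 50 bp (they then share the gapless signature)
    key_of_iso <- vapply(iso$isoform_id, function(id) {
      ev <- events[events$isoform_id == id & events$length > 50, ]
      keys <- vapply(seq_len(nrow(ev)), function(k) {
        se <- leftnorm_gap(full_seq[[gene]], ev$t_start[k], ev$t_end[k])
        sprintf("excl:%d-%d", se[1], se[2])
      }, character(1))
      paste(keys, collapse = ";")
    }, character(1))
    expected_classes <- length(unique(key_of_iso))
    got <- catalog[catalog$gene_id %in%
                     groups$gene_id[vapply(groups$read_ids, function(r)
                       any(manifest$gene_id[match(r, manifest$read_id)] ==
                             gene), logical(1))], ]
    expect_equal(nrow(got), expected_classes)
    # and the (normalised) planted exclusion coordinates appear verbatim
    planted <- events[events$gene_id == gene & events$length > 50, ]
    for (k in seq_len(nrow(planted))) {
      se <- leftnorm_gap(full_seq[[gene]], planted$t_start[k],
                         planted$t_end[k])
      expect_true(any(grepl(sprintf("excl:%d-%d", se[1], se[2]),
                            got$signature, fixed = TRUE)))
    }
  }
  # support sets partition each gene's catalogued reads
  all_reads <- unlist(catalog$read_ids)
  expect_false(any(duplicated(all_reads)))
})

test_that("catalogue summary histogram conserves gene counts", {
  groups <- fx_groups0()
  ref <- build_reference(groups, fx_contigs()$contigs)
  catalog <- catalog_splicing(groups, ref, fx_aln0(), round_bp = 0)
  s <- summarize_catalog(catalog)
  expect_equal(sum(s$histogram$n_genes), s$n_genes)
  expect_equal(s$n_genes, length(unique(catalog$gene_id)))
  expect_true(all(s$gene_lists$ge3 %in% s$gene_lists$ge2))
  expect_true(all(s$gene_lists$ge4 %in% s$gene_lists$ge3))
  # empty catalogue -> empty histogram
  s0 <- summarize_catalog(catalog[0, ])
  expect_equal(nrow(s0$histogram), 0L)
})

test_that("no catalogued event is ever at or below the gap threshold", {
  groups <- fx_groups0()
  ref <- build_reference(groups, fx_contigs()$contigs)
  aln <- fx_aln0()
  ca <- isomapr:::catalog_alignments(catalog_splicing(groups, ref, aln),
                                     groups, ref, aln, 0.99)
  ev <- extract_gaps(ca, min_gap = 50)
  expect_true(all(ev$length > 50))
})

test_that("junction fragments verify planted exclusion events and depth is monotone", {
  models <- fx_models()
  groups <- fx_groups0()
  ref <- build_reference(groups, fx_contigs()$contigs)
  frags <- sim_junction_fragments(models, per_junction = 4, seed = 19)
  # build events on reference contigs from the planted manifest
  roster <- fx_contigs()$roster
  longest <- setNames(roster$contig_id[roster$label == "longest"],
                      roster$gene_id[roster$label == "longest"])
  planted <- models$events[models$events$length > 50, ]
  events <- tibble::tibble(
    query_id = planted$isoform_id, target_id = unname(longest[planted$gene_id]),
    kind = "exclusion", t_start = planted$t_start, t_end = planted$t_end,
    length = planted$length)
  events <- events[events$target_id %in% ref$contig_id, ]
  got <- verify_junctions(events, ref, frags$fragments, flank = 25)
  expect_true(all(got$verified))
  # fragments from a skip isoform do not support the un-skipped junction:
  # probe the skipped exon's interior instead
  interior <- events
  interior$t_start <- interior$t_start + 3L
  interior$t_end <- interior$t_end - 3L
  got_wrong <- verify_junctions(interior, ref, frags$fragments, flank = 25)
  expect_false(any(got_wrong$verified))
  # no fragments -> nothing verified
  none <- verify_junctions(events, ref, frags$fragments[0, ], flank = 25)
  expect_true(all(none$support == 0))
  # support never decreases with fragment depth
  deeper <- sim_junction_fragments(models, per_junction = 8, seed = 19)
  got_deep <- verify_junctions(events, ref, deeper$fragments, flank = 25)
  expect_true(all(got_deep$support >= got$support))
})
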