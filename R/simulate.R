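# Ground-truthed synthetic transcriptome generator.
#
# Emulates the data structure the pipeline consumes: exon-structured genes
# with alternative isoforms (always including the all-exon form), error-
# bearing long reads with planted exact-substring duplicates, contig
# libraries containing the all-exon longest molecule plus true and false
# (shuffled / chimeric) contigs, short reads at known per-tissue
# abundances, and junction-spanning merged fragments.  Every emission is
# deterministic given its seed and is accompanied by a machine-readable
# truth manifest.

new_gene_models <- function(genes, isoforms, events, params) {
  structure(list(genes = genes, isoforms = isoforms, events = events,
                 params = params),
            class = "iso_gene_models")
}

#' @export
print.iso_gene_models <- function(x, ...) {
  cat(sprintf("Synthetic gene models: %d genes, %d isoforms, %d planted splice events\n",
              nrow(x$genes), nrow(x$isoforms), nrow(x$events)))
  invisible(x)
}

#' Simulate exon-structured gene models
#'
#' Each gene gets `exon_count` exons of random sequence; exon sequences
#' are redrawn until no 20-mer is shared across genes, so qualifying
#' alignments cannot cross genes.  Every gene carries the all-exon
#' isoform; additional isoforms each skip one distinct internal exon.
#' With probability `p_short_exon` one internal exon is short (drawn from
#' `short_exon_len_range`), planting skipped segments at or below the
#' splice-gap threshold.
#'
#' @param n number of genes.
#' @param exon_count_range,exon_len_range integer ranges (inclusive).
#' @param n_isoform_range isoforms per gene (capped at
#'   `1 + number of internal exons`).
#' @param p_short_exon probability that a gene carries one short internal
#'   exon.
#' @param short_exon_len_range length range of the short exon.
#' @param seed RNG seed (mandatory).
#' @return an object of class `iso_gene_models` with tibbles `genes`
#'   (`gene_id`, `n_exons`, `exon_lens`, `exons`), `isoforms` (`gene_id`,
#'   `isoform_id`, `exon_idx`, `skipped_exon`, `seq`, `length`,
#'   `base_abundance`) and `events` (planted exclusion events on all-exon
#'   contig coordinates: `gene_id`, `isoform_id`, `t_start`, `t_end`,
#'   `length`).
#' @export
sim_genes <- function(n, exon_count_range = c(4L, 8L),
                      exon_len_range = c(80L, 400L),
                      n_isoform_range = c(1L, 3L),
                      p_short_exon = 0.2,
                      short_exon_len_range = c(20L, 45L),
                      seed) {
  abort_if(missing(seed), "seed is mandatory")
  abort_if(any(exon_count_range < 2) || any(exon_len_range < 1) ||
             any(n_isoform_range < 1), "impossible range")
  with_seed(seed, {
    k_guard <- 20L
    seen <- new.env(parent = emptyenv())
    draw_exon <- function(len) {
      repeat {
        s <- random_seq(len)
        km <- seq_kmers(s, k_guard)
        if (!any(vapply(km, function(x) !is.null(seen[[x]]), logical(1)))) {
          for (x in km) seen[[x]] <- TRUE
          return(s)
        }
      }
    }
    gene_rows <- vector("list", n)
    iso_rows <- list()
    ev_rows <- list()
    for (g in seq_len(n)) {
      gene_id <- sprintf("gene%03d", g)
      n_ex <- safe_sample(exon_count_range[1]:exon_count_range[2], 1)
      lens <- safe_sample(exon_len_range[1]:exon_len_range[2], n_ex,
                          replace = TRUE)
      short_exon <- NA_integer_
      if (stats::runif(1) < p_short_exon && n_ex >= 3) {
        short_exon <- safe_sample(2:(n_ex - 1), 1)
        lens[short_exon] <- safe_sample(
          short_exon_len_range[1]:short_exon_len_range[2], 1)
      }
      exons <- vapply(lens, draw_exon, character(1))
      starts <- c(0L, cumsum(lens))  # 0-based exon starts on the full form
      n_internal <- max(0L, n_ex - 2L)
      n_iso <- min(safe_sample(n_isoform_range[1]:n_isoform_range[2], 1),
                   1L + n_internal)
      skips <- if (n_iso > 1) safe_sample(2:(n_ex - 1), n_iso - 1) else
        integer(0)
      abund <- stats::rexp(n_iso) + 0.2
      abund <- abund / sum(abund)
      for (j in seq_len(n_iso)) {
        skipped <- if (j == 1) NA_integer_ else skips[j - 1]
        idx <- if (j == 1) seq_len(n_ex) else setdiff(seq_len(n_ex), skipped)
        iso_id <- sprintf("%s_iso%d", gene_id, j)
        iso_rows[[iso_id]] <- tibble::tibble(
          gene_id = gene_id, isoform_id = iso_id,
          exon_idx = list(idx), skipped_exon = skipped,
          seq = paste(exons[idx], collapse = ""),
          length = sum(lens[idx]), base_abundance = abund[j])
        if (j > 1) {
          ev_rows[[iso_id]] <- tibble::tibble(
            gene_id = gene_id, isoform_id = iso_id,
            t_start = starts[skipped], t_end = starts[skipped + 1L],
            length = lens[skipped])
        }
      }
      gene_rows[[g]] <- tibble::tibble(
        gene_id = gene_id, n_exons = n_ex, exon_lens = list(lens),
        exons = list(exons), short_exon = short_exon)
    }
    new_gene_models(
      genes = dplyr::bind_rows(gene_rows),
      isoforms = dplyr::bind_rows(iso_rows),
      events = if (length(ev_rows)) dplyr::bind_rows(ev_rows) else
        tibble::tibble(gene_id = character(0), isoform_id = character(0),
                       t_start = integer(0), t_end = integer(0),
                       length = integer(0)),
      params = list(n = n, seed = seed, p_short_exon = p_short_exon))
  })
}

# Apply substitution/indel noise at `rate` errors per base.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  n_err <- stats::rbinom(1, length(bases), rate)
  if (n_err == 0) return(seq)
  pos <- sort(sample(length(bases), n_err))
  type <- sample(c("sub", "ins", "del"), n_err, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
  for (i in seq_len(n_err)) {
    p <- pos[i]
    if (type[i] == "sub") {
      bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1)
    } else if (type[i] == "ins") {
      bases[p] <- paste0(bases[p], sample(DNA_BASES, 1))
    } else {
      bases[p] <- ""
    }
  }
  paste(bases, collapse = "")
}

#' Emit corrected long reads from gene models
#'
#' Reads are isoform sequences: full-length with probability
#' `full_length_frac`, else 5'-truncated by 10-50%; substitution/indel
#' noise at `error_rate`; with probability `dup_rate` a read additionally
#' spawns an exact strictly-shorter substring duplicate (exercising the
#' containment dedup rule).
#'
#' @param models an `iso_gene_models` object.
#' @param per_isoform_depth reads per isoform.
#' @param error_rate residual error rate in `[0, 0.05]`.
#' @param full_length_frac probability a read is full-length.
#' @param dup_rate probability a read plants a duplicate.
#' @param seed RNG seed.
#' @return a list: `reads` (sequence tibble, role `long_read`) and
#'   `manifest` (tibble: `read_id`, `gene_id`, `isoform_id`,
#'   `full_length`, `duplicate_of`).
#' @export
sim_long_reads <- function(models, per_isoform_depth = 4L, error_rate = 0,
                           full_length_frac = 1, dup_rate = 0, seed) {
  abort_if(missing(seed), "seed is mandatory")
  abort_if(error_rate < 0 || error_rate > 0.05,
           "error_rate must be in [0, 0.05]")
  with_seed(seed, {
    ids <- character(0); seqs <- character(0)
    man <- list()
    counter <- 0L
    for (i in seq_len(nrow(models$isoforms))) {
      iso <- models$isoforms[i, ]
      for (d in seq_len(per_isoform_depth)) {
        counter <- counter + 1L
        full <- stats::runif(1) < full_length_frac
        s <- iso$seq
        if (!full) {
          cut <- floor(nchar(s) * stats::runif(1, 0.1, 0.5))
          s <- substring(s, cut + 1L)
        }
        s <- mutate_seq(s, error_rate)
        rid <- sprintf("LR%05d", counter)
        ids <- c(ids, rid); seqs <- c(seqs, s)
        man[[rid]] <- tibble::tibble(
          read_id = rid, gene_id = iso$gene_id,
          isoform_id = iso$isoform_id, full_length = full,
          duplicate_of = NA_character_)
        if (stats::runif(1) < dup_rate && nchar(s) > 100) {
          counter <- counter + 1L
          trim_l <- sample(0:5, 1)
          trim_r <- sample(1:10, 1)
          dup <- substring(s, trim_l + 1L, nchar(s) - trim_r)
          did <- sprintf("LR%05d", counter)
          ids <- c(ids, did); seqs <- c(seqs, dup)
          man[[did]] <- tibble::tibble(
            read_id = did, gene_id = iso$gene_id,
            isoform_id = iso$isoform_id, full_length = FALSE,
            duplicate_of = rid)
        }
      }
    }
    list(reads = as_seq_tbl(seqs, role = "long_read", ids = ids),
         manifest = dplyr::bind_rows(man))
  })
}

#' Emit an assembled-contig library from gene models
#'
#' Per gene: (a) the all-exon longest contig; (b) each non-full true
#' isoform as a contig with probability `true_frac`; and, when
#' `include_false` is set, (c) false contigs -- a shuffled-exon-order
#' variant (one internal exon dropped, internal order permuted) with
#' probability `p_shuffle`, and chimeras joining the head exons of one
#' gene to the tail exons of the next (`n_chimeras` of them, each longer
#' than its host gene's longest contig).  Contigs use Trinity-style ids
#' (`TRINITY_DN<g>_c0_g1_i<k>`) so name-based grouping is exercised.
#'
#' @param models an `iso_gene_models` object.
#' @param include_false emit shuffled and chimeric contigs?
#' @param true_frac probability a non-full isoform yields a contig.  The
#'   default 1 keeps, per gene, the number of expressed isoform classes
#'   at or below the number of assembled contigs (the theoretical
#'   assembly contains every expressed form), which the catalogue treats
#'   as an invariant of the data model.
#' @param p_shuffle probability of a shuffled false contig per gene.
#' @param n_chimeras number of chimeric contigs (default: one per ten
#'   genes).
#' @param seed RNG seed.
#' @return a list: `contigs` (sequence tibble, role `contig`) and `roster`
#'   (tibble: `contig_id`, `gene_id`, `label` in
#'   `{longest,true,shuffled,chimera}`, `isoform_id`, `partner_gene`,
#'   `length`).
#' @export
sim_contigs <- function(models, include_false = TRUE, true_frac = 1,
                        p_shuffle = 0.3,
                        n_chimeras = ceiling(nrow(models$genes) / 10),
                        seed) {
  abort_if(missing(seed), "seed is mandatory")
  with_seed(seed, {
    ids <- character(0); seqs <- character(0)
    roster <- list()
    trinity <- function(g, k) sprintf("TRINITY_DN%d_c0_g1_i%d", g, k)
    next_idx <- integer(nrow(models$genes)) + 1L
    add <- function(g, seq, label, isoform_id = NA_character_,
                    partner = NA_character_) {
      cid <- trinity(g, next_idx[g])
      next_idx[g] <<- next_idx[g] + 1L
      ids <<- c(ids, cid); seqs <<- c(seqs, seq)
      roster[[cid]] <<- tibble::tibble(
        contig_id = cid, gene_id = models$genes$gene_id[g], label = label,
        isoform_id = isoform_id, partner_gene = partner,
        length = nchar(seq))
    }
    for (g in seq_len(nrow(models$genes))) {
      gene <- models$genes[g, ]
      iso <- models$isoforms[models$isoforms$gene_id == gene$gene_id, ]
      full <- iso[is.na(iso$skipped_exon), ]
      add(g, full$seq[1], "longest", full$isoform_id[1])
      others <- iso[!is.na(iso$skipped_exon), ]
      for (j in seq_len(nrow(others))) {
        if (stats::runif(1) < true_frac) {
          add(g, others$seq[j], "true", others$isoform_id[j])
        }
      }
      if (include_false && stats::runif(1) < p_shuffle &&
          gene$n_exons >= 5) {
        exons <- gene$exons[[1]]
        internal <- 2:(gene$n_exons - 1)
        drop <- safe_sample(internal, 1)
        keep <- setdiff(seq_len(gene$n_exons), drop)
        mid <- setdiff(keep, c(1, gene$n_exons))
        perm <- c(1, safe_sample(mid), gene$n_exons)
        if (identical(perm, keep)) perm <- c(1, rev(mid), gene$n_exons)
        add(g, paste(exons[perm], collapse = ""), "shuffled")
      }
    }
    if (include_false && n_chimeras > 0 && nrow(models$genes) >= 2) {
      hosts <- sample(nrow(models$genes), n_chimeras)
      for (g in hosts) {
        partner <- if (g == nrow(models$genes)) 1L else g + 1L
        he <- models$genes$exons[[g]]
        pe <- models$genes$exons[[partner]]
        chim <- paste(c(he[seq_len(length(he) - 1L)], pe[-1]),
                      collapse = "")
        add(g, chim, "chimera",
            partner = models$genes$gene_id[partner])
      }
    }
    list(contigs = as_seq_tbl(seqs, role = "contig", ids = ids),
         roster = dplyr::bind_rows(roster))
  })
}

#' Default tissue design
#'
#' @param conditions condition labels.
#' @param replicates replicates per condition.
#' @return tibble with `sample`, `condition`, `replicate`.
#' @export
sim_design <- function(conditions = c("root", "stem", "leaf", "flower"),
                       replicates = 3L) {
  tidyr::crossing(condition = factor(conditions, levels = conditions),
                  replicate = seq_len(replicates)) |>
    dplyr::mutate(condition = as.character(.data$condition),
                  sample = paste0(.data$condition, "_", .data$replicate),
                  .before = 1) |>
    dplyr::select("sample", "condition", "replicate")
}

#' Emit short-read samples at known abundances
#'
#' Reads of fixed length are sampled uniformly along isoforms, with
#' isoform choice proportional to `base_abundance` (times any planted
#' per-condition fold change) times effective length.
#'
#' @param models an `iso_gene_models` object.
#' @param design a [sim_design()] tibble.
#' @param read_len read length (must be below the shortest isoform).
#' @param depth reads per sample.
#' @param fold_changes optional tibble (`isoform_id`, `condition`, `fold`)
#'   multiplying the focal isoform's abundance in that condition.
#' @param seed RNG seed.
#' @return a list: `samples` (named list of sequence tibbles),
#'   `truth` (tibble: `sample`, `isoform_id`, `weight`,
#'   `expected_reads`).
#' @export
sim_short_reads <- function(models, design = sim_design(), read_len = 75L,
                            depth = 5000L, fold_changes = NULL, seed) {
  abort_if(missing(seed), "seed is mandatory")
  iso <- models$isoforms
  abort_if(read_len >= min(iso$length),
           "read_len must be below the shortest isoform length (%d)",
           min(iso$length))
  with_seed(seed, {
    eff <- pmax(iso$length - read_len + 1, 1)
    samples <- list()
    truth <- list()
    for (s in seq_len(nrow(design))) {
      samp <- design$sample[s]
      w <- iso$base_abundance
      if (!is.null(fold_changes)) {
        fc <- fold_changes[fold_changes$condition == design$condition[s], ]
        ix <- match(fc$isoform_id, iso$isoform_id)
        w[ix] <- w[ix] * fc$fold
      }
      w <- w * eff
      w <- w / sum(w)
      counts <- as.integer(stats::rmultinom(1, depth, w))
      seqs <- character(0)
      srcs <- character(0)
      for (i in which(counts > 0)) {
        starts <- sample.int(iso$length[i] - read_len + 1L, counts[i],
                             replace = TRUE)
        seqs <- c(seqs, substring(iso$seq[i], starts,
                                  starts + read_len - 1L))
        srcs <- c(srcs, rep(iso$isoform_id[i], counts[i]))
      }
      ids <- sprintf("%s_r%06d", samp, seq_along(seqs))
      samples[[samp]] <- as_seq_tbl(seqs, role = "short_read", ids = ids)
      truth[[samp]] <- tibble::tibble(
        sample = samp, isoform_id = iso$isoform_id, weight = w,
        expected_reads = w * depth, observed_reads = counts)
    }
    list(samples = samples, truth = dplyr::bind_rows(truth))
  })
}

#' Emit junction-spanning merged fragments
#'
#' For every planted exclusion event, fragments are sampled from the
#' skipping isoform so that each covers the junction with at least
#' `min_flank` bp on both sides.
#'
#' @param models an `iso_gene_models` object.
#' @param frag_len_range fragment length range (bp); capped at the isoform
#'   length.
#' @param per_junction fragments per planted junction.
#' @param min_flank minimum junction flank covered on each side.
#' @param seed RNG seed.
#' @return a list: `fragments` (sequence tibble, role `short_read`) and
#'   `manifest` (tibble: `fragment_id`, `gene_id`, `isoform_id`,
#'   `t_start`, `t_end`).
#' @export
sim_junction_fragments <- function(models, frag_len_range = c(300L, 590L),
                                   per_junction = 5L, min_flank = 30L,
                                   seed) {
  abort_if(missing(seed), "seed is mandatory")
  with_seed(seed, {
    iso_seq <- setNames(models$isoforms$seq, models$isoforms$isoform_id)
    ids <- character(0); seqs <- character(0)
    man <- list()
    counter <- 0L
    for (i in seq_len(nrow(models$events))) {
      ev <- models$events[i, ]
      s <- iso_seq[[ev$isoform_id]]
      L <- nchar(s)
      # junction position on the skipping isoform: preceding exons are
      # shared with the full form, so it sits at the gap's start
      J <- ev$t_start
      for (f in seq_len(per_junction)) {
        counter <- counter + 1L
        flen <- min(safe_sample(frag_len_range[1]:frag_len_range[2], 1), L)
        lo <- max(1L, J + min_flank - flen + 1L)
        hi <- min(L - flen + 1L, J - min_flank + 1L)
        if (hi < lo) { lo <- 1L; hi <- max(1L, L - flen + 1L) }
        start <- sample(lo:hi, 1)
        fid <- sprintf("frag%05d", counter)
        ids <- c(ids, fid)
        seqs <- c(seqs, substring(s, start, start + flen - 1L))
        man[[fid]] <- tibble::tibble(
          fragment_id = fid, gene_id = ev$gene_id,
          isoform_id = ev$isoform_id, t_start = ev$t_start,
          t_end = ev$t_end)
      }
    }
    if (counter == 0) {
      return(list(fragments = tibble::tibble(id = character(0),
                                             seq = character(0),
                                             length = integer(0),
                                             role = character(0)),
                  manifest = tibble::tibble()))
    }
    list(fragments = as_seq_tbl(seqs, role = "short_read", ids = ids),
         manifest = dplyr::bind_rows(man))
  })
}
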