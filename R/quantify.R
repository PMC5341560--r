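# Isoform abundance estimation and differential-expression screening.
#
# Short reads are reduced to weighted compatibility classes (which
# reference isoforms contain the read); an EM on the standard mixture
# model splits multi-mapping classes proportional to abundance over
# effective length.  Screening applies the triple cutoff -- p < 0.05,
# BH FDR < 0.01, fold change >= 2 -- per isoform between two conditions,
# and tissue-specific isoforms are the intersection of one-vs-each screens.

#' Build a read-compatibility table against a reference
#'
#' A read is compatible with an isoform when it occurs in it as an exact
#' substring (forward or reverse-complement).  Reads compatible with no
#' isoform are dropped and counted; identical compatibility sets are
#' merged into weighted classes.
#'
#' @param short_reads sequence tibble of short reads (uniform length
#'   required for the fast dictionary match).
#' @param reference an [build_reference()] result or any tibble with
#'   `ref_id`-like `id`/`seq` columns; rows become isoforms.
#' @param id_col column of `reference` holding isoform ids.
#' @return a tibble of class `iso_compat`: `class_id`, `isoforms`
#'   (list-column of isoform ids), `weight`; attributes `n_unmapped`,
#'   `n_mapped`, `read_len`.
#' @export
build_compatibility <- function(short_reads, reference,
                                id_col = if ("ref_id" %in% names(reference))
                                  "ref_id" else "id") {
  abort_if(nrow(reference) == 0, "empty reference")
  iso_ids <- reference[[id_col]]
  if (nrow(short_reads) == 0) {
    out <- tibble::tibble(class_id = character(0), isoforms = list(),
                          weight = integer(0))
    attr(out, "n_unmapped") <- 0L
    attr(out, "n_mapped") <- 0L
    class(out) <- c("iso_compat", class(out))
    return(out)
  }
  widths <- unique(nchar(short_reads$seq))
  abort_if(length(widths) != 1,
           "short reads must have uniform length (found %d widths)",
           length(widths))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(short_reads$seq))
  subjects <- Biostrings::DNAStringSet(
    paste(reference$seq, revcomp(reference$seq), sep = strrep("N", widths)))
  hits <- Biostrings::vwhichPDict(pd, subjects)
  # hits[[i]] = read indices matching isoform i; invert to per-read sets
  read_sets <- vector("list", nrow(short_reads))
  for (i in seq_along(hits)) {
    for (r in hits[[i]]) read_sets[[r]] <- c(read_sets[[r]], i)
  }
  mapped <- lengths(read_sets) > 0
  keys <- vapply(read_sets[mapped], paste, character(1), collapse = ",")
  tab <- table(keys)
  classes <- names(tab)
  out <- tibble::tibble(
    class_id = classes,
    isoforms = lapply(strsplit(classes, ","),
                      function(ix) iso_ids[as.integer(ix)]),
    weight = as.integer(tab))
  out <- dplyr::arrange(out, .data$class_id)
  attr(out, "n_unmapped") <- sum(!mapped)
  attr(out, "n_mapped") <- sum(mapped)
  attr(out, "read_len") <- widths
  class(out) <- c("iso_compat", class(out))
  out
}

#' Estimate isoform abundance by EM
#'
#' The standard mixture model: each compatibility class is split among its
#' isoforms proportional to `theta_i / effective_length_i` times the
#' current mixture weight; the M-step renormalises.  Uniform
#' initialisation makes the fit deterministic.  Effective length is
#' `length - mean_fragment + 1`, floored at 1.
#'
#' @param compat an [build_compatibility()] table.
#' @param isoform_lengths named numeric vector of isoform lengths (bp).
#' @param mean_fragment mean fragment/read length used for effective
#'   lengths; defaults to the compatibility table's read length.
#' @param max_iter,tol EM stopping rule: `max_iter` iterations or
#'   `max |delta theta| < tol`.
#' @return an object of class `iso_em_fit`: tibble with `isoform_id`,
#'   `est_counts`, `tpm`, `theta`; attributes `loglik` (per-iteration
#'   trace), `n_iter`, `converged`.
#' @export
em_abundance <- function(compat, isoform_lengths,
                         mean_fragment = attr(compat, "read_len") %||% 1,
                         max_iter = 500L, tol = 1e-8) {
  iso <- names(isoform_lengths)
  abort_if(is.null(iso), "isoform_lengths must be named")
  eff_len <- pmax(isoform_lengths - mean_fragment + 1, 1)
  abort_if(any(eff_len <= 0), "zero effective length")
  K <- length(iso)
  # class membership matrix rows = classes
  memb <- lapply(compat$isoforms, function(ids) match(ids, iso))
  abort_if(any(vapply(memb, anyNA, logical(1))),
           "compatibility table references unknown isoform")
  w <- compat$weight
  N <- sum(w)
  theta <- rep(1 / K, K)
  loglik <- numeric(0)
  n_iter <- 0L
  converged <- FALSE
  if (N > 0) {
    for (it in seq_len(max_iter)) {
      # E-step: class c contributes w_c * p_i / sum(p_j in c),
      # p_i = theta_i / eff_len_i
      p <- theta / eff_len
      counts <- numeric(K)
      ll <- 0
      for (c in seq_along(memb)) {
        ix <- memb[[c]]
        pc <- p[ix]
        s <- sum(pc)
        counts[ix] <- counts[ix] + w[c] * pc / s
        ll <- ll + w[c] * log(s)
      }
      loglik <- c(loglik, ll)
      new_theta <- counts / N
      n_iter <- it
      if (max(abs(new_theta - theta)) < tol) {
        theta <- new_theta
        converged <- TRUE
        break
      }
      theta <- new_theta
    }
  }
  est_counts <- theta * N
  rate <- theta / eff_len
  tpm <- if (sum(rate) > 0) rate / sum(rate) * 1e6 else rep(0, K)
  out <- tibble::tibble(isoform_id = iso, est_counts = est_counts,
                        tpm = tpm, theta = theta)
  attr(out, "loglik") <- loglik
  attr(out, "n_iter") <- n_iter
  attr(out, "converged") <- converged
  attr(out, "n_mapped") <- N
  class(out) <- c("iso_em_fit", class(out))
  out
}

#' Quantify several samples against one reference
#'
#' @param sample_reads named list of short-read sequence tibbles, one per
#'   sample.
#' @param reference a [build_reference()] result (or id/seq tibble).
#' @param ... passed to [em_abundance()].
#' @return a long tibble of class `iso_expression`: `isoform_id`,
#'   `sample`, `est_counts`, `tpm`.
#' @export
quantify_samples <- function(sample_reads, reference, ...) {
  abort_if(is.null(names(sample_reads)), "sample_reads must be named")
  id_col <- if ("ref_id" %in% names(reference)) "ref_id" else "id"
  lens <- setNames(nchar(reference$seq), reference[[id_col]])
  rows <- purrr::imap(sample_reads, function(reads, sample) {
    compat <- build_compatibility(reads, reference, id_col = id_col)
    fit <- em_abundance(compat, lens, ...)
    tibble::tibble(isoform_id = fit$isoform_id, sample = sample,
                   est_counts = fit$est_counts, tpm = fit$tpm)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("iso_expression", class(out))
  out
}

# Vectorised Poisson likelihood-ratio test with library-size offsets.
# y_a, y_b: isoform x replicate count matrices; n_a, n_b: library sizes.
poisson_lrt <- function(y_a, n_a, y_b, n_b) {
  Ta <- rowSums(y_a); Tb <- rowSums(y_b)
  Na <- sum(n_a); Nb <- sum(n_b)
  xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)
  # profile log-likelihood terms (base measure cancels in the ratio)
  ll_alt <- xlogy(Ta, Ta / Na) + xlogy(Tb, Tb / Nb)
  ll_null <- xlogy(Ta + Tb, (Ta + Tb) / (Na + Nb))
  dev <- 2 * (ll_alt - ll_null)
  dev[dev < 0] <- 0
  pchisq(dev, df = 1, lower.tail = FALSE)
}

#' Screen differential isoform expression between two conditions
#'
#' Per-isoform p-values come from a likelihood-ratio test under a Poisson
#' model with library-size offsets on expected counts (a documented
#' stand-in; any external count table can be supplied through `expr`).
#' BH adjustment is applied across isoforms.  An isoform passes when
#' `p < p_cutoff`, `FDR < fdr_cutoff` and `|log2FC| >= log2(min_fold)`.
#'
#' @param expr long expression tibble (`isoform_id`, `sample`,
#'   `est_counts`), e.g. from [quantify_samples()].
#' @param design tibble mapping `sample` to `condition`.
#' @param cond_a,cond_b condition labels to compare (fold change is B over
#'   A).
#' @param p_cutoff,fdr_cutoff,min_fold screening cutoffs.
#' @param pseudo_count added to normalised means before fold change.
#' @return tibble of class `iso_de`: `isoform_id`, `mean_a`, `mean_b`,
#'   `log2_fc`, `p_value`, `fdr`, `pass`, `direction`.
#' @export
de_screen <- function(expr, design, cond_a, cond_b,
                      p_cutoff = 0.05, fdr_cutoff = 0.01, min_fold = 2,
                      pseudo_count = 0.5) {
  abort_if(!all(c(cond_a, cond_b) %in% design$condition),
           "unknown condition label")
  samp_a <- design$sample[design$condition == cond_a]
  samp_b <- design$sample[design$condition == cond_b]
  abort_if(length(samp_a) < 1 || length(samp_b) < 1,
           "each condition needs at least one sample")
  if (length(samp_a) == 1 || length(samp_b) == 1) {
    warning("single-replicate condition: the test degrades to a ",
            "count-ratio test")
  }
  wide <- tidyr::pivot_wider(expr[expr$sample %in% c(samp_a, samp_b),
                                  c("isoform_id", "sample", "est_counts")],
                             names_from = "sample",
                             values_from = "est_counts", values_fill = 0)
  y <- as.matrix(wide[, -1])
  rownames(y) <- wide$isoform_id
  lib <- colSums(y)
  y_a <- y[, samp_a, drop = FALSE]; y_b <- y[, samp_b, drop = FALSE]
  n_a <- lib[samp_a]; n_b <- lib[samp_b]
  p <- poisson_lrt(y_a, n_a, y_b, n_b)
  mean_lib <- mean(lib)
  norm_a <- rowMeans(sweep(y_a, 2, n_a / mean_lib, "/"))
  norm_b <- rowMeans(sweep(y_b, 2, n_b / mean_lib, "/"))
  log2_fc <- log2((norm_b + pseudo_count) / (norm_a + pseudo_count))
  fdr <- stats::p.adjust(p, method = "BH")
  pass <- p < p_cutoff & fdr < fdr_cutoff & abs(log2_fc) >= log2(min_fold)
  out <- tibble::tibble(
    isoform_id = rownames(y), mean_a = norm_a, mean_b = norm_b,
    log2_fc = log2_fc, p_value = unname(p), fdr = unname(fdr),
    pass = unname(pass),
    direction = dplyr::case_when(log2_fc > 0 ~ "up", log2_fc < 0 ~ "down",
                                 TRUE ~ "none"))
  class(out) <- c("iso_de", class(out))
  out
}

#' Isoforms consistently specific to one condition
#'
#' Runs [de_screen()] of the focal condition against every other condition
#' and intersects: an isoform is focal-specific (direction `"up"` or
#' `"down"`) only when it passes the triple cutoff in that direction
#' against each of the others.
#'
#' @param expr,design see [de_screen()].
#' @param focal focal condition label.
#' @param direction `"up"` (highest in focal) or `"down"` (lowest).
#' @param ... cutoffs passed to [de_screen()].
#' @return a list: `isoforms` (character vector, the intersection),
#'   `per_comparison` (named list of per-condition passing sets), and
#'   `screens` (named list of `iso_de` tibbles).
#' @export
tissue_specific <- function(expr, design, focal,
                            direction = c("up", "down"), ...) {
  direction <- match.arg(direction)
  others <- setdiff(unique(design$condition), focal)
  abort_if(length(others) < 1, "need at least two conditions")
  screens <- lapply(others, function(cond) {
    # fold change is focal over other: compare other (A) vs focal (B)
    de_screen(expr, design, cond_a = cond, cond_b = focal, ...)
  })
  names(screens) <- others
  per_comparison <- lapply(screens, function(de)
    de$isoform_id[de$pass & de$direction == direction])
  isoforms <- Reduce(intersect, per_comparison)
  list(isoforms = sort(isoforms), per_comparison = per_comparison,
       screens = screens)
}
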