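# Compatibility classes, EM abundance, differential screening and the
# tissue-specific intersection.

toy_reference <- function() {
  set.seed(21)
  shared <- rand_seq(400)
  tibble::tibble(id = c("X", "Y", "Z"),
                 seq = c(paste0(shared, rand_seq(400)),
                         paste0(shared, rand_seq(300)),
                         rand_seq(500)))
}

test_that("compatibility classes reflect substring containment and conserve reads", {
  ref <- toy_reference()
  reads <- as_seq_tbl(c(r1 = substr(ref$seq[1], 500, 574),   # X only
                        r2 = substr(ref$seq[1], 100, 174),   # shared X/Y
                        r3 = substr(ref$seq[3], 10, 84),     # Z only
                        r4 = paste(rep("A", 75), collapse = "")),
                      role = "short_read")
  compat <- build_compatibility(reads, ref)
  sets <- lapply(compat$isoforms, sort)
  expect_true(list(c("X")) %in% sets || any(vapply(sets, identical,
                                                   logical(1), "X")))
  expect_true(any(vapply(sets, identical, logical(1), c("X", "Y"))))
  expect_true(any(vapply(sets, identical, logical(1), "Z")))
  expect_equal(sum(compat$weight), attr(compat, "n_mapped"))
  expect_equal(attr(compat, "n_mapped") + attr(compat, "n_unmapped"),
               nrow(reads))
  expect_equal(attr(compat, "n_unmapped"), 1L)
})

test_that("EM equals direct counting when every read is unique, splits ties evenly", {
  lens <- c(X = 1000, Y = 1000)
  unique_tbl <- tibble::tibble(class_id = c("1", "2"),
                               isoforms = list("X", "Y"),
                               weight = c(300L, 100L))
  attr(unique_tbl, "read_len") <- 75
  fit <- em_abundance(unique_tbl, lens)
  expect_equal(fit$est_counts, c(300, 100), tolerance = 1e-6)
  expect_equal(sum(fit$est_counts), 400)

  shared <- tibble::tibble(class_id = "1", isoforms = list(c("X", "Y")),
                           weight = 400L)
  attr(shared, "read_len") <- 75
  fit2 <- em_abundance(shared, lens)
  expect_equal(fit2$theta, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(fit2$tpm), 1e6, tolerance = 1e-3)
})

test_that("EM recovers a 70/20/10 three-isoform mixture within 2 points from 20k reads", {
  set.seed(23)
  models <- sim_genes(1, exon_count_range = c(6L, 6L),
                      exon_len_range = c(200L, 300L),
                      n_isoform_range = c(3L, 3L), p_short_exon = 0,
                      seed = 23)
  iso <- models$isoforms
  iso$base_abundance <- c(0.7, 0.2, 0.1)
  models$isoforms <- iso
  design <- tibble::tibble(sample = "s1", condition = "one", replicate = 1L)
  sr <- sim_short_reads(models, design, read_len = 75, depth = 20000,
                        seed = 23)
  ref <- tibble::tibble(id = iso$isoform_id, seq = iso$seq)
  compat <- build_compatibility(sr$samples$s1, ref)
  fit <- em_abundance(compat, setNames(nchar(ref$seq), ref$id))
  # the planted 70/20/10 mixture is molar, i.e. the TPM fraction
  molar <- fit$tpm / 1e6
  expect_true(all(abs(molar - iso$base_abundance[match(fit$isoform_id,
                                                       iso$isoform_id)])
                  <= 0.02))
  # likelihood is monotonically non-decreasing across iterations
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) >= -1e-9))
  expect_equal(sum(fit$est_counts), attr(compat, "n_mapped"))
})

test_that("BH adjustment matches the hand-computed procedure on a fixed vector", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  # hand-applied BH: p_(i) * n / i, cumulative minimum from the largest
  n <- length(p)
  o <- order(p)
  raw <- p[o] * n / seq_len(n)
  hand <- rev(cummin(rev(raw)))[order(o)]
  expect_equal(hand, c(0.005, 0.025, 1 / 30, 0.05, 0.2), tolerance = 1e-9)
  expect_equal(stats::p.adjust(p, "BH"), hand)
})

test_that("identical conditions yield zero fold change and no passing isoform", {
  expr <- tidyr::crossing(isoform_id = sprintf("i%02d", 1:20),
                          sample = c("a_1", "a_2", "b_1", "b_2"))
  set.seed(31)
  counts <- stats::rpois(20, 100)
  expr$est_counts <- rep(counts, each = 4)
  design <- tibble::tibble(sample = c("a_1", "a_2", "b_1", "b_2"),
                           condition = c("a", "a", "b", "b"))
  de <- de_screen(expr, design, "a", "b")
  expect_true(all(de$log2_fc == 0))
  expect_false(any(de$pass))
  expect_error(de_screen(expr, design, "a", "nope"), "condition")
})

test_that("a planted four-fold isoform passes the triple cutoff with the right direction", {
  set.seed(29)
  n_iso <- 60
  base <- stats::rpois(n_iso, 200) + 50
  design <- tibble::tibble(sample = c(paste0("a_", 1:3), paste0("b_", 1:3)),
                           condition = rep(c("a", "b"), each = 3))
  mu <- cbind(matrix(base, n_iso, 3), matrix(base, n_iso, 3))
  mu[7, 4:6] <- base[7] * 4   # planted up in b
  mu[13, 4:6] <- base[13] / 4 # planted down in b
  counts <- matrix(stats::rpois(length(mu), mu), n_iso)
  expr <- tibble::tibble(
    isoform_id = rep(sprintf("i%02d", 1:n_iso), 6),
    sample = rep(design$sample, each = n_iso),
    est_counts = as.vector(counts))
  de <- de_screen(expr, design, "a", "b")
  expect_true(de$pass[de$isoform_id == "i07"])
  expect_equal(de$direction[de$isoform_id == "i07"], "up")
  expect_true(de$pass[de$isoform_id == "i13"])
  expect_equal(de$direction[de$isoform_id == "i13"], "down")
  expect_lt(sum(de$pass), 5)
  g <- glance(de)
  expect_equal(g$n_pass, sum(de$pass))
})

test_that("null simulations keep the p < 0.05 rate inside binomial 99% bounds", {
  set.seed(37)
  design <- tibble::tibble(sample = c(paste0("a_", 1:3), paste0("b_", 1:3)),
                           condition = rep(c("a", "b"), each = 3))
  n_iso <- 100
  hits <- 0L
  total <- 0L
  for (run in 1:20) {
    mu <- stats::runif(n_iso, 50, 300)
    counts <- matrix(stats::rpois(n_iso * 6, rep(mu, 6)), n_iso)
    expr <- tibble::tibble(
      isoform_id = rep(sprintf("i%03d", 1:n_iso), 6),
      sample = rep(design$sample, each = n_iso),
      est_counts = as.vector(counts))
    de <- de_screen(expr, design, "a", "b")
    hits <- hits + sum(de$p_value < 0.05)
    total <- total + n_iso
  }
  rate <- hits / total
  half_width <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / total)
  expect_gte(rate, 0.05 - half_width)
  expect_lte(rate, 0.05 + half_width)
})

test_that("tissue-specific isoforms are the intersection over every comparison", {
  set.seed(41)
  conds <- c("root", "stem", "leaf", "flower")
  design <- sim_design(conds, replicates = 3)
  n_iso <- 40
  base <- stats::rpois(n_iso, 300) + 100
  mu <- matrix(rep(base, nrow(design)), n_iso)
  colnames(mu) <- design$sample
  # i01: up in root vs all; i02: up vs stem and leaf only
  mu[1, design$condition == "root"] <- base[1] * 5
  mu[2, design$condition == "root"] <- base[2] * 5
  mu[2, design$condition == "flower"] <- base[2] * 5
  counts <- matrix(stats::rpois(length(mu), mu), n_iso)
  expr <- tibble::tibble(
    isoform_id = rep(sprintf("i%02d", 1:n_iso), nrow(design)),
    sample = rep(design$sample, each = n_iso),
    est_counts = as.vector(counts))
  up <- tissue_specific(expr, design, "root", "up")
  expect_true("i01" %in% up$isoforms)
  expect_false("i02" %in% up$isoforms)   # fails vs flower
  expect_true("i02" %in% up$per_comparison$stem)
  down <- tissue_specific(expr, design, "root", "down")
  expect_length(intersect(up$isoforms, down$isoforms), 0)
})
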