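# Independent alignment oracles, coded from the scoring definition alone:
# affine gaps (cost = open + L * extend), global in the query, local in
# the target, N scores as mismatch.  Tie policy mirrors the package's
# documented canonical order (diagonal, then target gap, then query gap;
# strict improvement to switch; leftmost end cell), implemented here from
# scratch against the definition.

# score-only oracle, vectorised per row -- handles pairs up to ~300 bp fast
oracle_score <- function(q, t, match = 1, mis = 2, go = 4, ge = 0.25,
                         free_ends = FALSE) {
  qb <- strsplit(q, "")[[1]]
  tb <- strsplit(t, "")[[1]]
  n <- length(qb); m <- length(tb)
  NEG <- -1e30
  Mp <- rep(NEG, m + 1); Ip <- rep(NEG, m + 1); Tp <- rep(NEG, m + 1)
  best <- NEG
  for (i in seq_len(n)) {
    s <- ifelse(tb == qb[i] & qb[i] != "N", match, -mis)
    diag_prev <- pmax(Mp, Tp, Ip)[seq_len(m)]          # states at (i-1, j-1)
    start_ok <- free_ends || i == 1
    if (start_ok) diag_prev <- pmax(diag_prev, 0)
    Mc <- c(NEG, diag_prev + s)
    Ic <- pmax(Mp - go - ge, Ip - ge)                  # query gap
    # leading query gap before any target base (start-anchored)
    Ic[1] <- if (free_ends) NEG else -(go + ge * i)
    # target gap: It[j] = -ge*j + cummax(Mc[k] - go + ge*k), k < j
    k <- 0:m
    run <- cummax(Mc - go + ge * k)
    Tc <- c(NEG, run[seq_len(m)] - ge * (1:m))
    if (i == n || free_ends) best <- max(best, Mc)
    Mp <- Mc; Ip <- Ic; Tp <- Tc
  }
  if (best <= 0) return(NULL)
  best
}

# full traceback oracle (slow loops) -- for small pairs; returns score and
# the block structure
oracle_align <- function(q, t, match = 1, mis = 2, go = 4, ge = 0.25,
                         free_ends = FALSE) {
  qb <- strsplit(q, "")[[1]]
  tb <- strsplit(t, "")[[1]]
  n <- length(qb); m <- length(tb)
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1)
  Iq <- matrix(NEG, n + 1, m + 1)
  It <- matrix(NEG, n + 1, m + 1)
  pM <- matrix(NA_integer_, n + 1, m + 1)  # 1=M 2=IT 3=IQ 0=START
  pQ <- matrix(NA_integer_, n + 1, m + 1)  # 1=M 3=IQ
  pT <- matrix(NA_integer_, n + 1, m + 1)  # 1=M 2=IT
  for (i in 1:n) {
    # column 0: leading query gap (disabled under free query ends)
    if (!free_ends) {
      if (i == 1) { Iq[2, 1] <- -(go + ge); pQ[2, 1] <- 0L }
      else if (Iq[i, 1] > NEG) {
        Iq[i + 1, 1] <- Iq[i, 1] - ge; pQ[i + 1, 1] <- 3L
      }
    }
    for (j in 1:m) {
      s <- if (qb[i] == tb[j] && qb[i] != "N") match else -mis
      # M: order M, IT, IQ, START; strict improvement to switch
      v <- M[i, j]; p <- 1L
      if (It[i, j] > v) { v <- It[i, j]; p <- 2L }
      if (Iq[i, j] > v) { v <- Iq[i, j]; p <- 3L }
      if ((free_ends || i == 1) && 0 > v) { v <- 0; p <- 0L }
      if (v > NEG / 2) { M[i + 1, j + 1] <- v + s; pM[i + 1, j + 1] <- p }
      # Iq: from M or Iq above
      vq <- M[i, j + 1] - go - ge; pq <- 1L
      if (Iq[i, j + 1] - ge > vq) { vq <- Iq[i, j + 1] - ge; pq <- 3L }
      if (vq > NEG / 2) { Iq[i + 1, j + 1] <- vq; pQ[i + 1, j + 1] <- pq }
      # It: from M or It on the left (current row)
      vt <- M[i + 1, j] - go - ge; pt <- 1L
      if (It[i + 1, j] - ge > vt) { vt <- It[i + 1, j] - ge; pt <- 2L }
      if (vt > NEG / 2) { It[i + 1, j + 1] <- vt; pT[i + 1, j + 1] <- pt }
    }
  }
  best <- NEG; bi <- -1L; bj <- -1L
  rows <- if (free_ends) 1:n else n
  for (i in rows) for (j in 1:m) {
    if (M[i + 1, j + 1] > best) { best <- M[i + 1, j + 1]; bi <- i; bj <- j }
  }
  if (bi < 0 || best <= 0) return(NULL)
  # traceback
  i <- bi; j <- bj; st <- 1L
  cols <- list()
  repeat {
    cols[[length(cols) + 1]] <- c(st, i, j)
    prev <- if (st == 1L) pM[i + 1, j + 1] else if (st == 3L)
      pQ[i + 1, j + 1] else pT[i + 1, j + 1]
    if (st == 1L) { i <- i - 1; j <- j - 1 }
    else if (st == 3L) { i <- i - 1 }
    else { j <- j - 1 }
    if (is.na(prev) || prev == 0L) break
    if (st == 1L && i == 0) break
    st <- prev
  }
  path <- do.call(rbind, rev(cols))  # columns: state, i, j (1-based ends)
  # trim terminal gap runs
  ms <- which(path[, 1] == 1L)
  path <- path[min(ms):max(ms), , drop = FALSE]
  size <- integer(0); qs <- integer(0); ts <- integer(0)
  matches <- 0L; mismatches <- 0L
  in_block <- FALSE
  for (r in seq_len(nrow(path))) {
    st0 <- path[r, 1]; qi <- path[r, 2]; tj <- path[r, 3]
    if (st0 == 1L) {
      if (!in_block) {
        size <- c(size, 0L); qs <- c(qs, qi - 1L); ts <- c(ts, tj - 1L)
        in_block <- TRUE
      }
      size[length(size)] <- size[length(size)] + 1L
      if (qb[qi] == tb[tj] && qb[qi] != "N") matches <- matches + 1L
      else mismatches <- mismatches + 1L
    } else in_block <- FALSE
  }
  list(score = best, matches = matches, mismatches = mismatches,
       blocks = data.frame(size = size, q_start = qs, t_start = ts))
}

# score implied by a returned alignment record (blocks + gaps), under the
# default scoring scheme -- used to check block-structure optimality
record_score <- function(aln, match = 1, mis = 2, go = 4, ge = 0.25) {
  b <- aln$blocks[[1]]
  gaps <- 0
  if (nrow(b) > 1) {
    dq <- b$q_start[-1] - (b$q_start[-nrow(b)] + b$size[-nrow(b)])
    dt <- b$t_start[-1] - (b$t_start[-nrow(b)] + b$size[-nrow(b)])
    gaps <- sum(ifelse(dq > 0, go + ge * dq, 0)) +
      sum(ifelse(dt > 0, go + ge * dt, 0))
  }
  # unaligned query ends are trimmed from records; when the query is
  # global they were paid as gaps in the DP, so account for them
  lead <- aln$q_start
  trail <- aln$q_size - aln$q_end
  end_cost <- sum(ifelse(c(lead, trail) > 0, go + ge * c(lead, trail), 0))
  aln$matches * match - aln$mismatches * mis - gaps - end_cost
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# mutate a sequence with substitutions only (oracle-side helper)
mutate_subs <- function(s, k) {
  b <- strsplit(s, "")[[1]]
  pos <- sample(length(b), min(k, length(b)))
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}

# canonical (left-normalised) placement of a target-side gap: an alignment
# gap's position is defined only up to shared bases at its junction, and
# the deterministic tie-break shifts it leftmost (as variant callers
# normalise deletions).  `s`, `e`: 0-based half-open gap on `contig`.
leftnorm_gap <- function(contig, s, e) {
  ch <- strsplit(contig, "")[[1]]
  while (s > 0 && ch[s] == ch[e]) { s <- s - 1; e <- e - 1 }
  c(s, e)
}
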