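# Independent oracles used to check the package's implementations.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force maximum base pairing by exhaustive enumeration of all
# non-crossing structures (no memoization, no shared code with the DP).
bf_pairable <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

bf_max_pairs <- function(seq, min_loop = 3) {
  chars <- strsplit(toupper(seq), "")[[1]]
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i, j - 1L) # j unpaired
    for (k in i:(j - min_loop - 1L)) {
      if (bf_pairable(chars[k], chars[j])) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        inner <- rec(k + 1L, j - 1L)
        best <- max(best, left + inner + 1L)
      }
    }
    best
  }
  if (length(chars) < 2) return(0L)
  rec(1L, length(chars))
}

# Position-by-position IUPAC matcher (single strand), independent of the
# bitmask implementation.
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
  H = c("A", "C", "T"), D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

naive_iupac_scan <- function(seq, pattern, max_mismatch = 0) {
  sc <- strsplit(toupper(seq), "")[[1]]
  pc <- strsplit(toupper(pattern), "")[[1]]
  m <- length(pc); n <- length(sc)
  hits <- integer(0); mms <- integer(0)
  if (m > n) return(data.frame(start = hits, mismatches = mms))
  for (i in seq_len(n - m + 1)) {
    mm <- 0L
    for (j in seq_len(m)) {
      if (!(sc[i + j - 1] %in% iupac_sets[[pc[j]]])) mm <- mm + 1L
    }
    if (mm <= max_mismatch) { hits <- c(hits, i); mms <- c(mms, mm) }
  }
  data.frame(start = hits, mismatches = mms)
}

# O(n^2) transitive-closure clustering of sites on a line.
cluster_oracle <- function(starts, ends, threshold) {
  n <- length(starts)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gap <- max(starts[j] - ends[i] - 1L, starts[i] - ends[j] - 1L)
      adj[i, j] <- gap <= threshold
    }
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        new <- which(adj[f, ] & comp == 0L)
        comp[new] <- cur
        nxt <- c(nxt, new)
      }
      frontier <- nxt
    }
  }
  comp
}

# Rotation-to-origin oracle for leading/lagging assignment: rotate the
# circular genome so the OriC midpoint is base 1, then replichore 1 is
# simply the first ceiling(L/2) bases.
rotation_strand_oracle <- function(L, oric_mid, start, end, strand) {
  rot <- function(p) ((p - oric_mid) %% L) + 1L
  mid <- rot((start + end) %/% 2L)
  in_r1 <- mid <= ceiling(L / 2)
  if ((in_r1 && strand == "+") || (!in_r1 && strand == "-")) "leading"
  else "lagging"
}

# dinucleotide shuffle: permute non-overlapping dinucleotide blocks
dinuc_shuffle <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars) - length(chars) %% 2
  blocks <- split(chars[1:n], rep(1:(n / 2), each = 2))
  paste(c(unlist(sample(blocks)), chars[setdiff(seq_along(chars), 1:n)]),
        collapse = "")
}
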