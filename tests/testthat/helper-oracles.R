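# Independent oracles used to compute expected values. These deliberately
# use naive algorithms distinct from the package implementation.

# Brute-force tryptic digest: build the 0-missed-cleavage partition by
# direct rule application, then enumerate every contiguous join of up to
# `mc` adjacent fragments.
oracleDigest <- function(sequence, mc = 0L) {
  res <- strsplit(sequence, "")[[1]]
  frags <- character()
  cur <- ""
  for (i in seq_along(res)) {
    cur <- paste0(cur, res[i])
    nxt <- if (i < length(res)) res[i + 1L] else ""
    if (res[i] %in% c("K", "R") && nxt != "P" && i < length(res)) {
      frags <- c(frags, cur); cur <- ""
    }
  }
  frags <- c(frags, cur)
  out <- character()
  for (m in 0:mc)
    for (i in seq_len(max(0L, length(frags) - m)))
      out <- c(out, paste(frags[i:(i + m)], collapse = ""))
  out
}

# Atom-by-atom isotope convolution: multiplies in one atom at a time
# (O(total atoms) naive polynomial products), unlike the implementation's
# exponentiation by squaring.
oracleIsotopes <- function(composition, max_peaks = 5L) {
  polymul <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a))
      for (j in seq_along(b))
        out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    out
  }
  counts <- floor(composition + 0.5)
  dist <- 1
  for (el in names(counts))
    if (counts[el] > 0)
      for (k in seq_len(counts[el]))
        dist <- polymul(dist, HCPprofiler::ISOTOPE_ABUNDANCE[[el]])
  dist <- dist[seq_len(min(length(dist), max_peaks))]
  dist / sum(dist)
}

# Exhaustive score-threshold scan for the PSM FDR filter: try every
# observed score as threshold, keep the one maximizing accepted targets
# subject to the decoy/target ratio constraint.
oracleFdrThreshold <- function(scores, decoy, q) {
  best_t <- Inf; best_n <- 0L
  for (t in sort(unique(scores))) {
    nt <- sum(scores >= t & !decoy)
    nd <- sum(scores >= t & decoy)
    if (nd / max(nt, 1L) <= q && nt > best_n) {
      best_n <- nt; best_t <- t
    }
  }
  list(threshold = best_t, n_target = best_n)
}

# Naive agglomerative clustering with complete linkage on a distance
# matrix; returns merge heights in order.
oracleCompleteLinkage <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(j, i) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Standard residue elemental compositions (C, H, N, O, S) for building the
# true isotope envelope of a peptide, independent of the averagine model.
RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0), A = c(3, 5, 1, 1, 0),
  S = c(3, 5, 1, 2, 0), P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0),
  T = c(4, 7, 1, 2, 0), C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0),
  I = c(6, 11, 1, 1, 0), N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0),
  Q = c(5, 8, 2, 2, 0), K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),
  M = c(5, 9, 1, 1, 1), H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0),
  R = c(6, 12, 4, 1, 0), Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))
RESIDUE_FORMULA <- lapply(RESIDUE_FORMULA, function(x)
  setNames(as.numeric(x), c("C", "H", "N", "O", "S")))

peptideFormula <- function(peptide) {
  res <- strsplit(peptide, "")[[1]]
  comp <- Reduce(`+`, RESIDUE_FORMULA[res])
  comp + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # add water
}

# Random peptide-like sequence
randomSequence <- function(n, letters = names(HCPprofiler::RESIDUE_MONO_MASS)) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
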