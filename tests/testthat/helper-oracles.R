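# Independent reference implementations used as oracles.  These are kept
# deliberately plain (full matrices, explicit loops) and mirror the stated
# conventions: gap of length k costs open + k*extend; traceback ties prefer
# diagonal, then up, then left; the traceback start is the first maximal
# match-state cell in row-major order; local alignments stop at score zero.

oracle_local_align <- function(q, t, scheme) {
  mat <- scheme$matrix
  go <- scheme$gap_open; ge <- scheme$gap_extend
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  IX <- matrix(NEG, n + 1, m + 1)
  IY <- matrix(NEG, n + 1, m + 1)
  for (i in 1:n) for (j in 1:m) {
    M[i + 1, j + 1] <- max(0, M[i, j], IX[i, j], IY[i, j]) +
      mat[qc[i], tc[j]]
    IX[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, IX[i, j + 1] - ge)
    IY[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, IY[i + 1, j] - ge)
  }
  best <- max(M)
  if (best <= 0) return(NULL)
  # first maximal cell in row-major order
  hit <- which(t(M) == best, arr.ind = TRUE)[1, ]
  i <- hit[2]; j <- hit[1]
  state <- "M"; overlap <- 0; matches <- 0
  repeat {
    if (state == "M") {
      overlap <- overlap + 1
      if (qc[i - 1] == tc[j - 1] && qc[i - 1] != "X")
        matches <- matches + 1
      prev <- M[i, j] - mat[qc[i - 1], tc[j - 1]]
      pi <- i - 1; pj <- j - 1
      if (prev <= 0) break
      state <- if (M[pi, pj] == prev) "M" else
        if (IX[pi, pj] == prev) "IX" else "IY"
      i <- pi; j <- pj
    } else if (state == "IX") {
      cur <- IX[i, j]
      state <- if (M[i - 1, j] - go - ge == cur) "M" else "IX"
      i <- i - 1
    } else {
      cur <- IY[i, j]
      state <- if (M[i, j - 1] - go - ge == cur) "M" else "IY"
      j <- j - 1
    }
  }
  list(score = best, overlap = overlap, matches = matches,
       identity_pct = 100 * matches / overlap)
}

# Exhaustive minimum-loss oracle under a single-gain constraint: enumerate
# every internal presence/absence labelling; a labelling is admissible when
# it implies exactly one gain (the root stem counts as a gain when the root
# is present); return the minimum loss count over admissible labellings.
oracle_min_losses <- function(tree, presence) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  root <- ntip + 1L
  presence <- presence[tree$tip.label]
  state_of <- function(lab, v)
    if (v <= ntip) presence[[v]] else lab[v - ntip]
  best <- Inf
  for (code in 0:(2^nint - 1)) {
    lab <- as.integer(intToBits(code)[1:nint])
    gains <- state_of(lab, root)
    losses <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- state_of(lab, tree$edge[e, 1])
      c <- state_of(lab, tree$edge[e, 2])
      if (p == 0 && c == 1) gains <- gains + 1L
      if (p == 1 && c == 0) losses <- losses + 1L
    }
    if (gains == 1L && losses < best) best <- losses
  }
  best
}

random_protein <- function(len, alphabet = c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
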