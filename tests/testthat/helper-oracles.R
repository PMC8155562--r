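# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Digestion oracle: evaluate the cleavage predicate at every bond, then
# enumerate every missed-cleavage join explicitly.
oracle_digest <- function(sequence, cut_after = c("K", "R"), suppress = "P",
                          missed = 0, min_len = 1, max_len = Inf) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut_after_bond <- logical(n - 1)
  for (i in seq_len(n - 1)) {
    cut_after_bond[i] <- res[i] %in% cut_after && !(res[i + 1] %in% suppress)
  }
  bounds <- c(0, which(cut_after_bond), n)
  segs <- data.frame(start = bounds[-length(bounds)] + 1, end = bounds[-1])
  out <- list()
  for (mc in 0:missed) {
    for (i in seq_len(nrow(segs))) {
      j <- i + mc
      if (j > nrow(segs)) next
      s <- segs$start[i]; e <- segs$end[j]
      out[[length(out) + 1]] <- data.frame(
        peptide = paste(res[s:e], collapse = ""),
        start = s, end = e, missed_cleavages = mc,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  len <- df$end - df$start + 1
  df <- df[len >= min_len & len <= max_len, , drop = FALSE]
  df[order(df$start, df$missed_cleavages), , drop = FALSE]
}

# Fragment-mass oracle: explicit per-residue sums, no cumsum.
oracle_fragment_mz <- function(peptide, series, ordinal, charge,
                               masses = gtlkit::residue_masses()) {
  res <- strsplit(peptide, "")[[1]]
  proton <- 1.007276466
  water <- 18.0105646
  piece <- if (series == "b") res[1:ordinal] else rev(rev(res)[1:ordinal])
  neutral <- 0
  for (r in piece) neutral <- neutral + masses[[r]]
  if (series == "y") neutral <- neutral + water
  (neutral + charge * proton) / charge
}

# Multi-library combination oracle: the three precedence sentences applied
# literally per peptide group.
oracle_combine <- function(results, own_id) {
  keys <- unique(unlist(lapply(results, function(df) {
    paste(df$peptide, df$charge, sep = "/")
  })))
  rows <- lapply(keys, function(k) {
    present <- Filter(function(id) {
      any(paste(results[[id]]$peptide, results[[id]]$charge, sep = "/") == k)
    }, names(results))
    grab <- function(id) {
      df <- results[[id]]
      r <- df[paste(df$peptide, df$charge, sep = "/") == k, , drop = FALSE]
      r$source_library <- id
      r
    }
    if (own_id %in% present) return(grab(own_id))            # rule 1
    if (length(present) == 1) return(grab(present))          # rule 2
    recs <- do.call(rbind, lapply(present, grab))            # rule 3
    recs[order(recs$pvalue, recs$source_library)[1], , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out[order(out$peptide, out$charge), , drop = FALSE]
}

# O(m^2) Benjamini-Hochberg oracle, straight from the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  rank_of <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min(p[p >= p[i]] * m / rank_of[p >= p[i]]))
  }, 0)
}

# Exhaustive maximum-clique oracle over an adjacency matrix (n <= 15 or so).
oracle_max_clique_size <- function(adj) {
  n <- nrow(adj)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    v <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(v) <= best) next
    ok <- TRUE
    if (length(v) > 1) {
      for (a in seq_along(v)[-length(v)]) {
        for (b in (a + 1):length(v)) {
          if (!adj[v[a], v[b]]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- length(v)
  }
  best
}

# Random peptide helper for property tests.
random_peptide <- function(len, residues = names(gtlkit::residue_masses())) {
  paste(sample(residues, len, replace = TRUE), collapse = "")
}
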