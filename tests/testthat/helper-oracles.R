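# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately share no code with the implementation paths they check.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT <- c("A", "C", "G", "T")

random_protein <- function(n) paste(sample(AA, n, replace = TRUE),
                                    collapse = "")
random_dna <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

# position-by-position degenerate pattern check on one window
oracle_pattern_hits <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  w <- length(positions)
  hits <- integer()
  if (length(chars) >= w) {
    for (off in 0:(length(chars) - w)) {
      match <- TRUE
      for (j in seq_len(w)) {
        if (!(chars[off + j] %in% positions[[j]])) { match <- FALSE; break }
      }
      if (match) hits <- c(hits, off)
    }
  }
  hits
}

# window-by-window PSWM scoring
oracle_pswm_scores <- function(seq, scores) {
  chars <- strsplit(seq, "")[[1]]
  w <- nrow(scores)
  n <- length(chars)
  if (n < w) return(numeric())
  vapply(0:(n - w), function(off) {
    tot <- 0
    for (j in seq_len(w)) tot <- tot + scores[j, chars[off + j]]
    tot
  }, numeric(1))
}

# plain affine-gap Smith-Waterman DP, score only (Gotoh three-state)
oracle_sw_score <- function(a, b, mat, gap_open, gap_extend) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1)      # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1)   # gap in b (up)
  Y <- matrix(-Inf, n + 1, m + 1)   # gap in a (left)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      s <- mat[x[i - 1], y[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i - 1, j - 1] + s,
                     Y[i - 1, j - 1] + s)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# --- independent NG86 enumeration ------------------------------------------

oracle_codon_table <- function() Biostrings::GENETIC_CODE

# synonymous-site count of one codon: recursion-free re-derivation
oracle_syn_sites <- function(codon, code = oracle_codon_table()) {
  total <- 0
  for (p in 1:3) {
    syn <- 0; valid <- 0
    for (b in NT) {
      if (b == substr(codon, p, p)) next
      mut <- paste0(substr(codon, 1, p - 1), b, substr(codon, p + 1, 3))
      if (code[[mut]] == "*") next
      valid <- valid + 1
      if (code[[mut]] == code[[codon]]) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# recursive enumeration of all stop-free substitution pathways between two
# sense codons; returns average (syn, nonsyn) step counts or NULL
oracle_path_counts <- function(c1, c2, code = oracle_codon_table()) {
  walk <- function(cur) {
    diff <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(diff) == 0) return(list(c(s = 0, n = 0)))
    out <- list()
    for (p in diff) {
      nxt <- paste0(substr(cur, 1, p - 1), substr(c2, p, p),
                    substr(cur, p + 1, 3))
      if (code[[nxt]] == "*") next
      step <- if (code[[nxt]] == code[[cur]]) c(s = 1, n = 0) else
        c(s = 0, n = 1)
      for (tail in walk(nxt)) out[[length(out) + 1]] <- step + tail
    }
    out
  }
  paths <- walk(c1)
  if (length(paths) == 0) return(NULL)
  Reduce(`+`, paths) / length(paths)
}

# whole-alignment pi over a region: direct recount
oracle_region_pi <- function(a, b, from1, to1) {
  x <- strsplit(substr(a, from1, to1), "")[[1]]
  y <- strsplit(substr(b, from1, to1), "")[[1]]
  valid <- x %in% NT & y %in% NT
  sum(x[valid] != y[valid]) / sum(valid)
}
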