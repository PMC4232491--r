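# Nucleotide diversity (pi) and Nei-Gojobori (1986) counting dN/dS.
#
# pi is the proportion of differing valid sites between aligned rows (a site
# is valid when neither row has a gap or ambiguity there). dN/dS follows the
# classic NG86 recipe: per-codon synonymous-site fractions from exhaustive
# single-nucleotide mutation enumeration, pathway-averaged difference counts
# for multi-substitution codons, and Jukes-Cantor (1969) distance correction.

#' Pairwise nucleotide diversity
#'
#' @param a,b Equal-length (gapped) nucleotide rows.
#' @return List with `pi` (differing / valid sites; `NA` when no site is
#'   valid, with a warning) and `valid_sites`.
#' @examples
#' pairwise_pi("AA-A", "AATA")   # gap column excluded: 0 over 3 sites
#' @export
pairwise_pi <- function(a, b) {
  x <- strsplit(toupper(unname(a)), "")[[1]]
  y <- strsplit(toupper(unname(b)), "")[[1]]
  if (length(x) != length(y)) stop("rows have unequal lengths")
  valid <- x %in% NT_ALPHABET & y %in% NT_ALPHABET
  n <- sum(valid)
  if (n == 0L) {
    warning("no valid sites; pi undefined")
    return(list(pi = NA_real_, valid_sites = 0L))
  }
  list(pi = sum(x[valid] != y[valid]) / n, valid_sites = n)
}

#' Sliding-window nucleotide diversity
#'
#' Windows are laid out in alignment coordinates (gaps occupy coordinates but
#' are excluded from pi) starting at 0 and advancing by `step` while
#' `start + window <= length`; a trailing partial window is dropped. For
#' alignments of more than two rows the window pi is the mean over all row
#' pairs.
#'
#' @param aln Named character vector of 2+ equal-length nucleotide rows.
#' @param window Window size in alignment columns (default 100).
#' @param step Step size in columns (default 25).
#' @return data.frame: `start` (0-based inclusive), `end` (0-based
#'   exclusive), `midpoint`, `pi` (`NA` when a window has no valid site in
#'   some pair), `valid_sites` (minimum over pairs). Empty (with a warning)
#'   when the alignment is shorter than one window.
#' @export
sliding_window_pi <- function(aln, window = 100L, step = 25L) {
  window <- as.integer(window); step <- as.integer(step)
  stopifnot(window >= 1L, step >= 1L, length(aln) >= 2L)
  len <- unique(nchar(aln))
  if (length(len) != 1L) stop("rows have unequal lengths")
  empty <- data.frame(start = integer(), end = integer(),
                      midpoint = numeric(), pi = numeric(),
                      valid_sites = integer())
  if (len < window) {
    warning("alignment (", len, " columns) shorter than window (", window, ")")
    return(empty)
  }
  starts <- as.integer(seq(0L, len - window, by = step))
  pairs <- utils::combn(length(aln), 2L)
  rows <- lapply(starts, function(s0) {
    slice <- substring(unname(aln), s0 + 1L, s0 + window)
    pis <- numeric(ncol(pairs)); valids <- integer(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      r <- suppressWarnings(pairwise_pi(slice[pairs[1L, k]],
                                        slice[pairs[2L, k]]))
      pis[k] <- r$pi; valids[k] <- r$valid_sites
    }
    data.frame(start = s0, end = s0 + window, midpoint = s0 + window / 2,
               pi = if (anyNA(pis)) NA_real_ else mean(pis),
               valid_sites = min(valids))
  })
  do.call(rbind, rows)
}

#' Summarize window diversity for a gene
#'
#' Mean, across-window sample variance (n-1 denominator; 0 by convention for
#' a single window) and box-plot statistics (type-7 quantiles, 1.5 x IQR
#' whisker bounds) of the defined window pi values.
#'
#' @param windows A [sliding_window_pi()] data.frame.
#' @param gene_label Label for the report.
#' @return A `diversity_summary` list: `gene_label`, `mean_pi`,
#'   `window_variance`, `min`, `q1`, `median`, `q3`, `max`,
#'   `whisker_low`, `whisker_high`, `n_windows`.
#' @export
summarize_diversity <- function(windows, gene_label = "gene") {
  pis <- windows$pi[!is.na(windows$pi)]
  if (length(pis) == 0L) stop("no windows with defined pi")
  q <- stats::quantile(pis, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  iqr <- q[4] - q[2]
  lo_bound <- q[2] - 1.5 * iqr
  hi_bound <- q[4] + 1.5 * iqr
  structure(list(
    gene_label = gene_label,
    mean_pi = mean(pis),
    window_variance = if (length(pis) > 1L) stats::var(pis) else 0,
    min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
    whisker_low = min(pis[pis >= lo_bound]),
    whisker_high = max(pis[pis <= hi_bound]),
    n_windows = length(pis)
  ), class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "%s: mean pi %.4f (variance %.4g) over %d windows; 5-number %s\n",
    x$gene_label, x$mean_pi, x$window_variance, x$n_windows,
    paste(round(c(x$min, x$q1, x$median, x$q3, x$max), 4), collapse = "/")))
  invisible(x)
}

# ---- NG86 machinery ---------------------------------------------------------

# Per-codon synonymous-site count: for each position, the fraction of the
# three single-nucleotide mutants that are synonymous, with mutations to stop
# codons excluded from numerator and denominator (keeps N + S = 3 per codon).
.ng86_syn_sites_table <- local({
  cache <- NULL
  function(code) {
    if (!is.null(cache)) return(cache)
    sense <- names(code)[code != "*"]
    tab <- vapply(sense, function(codon) {
      s <- 0
      for (pos in 1:3) {
        base <- substr(codon, pos, pos)
        muts <- vapply(setdiff(NT_ALPHABET, base), function(b) {
          cc <- codon; substr(cc, pos, pos) <- b; cc
        }, "")
        aa <- code[muts]
        keep <- aa != "*"
        if (any(keep)) s <- s + sum(aa[keep] == code[[codon]]) / sum(keep)
      }
      s
    }, numeric(1))
    cache <<- tab
    cache
  }
})

.perms <- list(`1` = list(1L),
               `2` = list(c(1L, 2L), c(2L, 1L)),
               `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                          c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# Pathway-averaged (synonymous, nonsynonymous) difference counts between two
# sense codons; NULL when every mutational ordering passes through a stop.
.ng86_pair_diffs <- function(c1, c2, code) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  sd_tot <- 0; nd_tot <- 0; nvalid <- 0L
  for (ord in .perms[[as.character(k)]]) {
    cur <- c1; sd <- 0; nd <- 0; valid <- TRUE
    for (pos in diff_pos[ord]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code[[nxt]] == "*") { valid <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (valid) {
      sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; nvalid <- nvalid + 1L
    }
  }
  if (nvalid == 0L) return(NULL)
  c(sd = sd_tot / nvalid, nd = nd_tot / nvalid)
}

.jc69 <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

.ng86_counts <- function(a, b, code) {
  x <- toupper(unname(a)); y <- toupper(unname(b))
  if (nchar(x) != nchar(y)) stop("rows have unequal lengths")
  if (nchar(x) %% 3L != 0L) stop("length not divisible by 3")
  starts <- seq(1L, nchar(x), 3L)
  cx <- substring(x, starts, starts + 2L)
  cy <- substring(y, starts, starts + 2L)
  clean <- !grepl("[^ACGT]", cx) & !grepl("[^ACGT]", cy)
  cx <- cx[clean]; cy <- cy[clean]
  if (any(code[cx] == "*") || any(code[cy] == "*")) {
    stop("stop codon in compared codons")
  }
  syn_tab <- .ng86_syn_sites_table(code)
  N <- 0; S <- 0; Nd <- 0; Sd <- 0; compared <- 0L; skipped <- 0L
  for (i in seq_along(cx)) {
    d <- .ng86_pair_diffs(cx[i], cy[i], code)
    if (is.null(d)) {
      skipped <- skipped + 1L
      next
    }
    s_sites <- (syn_tab[[cx[i]]] + syn_tab[[cy[i]]]) / 2
    S <- S + s_sites
    N <- N + (3 - s_sites)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
    compared <- compared + 1L
  }
  if (skipped > 0L) {
    warning(skipped, " codon pair(s) skipped: all pathways pass through stops")
  }
  list(N = N, S = S, Nd = Nd, Sd = Sd, codons_compared = compared,
       codons_skipped = skipped)
}

.dnds_from_counts <- function(cnt) {
  pN <- if (cnt$N > 0) cnt$Nd / cnt$N else NA_real_
  pS <- if (cnt$S > 0) cnt$Sd / cnt$S else NA_real_
  dN <- .jc69(pN)
  dS <- .jc69(pS)
  omega <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  structure(c(cnt, list(pN = pN, pS = pS, dN = dN, dS = dS, omega = omega)),
            class = "dnds_result")
}

#' Nei-Gojobori (1986) dN/dS for a pair of coding rows
#'
#' Counts synonymous and nonsynonymous sites by exhaustive single-nucleotide
#' mutation enumeration per codon (averaged between the two sequences) and
#' differences by equal-weight averaging over all mutational orderings that
#' avoid stop codons; proportions are Jukes-Cantor corrected. Codons with a
#' gap or ambiguity in either row are skipped pairwise. `omega` is `NA` when
#' `dS` is 0 or a correction is undefined (`p >= 3/4`).
#'
#' @param a,b Equal-length coding rows (length divisible by 3; gaps allowed
#'   as whole `---` codons).
#' @param code Genetic-code table.
#' @return A `dnds_result`: `N`, `S` (fractional site counts), `Nd`, `Sd`
#'   (pathway-averaged differences), `pN`, `pS`, `dN`, `dS`, `omega`,
#'   `codons_compared`, `codons_skipped`.
#' @examples
#' ng86_pair("TTT", "TTA")$pN   # 0.4
#' @export
ng86_pair <- function(a, b, code = Biostrings::GENETIC_CODE) {
  .dnds_from_counts(.ng86_counts(a, b, code))
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf(
    "NG86: N %.2f S %.2f | Nd %.2f Sd %.2f | dN %s dS %s | omega %s (%d codons)\n",
    x$N, x$S, x$Nd, x$Sd,
    format(round(x$dN, 5)), format(round(x$dS, 5)),
    format(round(x$omega, 5)), x$codons_compared))
  invisible(x)
}

#' Global dN/dS over a codon alignment
#'
#' Pools NG86 site and difference counts over all unordered row pairs, then
#' computes proportions, Jukes-Cantor rates and omega from the pooled counts.
#' This is a pairwise-counting approximation to tree-based ancestor-counting
#' (SLAC-style) estimates; agreement is expected to be approximate, not
#' exact.
#'
#' @param caln A [back_translate()] codon alignment, or any named character
#'   vector of equal-length coding rows.
#' @param code Genetic-code table.
#' @return A `dnds_result` from the pooled counts, with a `per_pair`
#'   data.frame attached (one NG86 row per pair).
#' @export
global_dnds <- function(caln, code = Biostrings::GENETIC_CODE) {
  stopifnot(length(caln) >= 2L)
  ids <- names(caln) %||% paste0("row", seq_along(caln))
  pairs <- utils::combn(length(caln), 2L)
  tot <- list(N = 0, S = 0, Nd = 0, Sd = 0, codons_compared = 0L,
              codons_skipped = 0L)
  per_pair <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cnt <- .ng86_counts(caln[[i]], caln[[j]], code)
    r <- .dnds_from_counts(cnt)
    per_pair[[k]] <- data.frame(
      id_a = ids[i], id_b = ids[j], N = r$N, S = r$S, Nd = r$Nd, Sd = r$Sd,
      pN = r$pN, pS = r$pS, dN = r$dN, dS = r$dS, omega = r$omega,
      stringsAsFactors = FALSE)
    for (f in names(tot)) tot[[f]] <- tot[[f]] + cnt[[f]]
  }
  out <- .dnds_from_counts(tot)
  out$per_pair <- do.call(rbind, per_pair)
  out
}
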