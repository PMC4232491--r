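# Degenerate alpha-repeat patterns and position-specific weight matrices.
#
# The alpha repeat is the tandem transport motif of all Na+/Ca2+ exchangers:
# two blocks (alpha-1, alpha-2) separated by a cytoplasmic loop. Strict
# degenerate patterns catch canonical repeats; the PSWM route scores divergent
# repeats below strict-pattern stringency.

#' Parse a printed degenerate motif pattern
#'
#' Pattern syntax: single upper-case residue letters, parenthesized
#' slash-alternations such as `(I/V/L)`, and lower-case `x` as a full
#' wildcard. One alignment position per letter, group or wildcard.
#'
#' @param text Pattern string, e.g. `"GTS(I/V/L)PD"`.
#' @param label Token naming the motif (e.g. `"NCX_alpha2"`).
#' @return A `motif_pattern`: list of per-position allowed-residue sets plus
#'   the original `source_text`.
#' @examples
#' p <- parse_pattern("G(S/G)SAPE", "NCX_alpha1")
#' p$positions[[2]]
#' @export
parse_pattern <- function(text, label = "motif") {
  chars <- strsplit(text, "")[[1]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "(") {
      j <- i + 1L
      grp <- character()
      expecting <- "letter"
      repeat {
        if (j > length(chars)) stop("unbalanced parenthesis at column ", i)
        cj <- chars[[j]]
        if (cj == ")") {
          if (expecting == "letter") stop("empty alternative at column ", j)
          break
        } else if (cj == "/") {
          if (expecting == "letter") stop("misplaced '/' at column ", j)
          expecting <- "letter"
        } else if (toupper(cj) %in% AA_ALPHABET && expecting == "letter") {
          grp <- c(grp, toupper(cj))
          expecting <- "sep"
        } else {
          stop("illegal character '", cj, "' at column ", j)
        }
        j <- j + 1L
      }
      if (length(grp) == 0L) stop("empty group at column ", i)
      positions[[length(positions) + 1L]] <- unique(grp)
      i <- j + 1L
    } else if (ch == "x") {
      positions[[length(positions) + 1L]] <- AA_ALPHABET
      i <- i + 1L
    } else if (toupper(ch) %in% AA_ALPHABET) {
      positions[[length(positions) + 1L]] <- toupper(ch)
      i <- i + 1L
    } else {
      stop("illegal character '", ch, "' at column ", i)
    }
  }
  if (length(positions) == 0L) stop("empty pattern")
  structure(list(positions = positions, label = label, source_text = text),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern", x$label, ":", x$source_text,
      "(", length(x$positions), "positions )\n")
  invisible(x)
}

#' Scan a protein sequence with a degenerate pattern
#'
#' Reports every offset (including overlapping ones) at which each pattern
#' position's allowed set contains the sequence residue.
#'
#' @param seq Ungapped protein sequence (character scalar or single-element
#'   `seq_set`).
#' @param pattern A [parse_pattern()] result.
#' @param seq_id Id used in the output (defaults to the name of `seq`).
#' @return data.frame `seq_id`, `offset` (0-based), `matched`,
#'   `pattern_label`, sorted by offset. Empty when the pattern is longer than
#'   the sequence.
#' @export
scan_pattern <- function(seq, pattern, seq_id = NULL) {
  s <- .as_single_seq(seq)
  if (is.null(seq_id)) seq_id <- names(s) %||% "seq"
  w <- length(pattern$positions)
  n <- nchar(s)
  empty <- data.frame(seq_id = character(), offset = integer(),
                      matched = character(), pattern_label = character(),
                      stringsAsFactors = FALSE)
  if (n < w) return(empty)
  chars <- strsplit(unname(s), "")[[1]]
  if (any(chars == "-")) stop("gapped sequence passed to scan_pattern")
  nwin <- n - w + 1L
  ok <- rep(TRUE, nwin)
  for (j in seq_len(w)) {
    ok <- ok & chars[j:(j + nwin - 1L)] %in% pattern$positions[[j]]
  }
  offs <- which(ok) - 1L
  if (length(offs) == 0L) return(empty)
  data.frame(seq_id = seq_id, offset = offs,
             matched = substring(unname(s), offs + 1L, offs + w),
             pattern_label = pattern$label, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

.as_single_seq <- function(seq) {
  if (length(seq) != 1L) stop("expected a single sequence")
  seq
}

#' Build a position-specific weight matrix from motif instances
#'
#' Log-odds scores with additive pseudocounts:
#' `score[j, a] = log2(((count_j(a) + k) / (N + 20 k)) / bg(a))`
#' where `k` is the pseudocount, `N` the number of instances and `bg` the
#' background residue frequency. With `pseudocount = 0` a zero-count cell
#' scores `-Inf`; the matrix is then flagged `has_neg_inf`.
#'
#' @param instances Character vector of equal-length ungapped motif sequences.
#' @param pseudocount Non-negative pseudocount (default 0.5).
#' @param background Length-20 residue frequency vector summing to 1 (named by
#'   residue, or unnamed in [AA_ALPHABET] order); defaults to uniform 0.05.
#' @param label Matrix label.
#' @return A `pswm`: scores matrix (`width` x 20, bits), background,
#'   pseudocount, consensus string and the maximum attainable window score.
#' @examples
#' m <- build_pswm(rep("GNGAPD", 4), pseudocount = 0.1)
#' round(m$scores[1, "G"], 4)   # log2((4.1/6)/0.05)
#' @export
build_pswm <- function(instances, pseudocount = 0.5,
                       background = NULL, label = "pswm") {
  if (length(instances) < 1L) stop("need at least one instance")
  w <- unique(nchar(instances))
  if (length(w) != 1L) {
    stop("motif instances have mixed lengths: ", paste(w, collapse = ", "))
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  if (is.null(names(background))) names(background) <- AA_ALPHABET
  background <- background[AA_ALPHABET]
  if (any(is.na(background)) || any(background <= 0)) {
    stop("background must assign positive frequency to all 20 residues")
  }
  mat <- do.call(rbind, strsplit(toupper(instances), ""))
  if (!all(mat %in% AA_ALPHABET)) {
    stop("instances contain non-amino-acid characters")
  }
  n <- nrow(mat)
  counts <- vapply(seq_len(w), function(j) {
    tab <- table(factor(mat[, j], levels = AA_ALPHABET))
    as.numeric(tab)
  }, numeric(20))
  counts <- t(counts)                      # width x 20
  colnames(counts) <- AA_ALPHABET
  freq <- (counts + pseudocount) / (n + 20 * pseudocount)
  scores <- log2(sweep(freq, 2L, background, "/"))
  has_neg_inf <- any(is.infinite(scores))
  if (has_neg_inf) warning("pseudocount 0 with zero-count cells: -Inf scores")
  consensus <- paste(AA_ALPHABET[apply(scores, 1L, which.max)], collapse = "")
  structure(list(width = w, scores = scores, background = background,
                 pseudocount = pseudocount, label = label,
                 consensus = consensus,
                 max_score = sum(apply(scores, 1L, max)),
                 has_neg_inf = has_neg_inf),
            class = "pswm")
}

#' @export
print.pswm <- function(x, ...) {
  cat("pswm", x$label, ": width", x$width, ", consensus", x$consensus,
      ", max score", round(x$max_score, 3), "bits\n")
  invisible(x)
}

#' Scan a protein sequence with a PSWM
#'
#' Every window of length `width` is scored by column sum; windows whose score
#' relative to the maximum attainable score reaches `min_relative_score` are
#' reported, sorted by descending score then ascending offset.
#'
#' @inheritParams scan_pattern
#' @param pswm A [build_pswm()] matrix.
#' @param min_relative_score Threshold on `score / max_score` in `[0, 1]`.
#' @return data.frame `seq_id`, `offset` (0-based), `window`, `score` (bits),
#'   `relative_score`.
#' @export
scan_pswm <- function(seq, pswm, min_relative_score = 0.8, seq_id = NULL) {
  s <- .as_single_seq(seq)
  if (is.null(seq_id)) seq_id <- names(s) %||% "seq"
  w <- pswm$width
  n <- nchar(s)
  empty <- data.frame(seq_id = character(), offset = integer(),
                      window = character(), score = numeric(),
                      relative_score = numeric(), stringsAsFactors = FALSE)
  if (n < w) return(empty)
  chars <- strsplit(unname(s), "")[[1]]
  if (any(chars == "-")) stop("gapped sequence passed to scan_pswm")
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) stop("non-amino-acid residue in sequence '", seq_id, "'")
  nwin <- n - w + 1L
  score <- numeric(nwin)
  for (j in seq_len(w)) {
    score <- score + pswm$scores[cbind(j, idx[j:(j + nwin - 1L)])]
  }
  rel <- score / pswm$max_score
  keep <- which(rel >= min_relative_score)
  if (length(keep) == 0L) return(empty)
  out <- data.frame(seq_id = seq_id, offset = keep - 1L,
                    window = substring(unname(s), keep, keep + w - 1L),
                    score = score[keep], relative_score = rel[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$offset), , drop = FALSE]
}

#' Locate a paired alpha-1 / alpha-2 repeat
#'
#' Searches a protein for an alpha-1 hit followed by an alpha-2 hit with a
#' cytoplasmic-loop-compatible separation: `paired` is `TRUE` iff some
#' alpha-1 hit precedes some alpha-2 hit with gap (alpha-2 offset minus
#' alpha-1 end) within `[min_gap, max_gap]`. `divergent` is `TRUE` iff exactly
#' one of the two repeats is found anywhere — the hallmark of the atypical
#' exchangers the PSWM route is designed to surface.
#'
#' @param seq Ungapped protein sequence.
#' @param alpha1,alpha2 A `motif_pattern` or `pswm` for each repeat.
#' @param min_gap,max_gap Allowed residue separation between alpha-1 end and
#'   alpha-2 start (defaults 50 and 1000).
#' @param min_relative_score PSWM threshold (ignored for strict patterns).
#' @param seq_id Output id.
#' @return List with `alpha1`/`alpha2` (best pair member rows or `NULL`),
#'   `alpha1_hits`/`alpha2_hits` (all hits), `paired`, `divergent`.
#' @export
find_alpha_repeat_pair <- function(seq, alpha1, alpha2,
                                   min_gap = 50L, max_gap = 1000L,
                                   min_relative_score = 0.8, seq_id = NULL) {
  if (min_gap > max_gap) stop("min_gap must be <= max_gap")
  s <- .as_single_seq(seq)
  if (is.null(seq_id)) seq_id <- names(s) %||% "seq"
  h1 <- .motif_hits(s, alpha1, min_relative_score, seq_id)
  h2 <- .motif_hits(s, alpha2, min_relative_score, seq_id)
  best1 <- best2 <- NULL
  paired <- FALSE
  if (nrow(h1) && nrow(h2)) {
    combos <- expand.grid(i = seq_len(nrow(h1)), j = seq_len(nrow(h2)))
    gap <- h2$offset[combos$j] - (h1$offset[combos$i] + h1$width[combos$i])
    ok <- gap >= min_gap & gap <= max_gap
    if (any(ok)) {
      paired <- TRUE
      cand <- combos[ok, , drop = FALSE]
      tot <- h1$score[cand$i] + h2$score[cand$j]
      pick <- if (all(is.na(tot))) {
        # strict patterns carry no score: first pair in sequence order
        order(h1$offset[cand$i], h2$offset[cand$j])[1L]
      } else {
        order(-tot, h1$offset[cand$i], h2$offset[cand$j])[1L]
      }
      best1 <- h1[cand$i[pick], , drop = FALSE]
      best2 <- h2[cand$j[pick], , drop = FALSE]
    }
  }
  list(seq_id = seq_id, alpha1_hits = h1, alpha2_hits = h2,
       alpha1 = best1, alpha2 = best2, paired = paired,
       divergent = xor(nrow(h1) > 0L, nrow(h2) > 0L))
}

# Normalize pattern/PSWM hits to a common data.frame(offset, width, score).
.motif_hits <- function(seq, motif, min_relative_score, seq_id) {
  if (inherits(motif, "motif_pattern")) {
    h <- scan_pattern(seq, motif, seq_id = seq_id)
    data.frame(offset = h$offset,
               width = rep(length(motif$positions), nrow(h)),
               score = rep(NA_real_, nrow(h)), matched = h$matched,
               stringsAsFactors = FALSE)
  } else if (inherits(motif, "pswm")) {
    h <- scan_pswm(seq, motif, min_relative_score, seq_id = seq_id)
    data.frame(offset = h$offset, width = rep(motif$width, nrow(h)),
               score = h$score, matched = h$window, stringsAsFactors = FALSE)
  } else {
    stop("motif must be a motif_pattern or pswm")
  }
}

#' Built-in alpha-repeat motif library
#'
#' The degenerate consensus patterns of the exchanger alpha repeats, both the
#' canonical published forms and the broader forms observed across nematode
#' proteomes. NCX and NCKX share the NCX-type repeats (G(S/G)SAPE /
#' GTS(I/V/L)PD); CCX/NCLX carries its own (GNG(A/S)PD / (G/S)(N/D)SxGD).
#'
#' @return Named list of `motif_pattern` objects.
#' @export
motif_library <- function() {
  list(
    ncx_alpha1          = parse_pattern("G(S/G)SAPE",      "NCX_alpha1"),
    ncx_alpha1_observed = parse_pattern("GSSAPE",          "NCX_alpha1_obs"),
    ncx_alpha2          = parse_pattern("GTS(I/V)PD",      "NCX_alpha2"),
    ncx_alpha2_observed = parse_pattern("GTS(I/V/L)PD",    "NCX_alpha2_obs"),
    ccx_alpha1          = parse_pattern("GNG(A/S)PD",      "CCX_alpha1"),
    ccx_alpha1_observed = parse_pattern("GNGAPD",          "CCX_alpha1_obs"),
    ccx_alpha2          = parse_pattern("(G/S)(N/D)SxGD",  "CCX_alpha2"),
    ccx_alpha2_observed = parse_pattern("(A/S)N(S/C)(V/I)GD", "CCX_alpha2_obs")
  )
}

#' Serialize / read a PSWM as plain text
#'
#' A minimal MEME-like format: comment header lines (`# key value`) carrying
#' label, width, pseudocount and background, then one tab-separated row of
#' bit scores per motif position with a residue header row.
#'
#' @param pswm A `pswm` object.
#' @param path Output file.
#' @export
write_pswm <- function(pswm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# pswm", pswm$label),
    paste("# width", pswm$width),
    paste("# pseudocount", format(pswm$pseudocount, digits = 17)),
    paste("# background", paste(format(pswm$background, digits = 17),
                                collapse = " ")),
    paste(colnames(pswm$scores), collapse = "\t")), con)
  utils::write.table(format(pswm$scores, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pswm
#' @param path Input file for `read_pswm`.
#' @export
read_pswm <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get <- function(key) sub(paste0("^# ", key, " "), "",
                           hdr[startsWith(hdr, paste0("# ", key, " "))][1L])
  label <- get("pswm")
  pseudocount <- as.numeric(get("pseudocount"))
  background <- stats::setNames(as.numeric(strsplit(get("background"),
                                                    " +")[[1]]), AA_ALPHABET)
  cols <- strsplit(body[[1L]], "\t")[[1]]
  scores <- do.call(rbind, lapply(body[-1L], function(l)
    as.numeric(strsplit(l, "\t")[[1]])))
  colnames(scores) <- cols
  scores <- scores[, AA_ALPHABET, drop = FALSE]
  structure(list(width = nrow(scores), scores = scores,
                 background = background, pseudocount = pseudocount,
                 label = label,
                 consensus = paste(AA_ALPHABET[apply(scores, 1L, which.max)],
                                   collapse = ""),
                 max_score = sum(apply(scores, 1L, max)),
                 has_neg_inf = any(is.infinite(scores))),
            class = "pswm")
}
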