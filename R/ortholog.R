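# Pairwise alignment and reciprocal-best-hit ortholog pairing: a desk-scale,
# fully deterministic stand-in for bidirectional BLAST searches.

.matrix_cache <- new.env(parent = emptyenv())

#' Resolve a substitution matrix
#'
#' `"BLOSUM62"` (the BLAST protein default, bundled via Biostrings) or a
#' numeric matrix, or a path to an NCBI-format matrix file.
#' @param matrix Matrix spec.
#' @return Numeric substitution matrix.
#' @export
resolve_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  stopifnot(is.character(matrix), length(matrix) == 1L)
  if (file.exists(matrix)) return(read_score_matrix(matrix))
  if (!exists(matrix, envir = .matrix_cache)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    assign(matrix, get(matrix, envir = e), envir = .matrix_cache)
  }
  get(matrix, envir = .matrix_cache)
}

#' Read an NCBI-format substitution matrix file
#'
#' Plain-text format as distributed with BLAST: `#` comment lines, a header
#' row of residue letters, then one labelled row of integers per residue.
#'
#' @param path File path.
#' @return Numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[[1L]]), "\\s+")[[1]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  rownames(m) <- vapply(rows, `[[`, "", 1L)
  colnames(m) <- cols
  m
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment of two proteins under a substitution matrix and
#' affine gap penalties (a gap of length k costs `gap_open + k * gap_extend`).
#' When no residue pairing scores positive the empty alignment (score 0) is
#' returned. Identity is computed over aligned columns.
#'
#' @param a,b Protein sequences (named character scalars; names become ids).
#' @param matrix Substitution matrix (see [resolve_matrix()]); default
#'   BLOSUM62.
#' @param gap_open,gap_extend Non-negative penalties, defaults 11 / 1
#'   (BLAST's protein defaults); `gap_open >= gap_extend` required.
#' @param id_a,id_b Ids for the report.
#' @return An `alignment_result`: `query_id`, `target_id`, `score`,
#'   `aligned_query`, `aligned_target`, `identity_fraction`.
#' @examples
#' r <- local_align(c(x = "ACDE"), c(y = "ACDE"))
#' r$score   # 24 under BLOSUM62
#' @export
local_align <- function(a, b, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1,
                        id_a = NULL, id_b = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (!(gap_open >= gap_extend && gap_extend >= 0)) {
    stop("need gap_open >= gap_extend >= 0")
  }
  id_a <- id_a %||% names(a) %||% "a"
  id_b <- id_b %||% names(b) %||% "b"
  mat <- resolve_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(unname(a)), Biostrings::AAString(unname(b)),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(pa)
  if (sc < 0) {           # Smith-Waterman admits the empty alignment
    return(structure(list(query_id = id_a, target_id = id_b, score = 0,
                          aligned_query = "", aligned_target = "",
                          identity_fraction = NA_real_),
                     class = "alignment_result"))
  }
  aq <- as.character(Biostrings::alignedPattern(pa))
  at <- as.character(Biostrings::alignedSubject(pa))
  structure(list(query_id = id_a, target_id = id_b, score = sc,
                 aligned_query = aq, aligned_target = at,
                 identity_fraction = .aligned_identity(aq, at)),
            class = "alignment_result")
}

# identity over aligned columns, excluding (never-occurring in pairwise
# output) dual-gap columns
.aligned_identity <- function(aq, at) {
  x <- strsplit(aq, "")[[1]]
  y <- strsplit(at, "")[[1]]
  keep <- !(x == "-" & y == "-")
  if (!any(keep)) return(NA_real_)
  mean(x[keep] == y[keep])
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$query_id, "vs", x$target_id, ": score", x$score,
      ", identity", round(x$identity_fraction, 4), "\n")
  invisible(x)
}

#' Percent identity between two proteins
#'
#' Identity over the aligned columns of a local (Smith-Waterman) or global
#' (Needleman-Wunsch) alignment under the same scoring scheme as
#' [local_align()].
#'
#' @inheritParams local_align
#' @param mode `"local"` or `"global"`.
#' @return Identity fraction in `[0, 1]`.
#' @export
percent_identity <- function(a, b, mode = c("local", "global"),
                             matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  # the optimal alignment (unlike its score) need not be unique; canonical
  # argument order keeps pid(a, b) == pid(b, a) whatever the traceback picks
  if (unname(b) < unname(a)) { tmp <- a; a <- b; b <- tmp }
  if (mode == "local") {
    return(local_align(a, b, matrix, gap_open, gap_extend)$identity_fraction)
  }
  mat <- resolve_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(unname(a)), Biostrings::AAString(unname(b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  .aligned_identity(as.character(Biostrings::alignedPattern(pa)),
                    as.character(Biostrings::alignedSubject(pa)))
}

#' Reciprocal best hits between two sequence sets
#'
#' Pair `(a, b)` is reported iff `b` is `a`'s strict (unique-maximum) best
#' local-alignment score in `set_b` and `a` is `b`'s strict best in `set_a`.
#' A tied maximum yields no pair; the tied candidates are returned in the
#' `ambiguous` side table. The result is invariant under input ordering.
#'
#' @param set_a,set_b Named character vectors of protein sequences with
#'   unique ids.
#' @inheritParams local_align
#' @return List with `pairs` (data.frame `id_a`, `id_b`, `score_ab`,
#'   `score_ba`, `identity`) and `ambiguous` (data.frame `side`, `id`,
#'   `tied_with`).
#' @export
reciprocal_best_hits <- function(set_a, set_b, matrix = "BLOSUM62",
                                 gap_open = 11, gap_extend = 1) {
  stopifnot(length(set_a) > 0L, length(set_b) > 0L,
            !anyDuplicated(names(set_a)), !anyDuplicated(names(set_b)))
  na <- length(set_a); nb <- length(set_b)
  S <- matrix(0, na, nb, dimnames = list(names(set_a), names(set_b)))
  P <- matrix(NA_real_, na, nb, dimnames = dimnames(S))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      r <- local_align(set_a[i], set_b[j], matrix, gap_open, gap_extend)
      S[i, j] <- r$score
      P[i, j] <- r$identity_fraction
    }
  }
  strict_best <- function(v) {
    m <- max(v)
    idx <- which(v == m)
    if (length(idx) == 1L) idx else NA_integer_
  }
  best_b <- apply(S, 1L, strict_best)   # per a: best column or NA (tie)
  best_a <- apply(S, 2L, strict_best)   # per b: best row or NA
  pairs <- list(); amb <- list()
  for (i in seq_len(na)) {
    if (is.na(best_b[i])) {
      ties <- colnames(S)[S[i, ] == max(S[i, ])]
      amb[[length(amb) + 1L]] <- data.frame(
        side = "a", id = rownames(S)[i],
        tied_with = paste(ties, collapse = ","), stringsAsFactors = FALSE)
      next
    }
    j <- best_b[i]
    if (!is.na(best_a[j]) && best_a[j] == i) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        id_a = rownames(S)[i], id_b = colnames(S)[j],
        score_ab = S[i, j], score_ba = S[i, j],   # SW score is symmetric
        identity = P[i, j], stringsAsFactors = FALSE)
    }
  }
  for (j in seq_len(nb)) {
    if (is.na(best_a[j])) {
      ties <- rownames(S)[S[, j] == max(S[, j])]
      amb[[length(amb) + 1L]] <- data.frame(
        side = "b", id = colnames(S)[j],
        tied_with = paste(ties, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  pairs_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(id_a = character(), id_b = character(), score_ab = numeric(),
               score_ba = numeric(), identity = numeric(),
               stringsAsFactors = FALSE)
  pairs_df <- pairs_df[order(pairs_df$id_a), , drop = FALSE]
  rownames(pairs_df) <- NULL
  amb_df <- if (length(amb)) do.call(rbind, amb) else
    data.frame(side = character(), id = character(), tied_with = character(),
               stringsAsFactors = FALSE)
  list(pairs = pairs_df, ambiguous = amb_df)
}
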