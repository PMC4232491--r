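# Sequence, alignment and domain-table I/O.

#' Amino-acid and nucleotide alphabets
#'
#' The 20 standard amino acids and the 4 DNA bases used for input
#' validation throughout the package.
#' @keywords internal
#' @name alphabets
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT_ALPHABET <- c("A", "C", "G", "T")

.alphabet_chars <- function(alphabet) {
  switch(alphabet,
    protein    = AA_ALPHABET,
    nucleotide = NT_ALPHABET,
    stop("unknown alphabet: ", alphabet)
  )
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased, multi-line records concatenated, and validated
#' against the chosen alphabet. The result is a named character vector of
#' residue strings; record descriptions (header text after the first
#' whitespace) are kept in the `"descriptions"` attribute and the alphabet in
#' the `"alphabet"` attribute.
#'
#' For protein input a single terminal `*` (stop) is stripped with a warning;
#' an internal `*` is an error. Gap characters are not permitted here; use
#' [read_alignment()] for gapped input.
#'
#' @param path Path to a FASTA file. Alternatively pass raw FASTA text via
#'   `text`.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param text Optional character scalar of FASTA-formatted text (overrides
#'   `path`).
#' @return Named character vector of sequences (class `"seq_set"`).
#' @examples
#' s <- read_fasta(text = ">a desc\nMKV\nLLL\n>b\nMR\n")
#' unname(s["a"])
#' @export
read_fasta <- function(path = NULL, alphabet = c("protein", "nucleotide"),
                       text = NULL) {
  alphabet <- match.arg(alphabet)
  if (!is.null(text)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(text, path)
  }
  stopifnot(is.character(path), length(path) == 1L)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1L]])
  seqs <- toupper(as.character(raw))
  names(seqs) <- ids

  if (alphabet == "protein") {
    term <- grepl("\\*$", seqs)
    if (any(term)) {
      warning("stripping terminal stop ('*') from: ",
              paste(ids[term], collapse = ", "))
      seqs[term] <- sub("\\*$", "", seqs[term])
    }
  }
  empty <- !nzchar(seqs)
  if (any(empty)) stop("empty sequence for id: ", ids[empty][[1L]])
  .check_alphabet(seqs, alphabet)
  structure(seqs, descriptions = stats::setNames(desc, ids),
            alphabet = alphabet, class = "seq_set")
}

.check_alphabet <- function(seqs, alphabet) {
  ok <- .alphabet_chars(alphabet)
  bad_re <- paste0("[^", paste(ok, collapse = ""), "]")
  for (i in seq_along(seqs)) {
    m <- regexpr(bad_re, seqs[[i]])
    if (m > 0L) {
      stop("illegal ", alphabet, " residue '",
           substr(seqs[[i]], m, m), "' at position ", m,
           " in sequence '", names(seqs)[i], "'")
    }
  }
  invisible(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  desc <- attr(seqs, "descriptions")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    hdr <- id
    if (!is.null(desc) && !is.na(desc[id]) && nzchar(desc[id])) {
      hdr <- paste(id, desc[id])
    }
    writeLines(paste0(">", hdr), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but `-` gap characters are permitted and all rows must
#' have equal length. At least two rows are required.
#'
#' @inheritParams read_fasta
#' @return Named character vector of gapped rows (class `"alignment"`).
#' @export
read_alignment <- function(path = NULL, alphabet = c("protein", "nucleotide"),
                           text = NULL) {
  alphabet <- match.arg(alphabet)
  if (!is.null(text)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(text, path)
  }
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1L]])
  rows <- toupper(as.character(raw))
  names(rows) <- ids
  as_alignment(rows, alphabet = alphabet)
}

#' Validate an alignment
#'
#' @param rows Named character vector of gapped rows.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return `rows` with class `"alignment"`.
#' @export
as_alignment <- function(rows, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (length(rows) < 2L) stop("an alignment needs at least 2 rows")
  w <- unique(nchar(rows))
  if (length(w) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(w, collapse = ", "))
  }
  .check_alphabet(stats::setNames(gsub("-", "", rows), names(rows)), alphabet)
  structure(rows, alphabet = alphabet, class = "alignment")
}

#' Strip gap-containing columns from an alignment
#'
#' Removes every column in which at least `max_gap_frac` of the rows (default:
#' any row) carries a gap. Row order is preserved and the retained original
#' column indices (0-based) are returned alongside.
#'
#' @param aln Named character vector of equal-length gapped rows.
#' @param max_gap_frac Maximum tolerated fraction of gaps per column; the
#'   default `0` removes columns with any gap.
#' @return A list with `alignment` (gap-stripped rows), `retained` (0-based
#'   original column indices) and `empty` (`TRUE` if no column survived; a
#'   warning is raised in that case).
#' @examples
#' strip_gap_columns(c(a = "A-C", b = "AGC"))$retained
#' @export
strip_gap_columns <- function(aln, max_gap_frac = 0) {
  w <- unique(nchar(aln))
  if (length(w) != 1L) stop("rows have unequal lengths")
  mat <- do.call(rbind, strsplit(unname(aln), ""))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= max_gap_frac
  out <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (length(out) == 0L) out <- rep("", length(aln))
  names(out) <- names(aln)
  empty <- !any(keep)
  if (empty) warning("all columns contained gaps; empty alignment returned")
  attributes(out) <- c(attributes(out),
                       attributes(aln)[setdiff(names(attributes(aln)), "names")])
  list(alignment = out, retained = which(keep) - 1L, empty = empty)
}

#' Default signature-role aliases
#'
#' Maps Pfam/InterPro accessions and member-database names onto the three
#' roles the subtype classifier consumes: `K_DEP` (potassium-dependent
#' exchanger domain, diagnostic of NCKX), `EXCHANGER` (the Na_Ca_ex cation
#' exchanger domain) and `CALX_BETA` (the CalX-beta calcium-binding domain,
#' tandemly repeated in NCX). The mapping is deliberately overridable because
#' accessions drift across database releases.
#'
#' @return Named character vector: accession/name -> role.
#' @export
default_signature_aliases <- function() {
  c(IPR004481   = "K_DEP",
    Na_K_Ca_ex  = "K_DEP",
    Na_Ca_ex    = "EXCHANGER",
    PF01699     = "EXCHANGER",
    IPR004837   = "EXCHANGER",
    CalX_Beta   = "CALX_BETA",
    `CalX-beta` = "CALX_BETA",
    PF03160     = "CALX_BETA")
}

#' Read an InterProScan-style domain table
#'
#' Parses a tab-separated domain-annotation table (no header). The default
#' column mapping follows InterProScan TSV output: protein id in column 1,
#' member-database signature accession in column 5, start/end in columns 7/8,
#' and the InterPro accession in column 12. Rows whose signature (or InterPro
#' accession) maps to a recognized role are flagged `relevant`; all other rows
#' are retained with `relevant = FALSE`.
#'
#' @param path TSV file path (or `text`).
#' @param columns Named integer vector with entries `id`, `signature`,
#'   `start`, `end` and optionally `interpro`.
#' @param aliases Accession-to-role map, see [default_signature_aliases()].
#' @param text Optional TSV text instead of a file.
#' @return data.frame with columns `protein_id`, `signature`, `start`, `end`,
#'   `interpro`, `role`, `relevant` (1-based inclusive coordinates).
#' @export
read_domain_table <- function(path = NULL,
                              columns = c(id = 1L, signature = 5L,
                                          start = 7L, end = 8L,
                                          interpro = 12L),
                              aliases = default_signature_aliases(),
                              text = NULL) {
  if (!is.null(text)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- readLines(path)
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(protein_id = character(), signature = character(),
                      start = integer(), end = integer(),
                      interpro = character(), role = character(),
                      relevant = logical(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get_col <- function(f, i) if (length(f) >= i) f[[i]] else NA_character_
  out <- lapply(seq_along(fields), function(k) {
    f <- fields[[k]]
    start_raw <- get_col(f, columns[["start"]])
    end_raw <- get_col(f, columns[["end"]])
    start <- suppressWarnings(as.integer(start_raw))
    end <- suppressWarnings(as.integer(end_raw))
    if (is.na(start) || is.na(end)) {
      stop("non-integer domain coordinates ('", start_raw, "', '", end_raw,
           "') at line ", k)
    }
    if (start > end) stop("start > end (", start, " > ", end, ") at line ", k)
    data.frame(protein_id = get_col(f, columns[["id"]]),
               signature = get_col(f, columns[["signature"]]),
               start = start, end = end,
               interpro = if ("interpro" %in% names(columns))
                 get_col(f, columns[["interpro"]]) else NA_character_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  role <- unname(aliases[tab$signature])
  miss <- is.na(role) & !is.na(tab$interpro)
  role[miss] <- unname(aliases[tab$interpro[miss]])
  tab$role <- role
  tab$relevant <- !is.na(role)
  tab
}

#' Write a domain table in InterProScan TSV layout
#'
#' Emits the 12-column tab-separated layout [read_domain_table()] reads by
#' default (unused columns are `-`).
#'
#' @param ann data.frame with `protein_id`, `signature`, `start`, `end` and
#'   optionally `interpro`.
#' @param path Output file.
#' @export
write_domain_table <- function(ann, path) {
  n <- nrow(ann)
  interpro <- if ("interpro" %in% names(ann)) ann$interpro else rep("-", n)
  tab <- cbind(ann$protein_id, "-", "-", "Pfam", ann$signature, "-",
               ann$start, ann$end, "-", "-", "-", interpro)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set of", length(x), attr(x, "alphabet"), "sequences;",
      "lengths", min(nchar(x)), "-", max(nchar(x)), "\n")
  invisible(x)
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", length(x), "rows x", nchar(x[[1]]), "columns (",
      attr(x, "alphabet"), ")\n")
  invisible(x)
}
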