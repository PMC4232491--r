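# Codon-aware back-translation of protein alignments (the Pal2Nal step).

#' Translate a coding sequence
#'
#' Standard-table translation (table 1; other tables may be supplied as a
#' named codon -> amino-acid vector such as [Biostrings::GENETIC_CODE]).
#' An internal stop codon is an error: split gene predictions in draft
#' annotations hinge on spurious stops, and silently accepting one would mask
#' exactly that class of misannotation. A terminal stop is trimmed.
#'
#' @param cds Nucleotide sequence (character scalar), length divisible by 3.
#' @param code Genetic-code table (default [Biostrings::GENETIC_CODE]).
#' @param allow_ambiguity If `TRUE`, codons with non-ACGT characters
#'   translate to `X` instead of erroring.
#' @return Protein string (no terminal `*`).
#' @examples
#' translate("ATGAAA")
#' @export
translate <- function(cds, code = Biostrings::GENETIC_CODE,
                      allow_ambiguity = FALSE) {
  s <- toupper(unname(.as_single_seq(cds)))
  if (nchar(s) %% 3L != 0L) {
    stop("CDS length ", nchar(s), " not divisible by 3")
  }
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  aa <- unname(code[codons])
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1L]
    if (allow_ambiguity) {
      aa[is.na(aa)] <- "X"
    } else {
      stop("ambiguous or invalid codon '", codons[bad], "' at codon ", bad)
    }
  }
  n <- length(aa)
  if (n > 0L && aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*")) {
    stop("internal stop codon at codon position ", which(aa == "*")[1L])
  }
  paste(aa, collapse = "")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces each residue column of a protein alignment with the matching
#' codon from that sequence's CDS, and each gap with `---`. Every CDS must
#' translate exactly to its ungapped protein row (a terminal stop codon is
#' tolerated and trimmed, with a warning).
#'
#' @param protein_aln Named character vector of gapped protein rows (an
#'   [as_alignment()] object or plain vector).
#' @param cds_map Named character vector of CDS nucleotide sequences, one per
#'   alignment row id.
#' @param code Genetic-code table.
#' @param allow_ambiguity Allow non-ACGT characters in codons.
#' @return A `codon_alignment`: named character vector of gapped nucleotide
#'   rows (3x the protein alignment width), with the source protein alignment
#'   attached as an attribute.
#' @examples
#' back_translate(c(a = "M-K", b = "MAK"),
#'                c(a = "ATGAAA", b = "ATGGCTAAG"))
#' @export
back_translate <- function(protein_aln, cds_map,
                           code = Biostrings::GENETIC_CODE,
                           allow_ambiguity = FALSE) {
  ids <- names(protein_aln)
  if (is.null(ids) || !all(nzchar(ids))) stop("protein alignment rows must be named")
  missing_cds <- setdiff(ids, names(cds_map))
  if (length(missing_cds)) {
    stop("no CDS for alignment row(s): ", paste(missing_cds, collapse = ", "))
  }
  rows <- vapply(ids, function(id) {
    prot_gapped <- protein_aln[[id]]
    prot <- gsub("-", "", prot_gapped)
    np <- nchar(prot)
    cds <- toupper(cds_map[[id]])
    if (nchar(cds) == 3L * (np + 1L)) {
      last <- substring(cds, nchar(cds) - 2L, nchar(cds))
      if (!is.na(code[last]) && code[last] == "*") {
        warning("trimming terminal stop codon from CDS '", id, "'")
        cds <- substring(cds, 1L, nchar(cds) - 3L)
      }
    }
    if (nchar(cds) != 3L * np) {
      stop("length mismatch for '", id, "': CDS ", nchar(cds),
           " nt vs protein ", np, " aa (expected ", 3L * np, " nt)")
    }
    if (!allow_ambiguity && grepl("[^ACGT]", cds)) {
      stop("ambiguous nucleotide in CDS '", id,
           "' (use allow_ambiguity = TRUE to permit)")
    }
    tr <- translate(cds, code, allow_ambiguity = allow_ambiguity)
    if (tr != prot) {
      pv <- strsplit(prot, "")[[1]]
      tv <- strsplit(tr, "")[[1]]
      pos <- which(pv != tv)[1L]
      stop("translation mismatch for '", id, "' at residue ", pos,
           ": protein has '", pv[pos], "', CDS encodes '", tv[pos], "'")
    }
    codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
    cols <- strsplit(prot_gapped, "")[[1]]
    out <- character(length(cols))
    k <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        out[i] <- codons[k]
      }
    }
    paste(out, collapse = "")
  }, "")
  structure(rows, class = "codon_alignment",
            protein_alignment = protein_aln,
            codon_columns = nchar(protein_aln[[1L]]))
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x), "rows x",
      attr(x, "codon_columns"), "codons\n")
  invisible(x)
}

#' Write an alignment in relaxed sequential PHYLIP format
#'
#' @param aln Named character vector of equal-length rows.
#' @param path Output file.
#' @export
write_phylip <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(aln), nchar(aln[[1L]])), con)
  writeLines(sprintf("%s  %s", names(aln), unname(aln)), con)
  invisible(path)
}
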