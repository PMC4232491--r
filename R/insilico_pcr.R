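# In-silico PCR and tandem gene-model bridging.
#
# Amplicon prediction is exact-match by default: a forward primer binds the
# plus strand, the reverse primer binds the minus strand (its reverse
# complement occurs on the plus strand downstream), and the product spans both
# primer footprints. Bridging asks whether one cDNA's genomic exons overlap
# two adjacent predicted gene models — the signature of a split gene
# prediction that actually encodes a single protein.

#' Reverse complement of a nucleotide string
#' @param x Character scalar over A/C/G/T (IUPAC codes accepted).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

.check_primer <- function(primer, iupac = FALSE) {
  s <- toupper(unname(primer))
  if (!nzchar(s)) stop("empty primer")
  pat <- if (iupac) "[^ACGTRYSWKMBDHVN]" else "[^ACGT]"
  if (grepl(pat, s)) {
    stop("primer contains characters outside ",
         if (iupac) "the IUPAC alphabet" else "A/C/G/T", ": ", s)
  }
  s
}

#' Find primer binding sites on a template
#'
#' Reports all 0-based offsets of the primer on the plus strand and of its
#' reverse complement (minus-strand binding) with at most `max_mismatches`
#' mismatches.
#'
#' @param template Nucleotide sequence (character scalar).
#' @param primer Primer sequence, 5'->3'.
#' @param max_mismatches Allowed mismatches (default 0).
#' @param iupac Treat IUPAC degeneracy codes in the primer as ambiguity
#'   (default `FALSE`: strict A/C/G/T).
#' @return List with integer vectors `plus` and `minus` (0-based offsets of
#'   the matched footprint's left end).
#' @export
find_primer_sites <- function(template, primer, max_mismatches = 0L,
                              iupac = FALSE) {
  tmpl <- Biostrings::DNAString(toupper(unname(.as_single_seq(template))))
  p <- .check_primer(primer, iupac)
  if (nchar(p) >= length(tmpl)) stop("primer not shorter than template")
  hit0 <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), tmpl,
                                  max.mismatch = max_mismatches,
                                  fixed = !iupac)
    m@ranges@start - 1L
  }
  list(plus = hit0(p), minus = hit0(revcomp(p)))
}

#' Predict PCR amplicons
#'
#' Every combination of a plus-strand forward site and a minus-strand reverse
#' site with `forward_start < reverse_end` and product length at most
#' `max_product` is reported, sorted by length. Product length counts both
#' primer footprints.
#'
#' @param template Nucleotide template (named character scalar).
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param max_product Maximum product length in bases (default 10000).
#' @param max_mismatches Allowed mismatches per primer (default 0).
#' @param template_id Id for the report.
#' @return data.frame: `template_id`, `forward_start` (0-based),
#'   `reverse_end` (0-based exclusive), `length`, `product_sequence`.
#' @export
predict_amplicon <- function(template, forward, reverse,
                             max_product = 10000L, max_mismatches = 0L,
                             template_id = NULL) {
  s <- .as_single_seq(template)
  if (is.null(template_id)) template_id <- names(s) %||% "template"
  fwd <- find_primer_sites(s, forward, max_mismatches)$plus
  rev_sites <- find_primer_sites(s, reverse, max_mismatches)$minus
  rev_len <- nchar(.check_primer(reverse))
  empty <- data.frame(template_id = character(), forward_start = integer(),
                      reverse_end = integer(), length = integer(),
                      product_sequence = character(), stringsAsFactors = FALSE)
  if (length(fwd) == 0L || length(rev_sites) == 0L) return(empty)
  combos <- expand.grid(f = fwd, r = rev_sites)
  combos$end <- combos$r + rev_len
  combos$len <- combos$end - combos$f
  combos <- combos[combos$f < combos$end & combos$len <= max_product, ,
                   drop = FALSE]
  if (nrow(combos) == 0L) return(empty)
  combos <- combos[order(combos$len, combos$f), , drop = FALSE]
  data.frame(template_id = template_id, forward_start = combos$f,
             reverse_end = combos$end, length = combos$len,
             product_sequence = substring(toupper(unname(s)),
                                          combos$f + 1L, combos$end),
             stringsAsFactors = FALSE)
}

#' Published bridging-PCR primer pairs
#'
#' The primer pairs used to test whether split CCX gene predictions are
#' bridged by a single transcript: `CJ` for the *C. japonica*
#' Cja11479/Cja38547 locus (expected cDNA product 813 bp on the deposited
#' cDNA, genomic product 2443 bp) and `Hba` for the *H. bacteriophora*
#' Hba_19836/Hba_19835 locus (674 bp cDNA, 1623 bp genomic). Run against the
#' deposited cDNA accessions (KJ873055, KM009146) when those sequences are
#' available locally.
#'
#' @return Named list of `c(forward, reverse)` primer pairs.
#' @export
bridging_primers <- function() {
  list(
    CJ  = c(forward = "TACGTGAGCCATGGACATCACA",
            reverse = "TCGATACGTTGGATTGAGAATC"),
    Hba = c(forward = "TGCTCTACTCCTTGCTTCGTGCCCCGTA",
            reverse = "GGGAGTTACATTCATGGCATTTGGCAATGG")
  )
}

#' Construct a gene model
#'
#' @param id Gene id.
#' @param contig_id Contig/scaffold id.
#' @param exons Two-column matrix or data.frame of 0-based half-open exon
#'   intervals; must be sorted and non-overlapping.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return A `gene_model` list.
#' @export
gene_model <- function(id, contig_id, exons, strand = "+") {
  ex <- as.matrix(exons)
  if (ncol(ex) != 2L) stop("exons need 2 columns (start, end)")
  mode(ex) <- "integer"
  colnames(ex) <- c("start", "end")
  if (any(ex[, 2L] <= ex[, 1L])) stop("exon end must exceed start")
  if (nrow(ex) > 1L) {
    o <- order(ex[, 1L])
    ex <- ex[o, , drop = FALSE]
    if (any(ex[-1L, 1L] < ex[-nrow(ex), 2L])) stop("overlapping exons")
  }
  structure(list(id = id, contig_id = contig_id, strand = strand, exons = ex),
            class = "gene_model")
}

.model_span <- function(m) c(min(m$exons[, 1L]), max(m$exons[, 2L]))

.overlap_len <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

.merge_intervals <- function(iv) {
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- nrow(out)
    if (iv[i, 1L] <= out[last, 2L]) {
      out[last, 2L] <- max(out[last, 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Test whether a cDNA bridges two predicted gene models
#'
#' Computes the overlap in bases between a cDNA's genome-mapped exons and
#' each model's exon span; the cDNA bridges the models iff both overlaps are
#' positive. When it does, a merged gene model is returned whose exons are
#' the union of both models' exons and the cDNA exons (overlaps collapsed) —
#' the cDNA's structure extends the merged model beyond either prediction.
#'
#' @param cdna_exons Two-column matrix of the cDNA's genomic exon intervals
#'   (0-based half-open), all on the models' contig.
#' @param model_a,model_b [gene_model()] objects on the same contig, with
#'   non-overlapping spans.
#' @param cdna_id Id for the report.
#' @return A `bridge_report`: `cdna_id`, `model_a_id`, `model_b_id`,
#'   `bridges`, `covered_a`, `covered_b`, `merged_model` (or `NULL`).
#' @export
bridge_check <- function(cdna_exons, model_a, model_b, cdna_id = "cdna") {
  stopifnot(inherits(model_a, "gene_model"), inherits(model_b, "gene_model"))
  if (model_a$contig_id != model_b$contig_id) {
    stop("gene models lie on different contigs: ",
         model_a$contig_id, " vs ", model_b$contig_id)
  }
  ex <- as.matrix(cdna_exons)
  mode(ex) <- "integer"
  span_a <- .model_span(model_a)
  span_b <- .model_span(model_b)
  cov <- function(span) {
    sum(vapply(seq_len(nrow(ex)), function(i)
      .overlap_len(ex[i, 1L], ex[i, 2L], span[1L], span[2L]), integer(1)))
  }
  covered_a <- cov(span_a)
  covered_b <- cov(span_b)
  bridges <- covered_a > 0L && covered_b > 0L
  merged <- NULL
  if (bridges) {
    all_iv <- rbind(model_a$exons, model_b$exons,
                    matrix(ex, ncol = 2L,
                           dimnames = list(NULL, c("start", "end"))))
    merged <- gene_model(paste(model_a$id, model_b$id, sep = "+"),
                         model_a$contig_id, .merge_intervals(all_iv),
                         strand = model_a$strand)
  }
  structure(list(cdna_id = cdna_id, model_a_id = model_a$id,
                 model_b_id = model_b$id, bridges = bridges,
                 covered_a = covered_a, covered_b = covered_b,
                 merged_model = merged),
            class = "bridge_report")
}

#' @export
print.bridge_report <- function(x, ...) {
  cat(x$cdna_id, if (x$bridges) "bridges" else "does not bridge",
      x$model_a_id, "and", x$model_b_id,
      sprintf("(%d / %d bases covered)\n", x$covered_a, x$covered_b))
  invisible(x)
}

#' Read gene models from a 4-column TSV or GFF3
#'
#' TSV columns: id, contig, start (1-based inclusive), end (1-based
#' inclusive); one row per exon, grouped by id. GFF3 input (via rtracklayer)
#' uses `exon` features grouped by `Parent`/`ID`.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"gff3"`.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("GFF3 input needs the rtracklayer package")
    }
    g <- rtracklayer::import(path)
    g <- g[tolower(as.character(g$type)) == "exon"]
    grp <- as.character(if (!is.null(g$Parent) && any(lengths(g$Parent) > 0))
      unlist(g$Parent) else g$ID)
    tab <- data.frame(id = grp,
                      contig = as.character(GenomicRanges::seqnames(g)),
                      start = GenomicRanges::start(g),
                      end = GenomicRanges::end(g),
                      strand = as.character(GenomicRanges::strand(g)),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("id", "contig", "start", "end"),
                             stringsAsFactors = FALSE)
    tab$strand <- "+"
  }
  lapply(split(tab, tab$id), function(d) {
    gene_model(d$id[[1L]], d$contig[[1L]],
               cbind(d$start - 1L, d$end), strand = d$strand[[1L]])
  })
}
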