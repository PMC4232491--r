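# Synthetic-data generators: exchanger-like proteins with planted
# alpha-repeat motifs per subtype, and ortholog nucleotide/codon pairs with a
# controlled per-site substitution probability.
#
# All generators are pure functions of their arguments plus `seed`; the same
# seed always reproduces the same output.

.subtype_motifs <- list(
  NCX  = c(alpha1 = "GSSAPE", alpha2 = "GTSIPD"),
  NCKX = c(alpha1 = "GSSAPE", alpha2 = "GTSIPD"),   # K_DEP comes as a domain
  CCX  = c(alpha1 = "GNGAPD", alpha2 = "SNSIGD")
)

#' Simulate one exchanger-like protein
#'
#' Draws a random-background protein, plants the subtype's alpha-1/alpha-2
#' repeat motifs at the requested offsets, applies optional substitution
#' noise outside the planted motifs, and emits the domain annotations the
#' classifier expects for the subtype: NCX gets two CalX-beta plus two
#' Na_Ca_ex rows, NCKX the IPR004481 potassium-dependence signature plus a
#' Na_Ca_ex row, CCX a single Na_Ca_ex row. Motif content is never mutated,
#' so noise leaves subtype evidence intact by construction.
#'
#' @param subtype `"NCX"`, `"NCKX"` or `"CCX"`.
#' @param length Protein length in residues (default 900, a typical exchanger
#'   size).
#' @param alpha1_pos 0-based offset of the alpha-1 motif (default 60,
#'   following the N-terminal TM block).
#' @param alpha2_pos 0-based offset of the alpha-2 motif (default: alpha-1
#'   end plus a cytoplasmic-loop-sized gap drawn from 150-600 residues).
#' @param noise_rate Per-residue substitution probability outside the motifs.
#' @param seed Optional integer seed (RNG state restored on exit).
#' @param id Sequence id.
#' @return List: `id`, `sequence`, `label` (ground truth), `annotations`
#'   (data.frame in [read_domain_table()] layout).
#' @export
simulate_exchanger_protein <- function(subtype = c("NCX", "NCKX", "CCX"),
                                       length = 900L, alpha1_pos = 60L,
                                       alpha2_pos = NULL, noise_rate = 0,
                                       seed = NULL, id = NULL) {
  subtype <- match.arg(subtype)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  motifs <- .subtype_motifs[[subtype]]
  w1 <- nchar(motifs[["alpha1"]]); w2 <- nchar(motifs[["alpha2"]])
  if (is.null(alpha2_pos)) {
    # cytoplasmic-loop-sized gap, shrunk when the protein is short
    hi <- min(600L, length - w2 - alpha1_pos - w1)
    if (hi < 50L) stop("length too short to place both alpha repeats")
    lo <- min(150L, hi)
    alpha2_pos <- alpha1_pos + w1 + sample(lo:hi, 1L)
  }
  if (alpha1_pos + w1 > alpha2_pos) stop("planted motifs overlap")
  if (alpha2_pos + w2 > length) stop("alpha2 motif does not fit in length")
  if (is.null(id)) id <- paste0("sim_", subtype, "_", alpha1_pos)
  res <- sample(AA_ALPHABET, length, replace = TRUE)
  motif_idx <- c(alpha1_pos + seq_len(w1), alpha2_pos + seq_len(w2))
  res[alpha1_pos + seq_len(w1)] <- strsplit(motifs[["alpha1"]], "")[[1]]
  res[alpha2_pos + seq_len(w2)] <- strsplit(motifs[["alpha2"]], "")[[1]]
  if (noise_rate > 0) {
    outside <- setdiff(seq_len(length), motif_idx)
    hit <- outside[stats::runif(base::length(outside)) < noise_rate]
    if (base::length(hit)) {
      res[hit] <- vapply(res[hit], function(r)
        sample(setdiff(AA_ALPHABET, r), 1L), "")
    }
  }
  seq <- paste(res, collapse = "")
  loop_mid <- as.integer((alpha1_pos + w1 + alpha2_pos) / 2)
  ann <- switch(subtype,
    NCX = data.frame(
      protein_id = id,
      signature = c("PF03160", "PF03160", "PF01699", "PF01699"),
      start = c(loop_mid - 220L, loop_mid - 80L, alpha1_pos - 20L,
                alpha2_pos - 20L),
      end = c(loop_mid - 121L, loop_mid + 19L, alpha1_pos + 40L,
              alpha2_pos + 40L),
      interpro = c("IPR011992", "IPR011992", "IPR004837", "IPR004837"),
      stringsAsFactors = FALSE),
    NCKX = data.frame(
      protein_id = id,
      signature = c("Na_K_Ca_ex", "PF01699"),
      start = c(alpha1_pos - 20L, alpha2_pos - 20L),
      end = c(alpha1_pos + 40L, alpha2_pos + 40L),
      interpro = c("IPR004481", "IPR004837"),
      stringsAsFactors = FALSE),
    CCX = data.frame(
      protein_id = id, signature = "PF01699",
      start = alpha1_pos - 20L, end = alpha1_pos + 40L,
      interpro = "IPR004837", stringsAsFactors = FALSE))
  ann$start <- pmax(ann$start, 1L)
  ann$role <- unname(default_signature_aliases()[ann$signature])
  miss <- is.na(ann$role)
  ann$role[miss] <- unname(default_signature_aliases()[ann$interpro[miss]])
  ann$relevant <- !is.na(ann$role)
  list(id = id, sequence = seq, label = subtype, annotations = ann)
}

#' Simulate a labelled set of exchanger proteins
#'
#' @param n_per_subtype Proteins per subtype (default 100).
#' @param noise_rate Per-residue substitution probability outside motifs.
#' @param seed Integer seed.
#' @param length Protein length.
#' @return List: `sequences` (named character vector), `annotations`
#'   (combined domain table), `truth` (data.frame `protein_id`, `label`).
#' @export
simulate_exchanger_set <- function(n_per_subtype = 100L, noise_rate = 0,
                                   seed = 1L, length = 900L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  subtypes <- rep(c("NCX", "NCKX", "CCX"), each = n_per_subtype)
  sims <- lapply(seq_along(subtypes), function(i) {
    simulate_exchanger_protein(subtypes[i], length = length,
                               noise_rate = noise_rate,
                               id = sprintf("sim_%s_%03d", subtypes[i],
                                            ((i - 1L) %% n_per_subtype) + 1L))
  })
  list(
    sequences = stats::setNames(vapply(sims, `[[`, "", "sequence"),
                                vapply(sims, `[[`, "", "id")),
    annotations = do.call(rbind, lapply(sims, `[[`, "annotations")),
    truth = data.frame(protein_id = vapply(sims, `[[`, "", "id"),
                       label = vapply(sims, `[[`, "", "label"),
                       stringsAsFactors = FALSE)
  )
}

#' Simulate an ortholog sequence pair
#'
#' Draws a uniform-random ancestor and mutates each site independently with
#' probability `rate` under a Jukes-Cantor kernel (a mutated site takes one
#' of the other three bases uniformly). In the codon modes the ancestor is a
#' run of random sense codons and proposed mutations are rejected when they
#' would create a stop codon (`codon_free`) or change the encoded amino acid
#' (`codon_synonymous_only`); rejected sites stay ancestral.
#'
#' @param length Sequence length in bases (rounded down to whole codons in
#'   the codon modes); default 10000.
#' @param rate Per-site substitution probability, `< 0.75` (the Jukes-Cantor
#'   correction domain).
#' @param mode `"nucleotide"`, `"codon_synonymous_only"` or `"codon_free"`.
#' @param seed Optional integer seed.
#' @param code Genetic-code table (codon modes).
#' @return List: `ancestor`, `derived` (character scalars), `rate`,
#'   `realized` (observed differing-site fraction), `mode`.
#' @export
simulate_ortholog_pair <- function(length = 10000L, rate = 0.1,
                                   mode = c("nucleotide",
                                            "codon_synonymous_only",
                                            "codon_free"),
                                   seed = NULL,
                                   code = Biostrings::GENETIC_CODE) {
  mode <- match.arg(mode)
  stopifnot(rate >= 0, rate < 0.75)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (mode == "nucleotide") {
    anc <- sample(NT_ALPHABET, length, replace = TRUE)
    der <- anc
    hit <- which(stats::runif(length) < rate)
    if (base::length(hit)) {
      der[hit] <- vapply(anc[hit], function(b)
        sample(setdiff(NT_ALPHABET, b), 1L), "")
    }
  } else {
    n_codons <- length %/% 3L
    if (n_codons < 1L) stop("length below one codon")
    sense <- names(code)[code != "*"]
    anc_codons <- sample(sense, n_codons, replace = TRUE)
    anc <- strsplit(paste(anc_codons, collapse = ""), "")[[1]]
    der <- anc
    hit <- which(stats::runif(base::length(anc)) < rate)
    codon_used <- logical(n_codons)
    for (i in hit) {
      ci <- (i - 1L) %/% 3L              # codon index, 0-based
      # synonymous-only: at most one substitution per codon, so that every
      # NG86 mutational ordering of the realized differences is synonymous
      # (two same-codon synonymous steps can have a nonsynonymous reordering)
      if (mode == "codon_synonymous_only" && codon_used[ci + 1L]) next
      prop <- sample(setdiff(NT_ALPHABET, der[i]), 1L)
      cod <- der[ci * 3L + 1:3]
      old_codon <- paste(cod, collapse = "")
      cod[(i - 1L) %% 3L + 1L] <- prop
      new_codon <- paste(cod, collapse = "")
      accept <- code[[new_codon]] != "*" &&
        (mode == "codon_free" || code[[new_codon]] == code[[old_codon]])
      if (accept) {
        der[i] <- prop
        codon_used[ci + 1L] <- TRUE
      }
    }
  }
  list(ancestor = paste(anc, collapse = ""),
       derived = paste(der, collapse = ""),
       rate = rate, realized = mean(anc != der), mode = mode)
}
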