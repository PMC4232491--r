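# Rule-based NCX / NCKX / CCX subtype classification.
#
# Decision tree, first matching rule wins:
#   1. potassium-dependent exchanger domain (role K_DEP)      -> NCKX
#   2. exchanger evidence + tandem CalX-beta (>= min_calx)    -> NCX
#   3. exchanger evidence + no CalX-beta                      -> CCX
#   4. otherwise                                              -> UNCLASSIFIED
# "Exchanger evidence" is a Na_Ca_ex-type domain annotation or a paired
# alpha-1/alpha-2 repeat of the matching motif family.

#' Collect classification evidence for one protein
#'
#' Combines role-mapped domain annotations (see [read_domain_table()]) with
#' alpha-repeat pair reports from both the NCX-type and CCX-type motif
#' libraries.
#'
#' @param seq Ungapped protein sequence (named character scalar).
#' @param domains Optional domain-annotation data.frame for this protein (as
#'   from [read_domain_table()]; rows for other proteins are ignored).
#' @param seq_id Protein id (defaults to the name of `seq`).
#' @param library Motif library, see [motif_library()].
#' @param min_gap,max_gap Alpha-repeat spacing bounds (residues).
#' @return A `subtype_evidence` list: `has_k_dep_domain`,
#'   `exchanger_domain_count`, `calx_beta_count`, `ncx_pair`, `ccx_pair`,
#'   `divergent`, `warnings`.
#' @export
collect_evidence <- function(seq, domains = NULL, seq_id = NULL,
                             library = motif_library(),
                             min_gap = 50L, max_gap = 1000L) {
  s <- .as_single_seq(seq)
  if (is.null(seq_id)) seq_id <- names(s) %||% "seq"
  warnings <- character()
  k_dep <- 0L; exch <- 0L; calx <- 0L
  if (!is.null(domains) && nrow(domains)) {
    d <- domains[domains$protein_id == seq_id & domains$relevant, ,
                 drop = FALSE]
    over <- d$end > nchar(s)
    if (any(over)) {
      warnings <- c(warnings, paste0("domain ", d$signature[over],
                                     " extends past sequence end"))
    }
    k_dep <- sum(d$role == "K_DEP")
    exch <- sum(d$role == "EXCHANGER")
    calx <- sum(d$role == "CALX_BETA")
  }
  ncx_pair <- find_alpha_repeat_pair(s, library$ncx_alpha1,
                                     library$ncx_alpha2_observed,
                                     min_gap, max_gap, seq_id = seq_id)
  ccx_pair <- find_alpha_repeat_pair(s, library$ccx_alpha1,
                                     library$ccx_alpha2,
                                     min_gap, max_gap, seq_id = seq_id)
  # NCKX potassium-dependence note (no printed coordinate exists for the
  # conserved aspartate, so this is informational only, never a rule)
  alpha2_final_d <- (!is.null(ncx_pair$alpha2) &&
                       endsWith(ncx_pair$alpha2$matched, "D"))
  structure(list(
    protein_id = seq_id,
    has_k_dep_domain = k_dep > 0L,
    k_dep_count = k_dep,
    exchanger_domain_count = exch,
    calx_beta_count = calx,
    ncx_pair = ncx_pair,
    ccx_pair = ccx_pair,
    alpha2_final_aspartate = alpha2_final_d,
    divergent = (ncx_pair$divergent || ccx_pair$divergent) &&
      !(ncx_pair$paired || ccx_pair$paired),
    warnings = warnings
  ), class = "subtype_evidence")
}

#' Classify one protein from its evidence record
#'
#' Applies the subtype decision tree (see the module header); the first
#' matching rule wins, so a potassium-dependent domain always dominates.
#' NCX requires `min_calx` CalX-beta hits (default 2: the tandem CBD1/CBD2
#' arrangement); pass `min_calx = 1` for fragmentary proteins.
#'
#' @param ev A [collect_evidence()] record.
#' @param min_calx Minimum CalX-beta count for an NCX call (default 2).
#' @return A `subtype_call`: `protein_id`, `label` (one of `"NCX"`, `"NCKX"`,
#'   `"CCX"`, `"UNCLASSIFIED"`), `divergent_candidate`, `rationale` (ordered
#'   character vector of fired rules and supporting evidence).
#' @export
classify_protein <- function(ev, min_calx = 2L) {
  stopifnot(inherits(ev, "subtype_evidence"))
  rationale <- character()
  ncx_exch <- ev$exchanger_domain_count >= 1L || ev$ncx_pair$paired
  ccx_exch <- ev$exchanger_domain_count >= 1L || ev$ccx_pair$paired
  if (ev$has_k_dep_domain) {
    label <- "NCKX"
    rationale <- c("rule1: K_DEP domain present",
                   sprintf("k_dep_count=%d", ev$k_dep_count))
  } else if (ncx_exch && ev$calx_beta_count >= min_calx) {
    label <- "NCX"
    rationale <- c(sprintf("rule2: exchanger evidence (%s) with %d CalX-beta",
                           if (ev$exchanger_domain_count >= 1L)
                             "domain" else "alpha-repeat pair",
                           ev$calx_beta_count))
  } else if (ccx_exch && ev$calx_beta_count == 0L) {
    label <- "CCX"
    rationale <- c(sprintf("rule3: exchanger evidence (%s), no CalX-beta",
                           if (ev$exchanger_domain_count >= 1L)
                             "domain" else "alpha-repeat pair"))
    if (ev$exchanger_domain_count == 0L) {
      rationale <- c(rationale, "motif-only call (lower confidence)")
    }
  } else {
    label <- "UNCLASSIFIED"
    if (ev$ncx_pair$paired || ev$ccx_pair$paired ||
        ev$exchanger_domain_count > 0L || ev$calx_beta_count > 0L) {
      rationale <- "rule4: evidence present but no rule satisfied"
    }
  }
  if (ev$alpha2_final_aspartate) {
    rationale <- c(rationale, "note: alpha2 ends in aspartate (K-dependence)")
  }
  structure(list(protein_id = ev$protein_id, label = label,
                 divergent_candidate = ev$divergent,
                 rationale = rationale, evidence = ev),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat(x$protein_id, "->", x$label,
      if (x$divergent_candidate) "[divergent candidate]" else "", "\n")
  if (length(x$rationale)) cat("  ", paste(x$rationale, collapse = "; "), "\n")
  invisible(x)
}

#' Classify a batch of proteins
#'
#' Applies [collect_evidence()] and [classify_protein()] to every sequence,
#' preserving input order. Equivalent to the element-wise per-protein calls.
#'
#' @param seqs Named character vector of ungapped protein sequences.
#' @param domains Optional domain table ([read_domain_table()]); ids absent
#'   from `seqs` are warned about, not fatal.
#' @param min_calx,min_gap,max_gap,library See [classify_protein()] and
#'   [collect_evidence()].
#' @param keep_unclassified Keep `UNCLASSIFIED` rows (default `TRUE`; the CLI
#'   drops them unless asked).
#' @return data.frame: `protein_id`, `label`, `divergent_candidate`,
#'   `rationale` (semicolon-joined), domain counts and pairing flags.
#' @export
classify_batch <- function(seqs, domains = NULL, min_calx = 2L,
                           library = motif_library(),
                           min_gap = 50L, max_gap = 1000L,
                           keep_unclassified = TRUE) {
  if (length(seqs) == 0L) {
    return(data.frame(protein_id = character(), label = character(),
                      divergent_candidate = logical(), rationale = character(),
                      k_dep = integer(), exchanger_domains = integer(),
                      calx_beta = integer(), ncx_paired = logical(),
                      ccx_paired = logical(), stringsAsFactors = FALSE))
  }
  if (!is.null(domains) && nrow(domains)) {
    orphan <- setdiff(unique(domains$protein_id), names(seqs))
    if (length(orphan)) {
      warning("domain annotations for unknown protein ids: ",
              paste(orphan, collapse = ", "))
    }
  }
  calls <- lapply(names(seqs), function(id) {
    ev <- collect_evidence(seqs[id], domains, seq_id = id, library = library,
                           min_gap = min_gap, max_gap = max_gap)
    classify_protein(ev, min_calx = min_calx)
  })
  out <- data.frame(
    protein_id = vapply(calls, `[[`, "", "protein_id"),
    label = vapply(calls, `[[`, "", "label"),
    divergent_candidate = vapply(calls, `[[`, NA, "divergent_candidate"),
    rationale = vapply(calls, function(x)
      paste(x$rationale, collapse = "; "), ""),
    k_dep = vapply(calls, function(x) x$evidence$k_dep_count, 0L),
    exchanger_domains = vapply(calls, function(x)
      x$evidence$exchanger_domain_count, 0L),
    calx_beta = vapply(calls, function(x) x$evidence$calx_beta_count, 0L),
    ncx_paired = vapply(calls, function(x) x$evidence$ncx_pair$paired, NA),
    ccx_paired = vapply(calls, function(x) x$evidence$ccx_pair$paired, NA),
    stringsAsFactors = FALSE)
  if (!keep_unclassified) out <- out[out$label != "UNCLASSIFIED", ,
                                     drop = FALSE]
  message("classified ", nrow(out), " proteins: ",
          paste(names(table(out$label)), table(out$label),
                sep = "=", collapse = ", "))
  out
}
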