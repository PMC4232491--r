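# helpers shared by the classifier tests: evidence built from planted
# sequences and synthetic domain rows

.domain_row <- function(id, sig, start = 10L, end = 100L, ipr = NA) {
  data.frame(protein_id = id, signature = sig, start = start, end = end,
             interpro = ipr,
             role = unname(default_signature_aliases()[sig]),
             relevant = sig %in% names(default_signature_aliases()),
             stringsAsFactors = FALSE)
}

.planted_seq <- function(a1 = NA, a2 = NA, len = 600) {
  chars <- strsplit(strrep("K", len), "")[[1]]
  if (!is.na(a1)) chars[61:66] <- strsplit(a1, "")[[1]]
  if (!is.na(a2)) chars[401:406] <- strsplit(a2, "")[[1]]
  c(p = paste(chars, collapse = ""))
}

test_that("collect_evidence counts roles and detects motif pairs", {
  s <- .planted_seq()
  d <- rbind(.domain_row("p", "Na_K_Ca_ex"), .domain_row("p", "PF01699"),
             .domain_row("p", "PF01699", 200, 300))
  ev <- collect_evidence(s, d, seq_id = "p")
  expect_true(ev$has_k_dep_domain)
  expect_identical(ev$exchanger_domain_count, 2L)
  expect_identical(ev$calx_beta_count, 0L)

  ev2 <- collect_evidence(.planted_seq("GNGAPD", "SNSIGD"), seq_id = "p")
  expect_true(ev2$ccx_pair$paired)
  expect_false(ev2$ncx_pair$paired)

  ev3 <- collect_evidence(c(p = "MKVLT"), seq_id = "p")
  expect_false(ev3$has_k_dep_domain)
  expect_identical(ev3$exchanger_domain_count, 0L)
  expect_false(ev3$ncx_pair$paired || ev3$ccx_pair$paired)

  # domain past the sequence end: warning recorded, evidence still built
  ev4 <- collect_evidence(c(p = "MKVLT"), .domain_row("p", "PF03160", 1, 999),
                          seq_id = "p")
  expect_identical(ev4$calx_beta_count, 1L)
  expect_match(ev4$warnings, "past sequence end")
})

test_that("classify_protein follows the decision tree in order", {
  # rule 1 precedes rule 2: K_DEP dominates even with tandem CalX-beta
  ev <- collect_evidence(.planted_seq(),
                         rbind(.domain_row("p", "Na_K_Ca_ex"),
                               .domain_row("p", "PF03160"),
                               .domain_row("p", "PF03160", 200, 300)),
                         seq_id = "p")
  expect_identical(classify_protein(ev)$label, "NCKX")

  # exchanger domains + tandem CalX-beta -> NCX
  ev <- collect_evidence(.planted_seq(),
                         rbind(.domain_row("p", "PF01699"),
                               .domain_row("p", "PF01699", 150, 250),
                               .domain_row("p", "PF03160", 300, 350),
                               .domain_row("p", "PF03160", 360, 410)),
                         seq_id = "p")
  expect_identical(classify_protein(ev)$label, "NCX")

  # exchanger evidence without CalX-beta -> CCX
  ev <- collect_evidence(.planted_seq("GNGAPD", "SNSIGD"),
                         .domain_row("p", "PF01699"), seq_id = "p")
  expect_identical(classify_protein(ev)$label, "CCX")

  # nothing -> UNCLASSIFIED
  ev <- collect_evidence(c(p = "MKVLT"), seq_id = "p")
  call <- classify_protein(ev)
  expect_identical(call$label, "UNCLASSIFIED")
})

test_that("precedence property: adding K_DEP can only flip a label to NCKX", {
  base_evs <- list(
    collect_evidence(.planted_seq("GSSAPE", "GTSIPD"),
                     rbind(.domain_row("p", "PF03160"),
                           .domain_row("p", "PF03160", 200, 300)),
                     seq_id = "p"),
    collect_evidence(.planted_seq("GNGAPD", "SNSIGD"), seq_id = "p"),
    collect_evidence(c(p = "MKVLT"), seq_id = "p"))
  for (ev in base_evs) {
    with_k <- ev
    with_k$has_k_dep_domain <- TRUE
    with_k$k_dep_count <- ev$k_dep_count + 1L
    expect_identical(classify_protein(with_k)$label, "NCKX")
  }
})

test_that("monotonicity: dropping CalX-beta from an NCX with a CCX pair", {
  s <- .planted_seq("GNGAPD", "SNSIGD")
  with_calx <- collect_evidence(
    s, rbind(.domain_row("p", "PF03160"), .domain_row("p", "PF03160", 2, 99),
             .domain_row("p", "PF01699", 150, 250)), seq_id = "p")
  expect_identical(classify_protein(with_calx)$label, "NCX")
  without <- collect_evidence(s, .domain_row("p", "PF01699", 150, 250),
                              seq_id = "p")
  expect_true(classify_protein(without)$label %in% c("CCX", "UNCLASSIFIED"))
  expect_identical(classify_protein(without)$label, "CCX")
})

test_that("min_calx = 1 admits fragmentary NCX proteins", {
  ev <- collect_evidence(.planted_seq("GSSAPE", "GTSIPD"),
                         .domain_row("p", "PF03160"), seq_id = "p")
  expect_identical(classify_protein(ev)$label, "UNCLASSIFIED")
  expect_identical(classify_protein(ev, min_calx = 1L)$label, "NCX")
})

test_that("classify_batch equals element-wise classification", {
  set.seed(5)
  sim <- simulate_exchanger_set(n_per_subtype = 4, seed = 99, length = 700)
  batch <- suppressMessages(classify_batch(sim$sequences, sim$annotations))
  expect_identical(nrow(batch), length(sim$sequences))
  expect_identical(batch$protein_id, names(sim$sequences))
  elementwise <- vapply(names(sim$sequences), function(id) {
    ev <- collect_evidence(sim$sequences[id], sim$annotations, seq_id = id)
    classify_protein(ev)$label
  }, "")
  expect_identical(batch$label, unname(elementwise))
  # and a second run is identical (determinism)
  batch2 <- suppressMessages(classify_batch(sim$sequences, sim$annotations))
  expect_identical(batch, batch2)
})

test_that("classify_batch edge cases", {
  empty <- suppressMessages(classify_batch(setNames(character(), character())))
  expect_identical(nrow(empty), 0L)
  expect_warning(suppressMessages(
    classify_batch(c(a = "MKVLT"), .domain_row("ghost", "PF01699"))),
    "unknown protein ids")
  batch <- suppressMessages(
    classify_batch(c(a = "MKVLT"), keep_unclassified = FALSE))
  expect_identical(nrow(batch), 0L)
})
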