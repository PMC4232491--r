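test_that("parse_pattern handles letters, groups and wildcards", {
  p <- parse_pattern("GTS(I/V/L)PD", "a2")
  expect_length(p$positions, 6)
  expect_setequal(p$positions[[4]], c("I", "V", "L"))
  expect_identical(p$positions[[1]], "G")

  p2 <- parse_pattern("(G/S)(N/D)SxGD", "c2")
  expect_length(p2$positions, 6)
  expect_length(p2$positions[[4]], 20)
  expect_setequal(p2$positions[[1]], c("G", "S"))

  # source text round-trips
  for (txt in c("G(S/G)SAPE", "GNG(A/S)PD", "(A/S)N(S/C)(V/I)GD")) {
    expect_identical(parse_pattern(txt)$source_text, txt)
  }

  expect_error(parse_pattern("G(S/"), "unbalanced")
  expect_error(parse_pattern("G()A"), "empty")
  expect_error(parse_pattern("G(S//G)A"), "misplaced")
  expect_error(parse_pattern("GB1"), "illegal character")
  expect_error(parse_pattern(""), "empty pattern")
})

test_that("scan_pattern matches spec examples", {
  expect_identical(
    scan_pattern(c(s = "MAGSSAPEKL"), parse_pattern("G(S/G)SAPE"))$offset, 2L)
  expect_identical(
    scan_pattern(c(s = "MAGSSAPEKL"), parse_pattern("G(S/G)SAPE"))$matched,
    "GSSAPE")
  expect_identical(
    nrow(scan_pattern(c(s = "GNGTPD"), parse_pattern("GNG(A/S)PD"))), 0L)
  expect_identical(
    scan_pattern(c(s = "SNSIGD"), parse_pattern("(G/S)(N/D)SxGD"))$offset, 0L)
  # overlapping hits all reported; pattern longer than sequence -> empty
  expect_identical(scan_pattern(c(s = "AAAA"), parse_pattern("AA"))$offset,
                   0:2)
  expect_identical(nrow(scan_pattern(c(s = "MK"), parse_pattern("MKVLL"))), 0L)
  expect_error(scan_pattern(c(s = "MK-V"), parse_pattern("MK")), "gapped")
})

test_that("scan_pattern equals the brute-force oracle on random input", {
  set.seed(11)
  pats <- lapply(c("G(S/G)SAPE", "GTS(I/V/L)PD", "(G/S)(N/D)SxGD",
                   "A(C/D)x(E/F/G)H"), parse_pattern)
  for (rep in 1:50) {
    s <- random_protein(sample(4:80, 1))
    for (p in pats) {
      expect_identical(scan_pattern(c(x = s), p)$offset,
                       oracle_pattern_hits(s, p$positions),
                       info = s)
    }
  }
})

test_that("build_pswm reproduces the hand-evaluated log-odds", {
  m <- build_pswm(rep("GNGAPD", 4), pseudocount = 0.1)
  expected <- log2((4.1 / 6) / 0.05)
  for (j in 1:6) {
    cons <- substr("GNGAPD", j, j)
    expect_equal(unname(m$scores[j, cons]), expected, tolerance = 1e-12)
  }
  expect_equal(m$max_score, 6 * expected, tolerance = 1e-12)
  expect_identical(m$consensus, "GNGAPD")

  expect_error(build_pswm(c("AB", "ABC")), "mixed lengths")
  expect_error(build_pswm(character()), "at least one")
  expect_warning(m0 <- build_pswm(c("GG", "GG"), pseudocount = 0), "-Inf")
  expect_true(m0$has_neg_inf)
})

test_that("uniform counts with uniform background give all-zero scores", {
  # each residue seen equally often per column
  inst <- vapply(AA, function(a) paste0(a, a), "")
  m <- build_pswm(inst, pseudocount = 0.5)
  expect_true(all(abs(m$scores) < 1e-12))
})

test_that("scan_pswm: consensus maximality, thresholds, ordering", {
  m <- build_pswm(c("GNGAPD", "GNGSPD", "GNGAPD"), pseudocount = 0.5)
  seq <- c(x = paste0("MKL", m$consensus, "TTR"))
  top <- scan_pswm(seq, m, min_relative_score = 0)[1, ]
  expect_equal(top$relative_score, 1, tolerance = 1e-12)
  expect_identical(top$offset, 3L)
  # threshold 1 with no exact-consensus window -> empty
  expect_identical(nrow(scan_pswm(c(x = "MKLMKLMKL"), m, 1)), 0L)
  # shorter than width -> empty
  expect_identical(nrow(scan_pswm(c(x = "MKL"), m, 0)), 0L)
  # sorted by descending score then offset
  h <- scan_pswm(c(x = paste0(m$consensus, "A", m$consensus)), m, 0)
  expect_true(all(diff(h$score) <= 0))
})

test_that("scan_pswm equals exhaustive window scoring on random input", {
  set.seed(23)
  for (rep in 1:30) {
    inst <- vapply(1:4, function(i) random_protein(5), "")
    m <- build_pswm(inst, pseudocount = runif(1, 0.1, 2))
    s <- random_protein(sample(5:60, 1))
    got <- scan_pswm(c(x = s), m, min_relative_score = -Inf)
    want <- oracle_pswm_scores(s, m$scores)
    expect_equal(sort(got$score), sort(want), tolerance = 1e-9)
    expect_equal(got$score[order(got$offset)], want, tolerance = 1e-9)
    expect_true(all(got$relative_score <= 1 + 1e-12))
  }
})

test_that("find_alpha_repeat_pair applies spacing and divergence rules", {
  lib <- motif_library()
  mk <- function(a1_at, a2_at, len = 400, a1 = "GSSAPE", a2 = "GTSIPD") {
    chars <- strsplit(strrep("K", len), "")[[1]]
    if (!is.na(a1_at)) chars[a1_at + 1:6] <- strsplit(a1, "")[[1]]
    if (!is.na(a2_at)) chars[a2_at + 1:6] <- strsplit(a2, "")[[1]]
    c(x = paste(chars, collapse = ""))
  }
  r <- find_alpha_repeat_pair(mk(40, 300), lib$ncx_alpha1,
                              lib$ncx_alpha2_observed, 50, 800)
  expect_true(r$paired)
  expect_false(r$divergent)
  expect_identical(r$alpha1$offset, 40L)
  expect_identical(r$alpha2$offset, 300L)

  r <- find_alpha_repeat_pair(mk(40, NA), lib$ncx_alpha1,
                              lib$ncx_alpha2_observed, 50, 800)
  expect_false(r$paired)
  expect_true(r$divergent)

  # spacing too tight: alpha2 at 50 with min_gap 50 means gap 4 < 50
  r <- find_alpha_repeat_pair(mk(40, 50), lib$ncx_alpha1,
                              lib$ncx_alpha2_observed, 50, 800)
  expect_false(r$paired)
  expect_false(r$divergent)   # both repeats present, just unpaired

  expect_error(find_alpha_repeat_pair(mk(40, 300), lib$ncx_alpha1,
                                      lib$ncx_alpha2, 100, 50),
               "min_gap")
})

test_that("PSWMs work as alpha-repeat detectors in pair search", {
  m1 <- build_pswm(c("GSSAPE", "GGSAPE"), label = "a1")
  m2 <- build_pswm(c("GTSIPD", "GTSVPD"), label = "a2")
  chars <- strsplit(strrep("K", 500), "")[[1]]
  chars[61:66] <- strsplit("GSSAPE", "")[[1]]
  chars[401:406] <- strsplit("GTSVPD", "")[[1]]
  r <- find_alpha_repeat_pair(c(x = paste(chars, collapse = "")), m1, m2,
                              min_gap = 50, max_gap = 1000,
                              min_relative_score = 0.9)
  expect_true(r$paired)
})

test_that("write_pswm / read_pswm round-trips scores and metadata", {
  m <- build_pswm(c("GNGAPD", "GNGSPD"), pseudocount = 0.25, label = "ccx")
  f <- withr::local_tempfile(fileext = ".pswm")
  write_pswm(m, f)
  back <- read_pswm(f)
  expect_equal(back$scores, m$scores, tolerance = 1e-12)
  expect_identical(back$label, m$label)
  expect_equal(back$pseudocount, m$pseudocount)
  expect_equal(back$max_score, m$max_score, tolerance = 1e-12)
})

test_that("built-in motif library matches the published patterns", {
  lib <- motif_library()
  expect_identical(lib$ncx_alpha1$source_text, "G(S/G)SAPE")
  expect_identical(lib$ccx_alpha2$source_text, "(G/S)(N/D)SxGD")
  # observed CCX alpha2 form accepts SNSIGD? no: (A/S)N(S/C)(V/I)GD
  expect_identical(
    scan_pattern(c(s = "SNSIGD"), lib$ccx_alpha2_observed)$offset, 0L)
})
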