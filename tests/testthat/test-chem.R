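# Formula parsing, mass computation, pharmacokinetic screening.

test_that("parse_formula reads plain and subscript-markup formulas", {
  expect_equal(parse_formula("CCaO_3_"), c(C = 1L, Ca = 1L, O = 3L))
  expect_equal(parse_formula("C_29_H_50_O"), c(C = 29L, H = 50L, O = 1L))
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parse_formula("Al"), c(Al = 1L))
  # repeated element symbols accumulate
  expect_equal(parse_formula("CH3CH3")[["C"]], 2L)
})

test_that("parse_formula rejects unknown elements and garbled input", {
  expect_error(parse_formula("Xx2"), "unknown element")
  expect_error(parse_formula("Qq"), "unknown element")
  expect_error(parse_formula(""), "empty")
  expect_error(parse_formula("C2#O"), "garbled")
  expect_error(parse_formula("2CO"), "garbled")
})

test_that("molecular_mass reproduces worked masses in both modes", {
  # average-mode mineral, monoisotopic sterol, hand-summed water
  expect_equal(round_half_up(molecular_mass(c(C = 1, Ca = 1, O = 3)), 3),
               100.087)
  expect_equal(round_half_up(
    molecular_mass(c(C = 29, H = 50, O = 1), "monoisotopic"), 3), 414.386)
  expect_equal(round_half_up(molecular_mass(c(H = 2, O = 1)), 3), 18.015)
  expect_error(molecular_mass(c(Zz = 1)), "missing from weight table")
})

test_that("mass is additive and monoisotopic <= average for carbon formulas", {
  set.seed(42)
  # Fe is excluded from the ordering check: its principal isotope (56Fe)
  # is heavier than the abundance-weighted standard weight, so the
  # monoisotopic <= average ordering only holds for the organic elements.
  els <- setdiff(atomic_weights()$element, "Fe")
  for (rep in 1:25) {
    pick_a <- sample(els, sample(1:4, 1))
    pick_b <- sample(els, sample(1:4, 1))
    a <- stats::setNames(sample(1:20, length(pick_a), TRUE), pick_a)
    b <- stats::setNames(sample(1:20, length(pick_b), TRUE), pick_b)
    ab <- tapply(c(a, b), names(c(a, b)), sum)
    for (mode in c("average", "monoisotopic")) {
      expect_equal(molecular_mass(ab, mode),
                   molecular_mass(a, mode) + molecular_mass(b, mode))
    }
    with_c <- c(a[names(a) != "C"], C = 3L)
    expect_lte(molecular_mass(with_c, "monoisotopic"),
               molecular_mass(with_c, "average"))
  }
})

test_that("passes_filter applies inclusive cuts, strict adjusted P", {
  tc <- data.frame(source_rule = "TCMSP", OB = c(30, 29.99, 31),
                   caco2 = c(0.4, 0.9, 0.39), DL = c(0.18, 0.5, 0.5))
  expect_equal(passes_filter(tc), c(TRUE, FALSE, FALSE))
  bm <- data.frame(source_rule = "BATMAN", score = c(20, 20, 19.9),
                   adj_p = c(0.05, 0.049, 0.01))
  expect_equal(passes_filter(bm), c(FALSE, TRUE, FALSE))
})

test_that("passes_filter errors on missing required fields", {
  expect_error(passes_filter(data.frame(source_rule = "TCMSP", OB = 50,
                                        caco2 = 1, DL = NA)),
               "missing TCMSP field 'DL'")
  expect_error(passes_filter(data.frame(source_rule = "BATMAN", score = 30)),
               "missing BATMAN field 'adj_p'")
  expect_error(passes_filter(data.frame(source_rule = "OTHER", OB = 1)),
               "unknown source_rule")
})

test_that("raising any TCMSP threshold never grows the candidate set", {
  set.seed(7)
  tb <- data.frame(herb_latin = "H", herb_pinyin = "h",
                   name = sprintf("c%02d", 1:40), compound_id = as.character(1:40),
                   source_rule = "TCMSP", OB = runif(40, 0, 100),
                   caco2 = runif(40, -1, 2), DL = runif(40, 0, 1))
  base <- select_candidates(list(tb))
  for (bump in list(pk_thresholds(ob_min = 50),
                    pk_thresholds(caco2_min = 0.9),
                    pk_thresholds(dl_min = 0.5))) {
    tighter <- select_candidates(list(tb), bump)
    expect_true(all(tighter$name %in% base$name))
    expect_lte(nrow(tighter), nrow(base))
  }
})

test_that("dedup on the packaged ten-row worked example yields 9 candidates", {
  t2 <- read_table2()
  rows <- split(t2, factor(t2$herb_latin, unique(t2$herb_latin)))
  cands <- select_candidates(rows, prefiltered = TRUE)
  expect_equal(nrow(cands), 9L)
  expect_equal(anyDuplicated(tolower(cands$name)), 0L)
  sito <- cands[cands$n_herbs == 2L, ]
  expect_equal(nrow(sito), 1L)
  expect_equal(sort(strsplit(sito$herbs, ";")[[1]]),
               c("Bulbus Fritillariae Ferganensis", "Radix Scrophulariae"))
  # the shared compound keeps one row; the case-distinct sterol stays separate
  expect_equal(sum(cands$n_herbs), 10L)
})

test_that("identical single compound in two herbs dedups to one candidate", {
  mk <- function(herb) data.frame(herb_latin = herb, herb_pinyin = herb,
                                  name = "compoundX", compound_id = "1",
                                  source_rule = "TCMSP", OB = 50, caco2 = 1,
                                  DL = 0.5)
  cands <- select_candidates(list(mk("Herb A"), mk("Herb B")))
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$herbs, "Herb A;Herb B")
  expect_equal(cands$n_herbs, 2L)
})

test_that("candidate set size is bounded by input size with unique names", {
  set.seed(11)
  tbs <- lapply(1:3, function(h) {
    n <- sample(5:15, 1)
    data.frame(herb_latin = paste("Herb", h), herb_pinyin = "x",
               name = sample(sprintf("c%02d", 1:10), n, TRUE),
               compound_id = as.character(seq_len(n)), source_rule = "TCMSP",
               OB = runif(n, 0, 100), caco2 = runif(n, -1, 2),
               DL = runif(n, 0, 1))
  })
  cands <- select_candidates(tbs)
  expect_lte(nrow(cands), sum(vapply(tbs, nrow, integer(1))))
  expect_equal(anyDuplicated(tolower(cands$name)), 0L)
})
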