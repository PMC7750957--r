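test_that("flexibility window is a convex combination: homopolymer profile equals B", {
  b_a <- get_scale("vihinen")$values[["A"]]
  p <- flexibility_profile(strrep("A", 9))
  expect_equal(p$values, b_a, tolerance = 1e-12)
  expect_equal(p$start_position, 5L)
  # window count: length-10 sequence gives a 2-value profile
  p10 <- flexibility_profile(strrep("A", 10))
  expect_length(p10$values, 2L)
  expect_error(flexibility_profile("ACDEFGHI"), "9 residues")
})

test_that("a 9-residue mixed window matches a spreadsheet-style evaluation", {
  s <- "ACDEFGHIK"
  B <- get_scale("vihinen")$values[strsplit(s, "")[[1]]]
  expected <- (B[5] + 0.8125 * (B[4] + B[6]) + 0.625 * (B[3] + B[7]) +
                 0.4375 * (B[2] + B[8]) + 0.25 * (B[1] + B[9])) / 5.25
  expect_equal(flexibility_profile(s)$values, unname(expected), tolerance = 1e-12)
})

test_that("profile values are bounded by the scale extremes", {
  set.seed(21)
  sc <- get_scale("vihinen")
  for (i in 1:25) {
    p <- flexibility_profile(rseq(sample(9:80, 1)), sc)
    expect_true(all(p$values >= min(sc$values) - 1e-12))
    expect_true(all(p$values <= max(sc$values) + 1e-12))
  }
})

test_that("global flexibility: window mean vs per-residue mean", {
  b <- get_scale("vihinen")$values
  expect_equal(global_flexibility(strrep("C", 12), method = "window"),
               b[["C"]], tolerance = 1e-12)
  expect_equal(global_flexibility(strrep("C", 12), method = "mean"), b[["C"]])
  expect_equal(global_flexibility("AC", method = "mean"),
               (b[["A"]] + b[["C"]]) / 2)
  expect_error(global_flexibility("AC", method = "window"), "9 residues")
})

test_that("swi is the mean weight: permutation-invariant and length-weighted", {
  toy <- residue_scale("toy", setNames(c(0.6, 0.2, runif(18)), aa_alphabet()))
  expect_equal(swi("AAC", toy), (0.6 + 0.6 + 0.2) / 3)
  expect_equal(swi("AAAA", toy), 0.6)
  expect_equal(swi("ACD"), swi("DCA"))
  # concatenation identity
  set.seed(31)
  for (i in 1:20) {
    s1 <- rseq(sample(5:60, 1)); s2 <- rseq(sample(5:60, 1))
    expect_equal(swi(paste0(s1, s2)),
                 (nchar(s1) * swi(s1) + nchar(s2) * swi(s2)) / (nchar(s1) + nchar(s2)),
                 tolerance = 1e-12)
  }
  expect_error(swi(""), "empty")
})

test_that("swi matches a brute-force per-residue-sum oracle on random sequences", {
  set.seed(41)
  w <- get_scale("swi_final")$values
  for (i in 1:1000) {
    s <- rseq(sample(10:300, 1))
    oracle <- sum(w[strsplit(s, "")[[1]]]) / nchar(s)
    expect_equal(swi(s), oracle, tolerance = 1e-12)
  }
})

test_that("gravy reproduces Kyte-Doolittle reference points", {
  expect_equal(gravy("I"), 4.5)
  expect_equal(gravy("R"), -4.5)
  expect_equal(gravy("IR"), 0)
  expect_error(gravy("IZ"), "Z")
})

test_that("probability of solubility matches arbitrary-precision reference values", {
  # reference values computed once with 50-digit arithmetic for the published
  # calibration a = 81.05812, b = -62.7775
  ref <- c(`0.5` = 2.1758315857043461e-10,
           `0.7` = 0.0023834594306198707,
           `0.75` = 0.12090264639525164,
           `0.8` = 0.88785303205872529,
           `0.9` = 0.99996188284512118,
           `1.0` = 0.9999999884965634)
  x <- as.numeric(names(ref))
  expect_equal(probability_of_solubility(x), unname(ref), tolerance = 1e-14)
})

test_that("probability is monotone, 0.5 at the midpoint, and saturates stably", {
  cal <- published_calibration()
  mid <- -cal$b / cal$a
  expect_identical(probability_of_solubility(mid), 0.5)
  expect_lt(probability_of_solubility(0), 1e-20)
  expect_identical(probability_of_solubility(-1e6), 0)   # no overflow / NaN
  expect_identical(probability_of_solubility(1e6), 1)
  x <- seq(0.5, 1, length.out = 101)
  expect_true(all(diff(probability_of_solubility(x)) > 0))
})

test_that("solubility_report scores regions as extracted substrings", {
  s <- "MRGSHHHHHHTDPALRAMKVLWAALLVTFLAGCQA"
  full <- solubility_report(s, id = "x")
  expect_equal(full$length, nchar(s))
  expect_equal(full$swi, swi(s))
  expect_equal(full$gravy, gravy(s))
  sub <- solubility_report(s, start = 2, end = 4)
  expect_equal(sub$swi, swi(substring(s, 2, 4)))
  expect_true(is.na(solubility_report(s, start = 1, end = 5)$flexibility_window))
  expect_error(solubility_report(s, start = 0, end = 3), "start")
  expect_error(solubility_report(s, start = 3, end = 99), "end")
})
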