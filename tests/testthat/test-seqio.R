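test_that("read_fasta parses entries in order, uppercases, and applies policies", {
  fa <- write_fasta_fixture(list(s1 = "MKV", s2 = c("mkwl", "vva")))
  df <- read_fasta(fa)
  expect_equal(df$id, c("s1", "s2"))
  expect_equal(df$seq, c("MKV", "MKWLVVA"))

  fx <- write_fasta_fixture(list(ok = "MKV", bad = "MKXV"))
  expect_error(read_fasta(fx, policy = "error"), "nonstandard residue")
  expect_equal(read_fasta(fx, policy = "drop")$seq, c("MKV", "MKV"))
  expect_warning(kept <- read_fasta(fx, policy = "reject"), "rejecting")
  expect_equal(kept$id, "ok")
})

test_that("read_fasta rejects malformed and empty input", {
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta(empty), "empty FASTA")
  noheader <- tempfile(fileext = ".fasta")
  writeLines(c("MKV", ">late", "MKW"), noheader)
  expect_error(read_fasta(noheader), "line 1")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("write_fasta / read_fasta round-trips validated records", {
  set.seed(11)
  df <- data.frame(id = paste0("p", 1:5),
                   seq = vapply(sample(60:200, 5), rseq, character(1)),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".fasta")
  write_fasta(df, path)
  expect_equal(read_fasta(path), df)
})

test_that("translate_if_nucleotide follows the standard code and is idempotent", {
  expect_equal(translate_if_nucleotide("ATGAAAGTG"), "MKV")
  expect_equal(translate_if_nucleotide("ATGTAA"), "M")  # stop codon terminates
  expect_equal(translate_if_nucleotide("MKVLW"), "MKVLW")
  expect_equal(translate_if_nucleotide("AUGAAAGUG"), "MKV")  # RNA accepted
  expect_error(translate_if_nucleotide("ATGAAAG"), "multiple of 3")
  out <- translate_if_nucleotide("ATGAAAGTG")
  expect_equal(translate_if_nucleotide(out), out)  # idempotent on own output
})

test_that("trim_his_tag strips exact affixes only and is idempotent", {
  expect_equal(trim_his_tag("MRGSHHHHHHTDPALRAMKVGLCGR"), "MKV")
  expect_equal(trim_his_tag("MKV"), "MKV")
  expect_equal(trim_his_tag("MRGSHHHHHHTDPALRAMKV"), "MKV")   # N-terminal only
  expect_equal(trim_his_tag("MKVGLCGR"), "MKV")               # C-terminal only
  expect_error(trim_his_tag("MRGSHHHHHHTDPALRAGLCGR"), "empty")
  once <- trim_his_tag("MRGSHHHHHHTDPALRAMKVGLCGR")
  expect_identical(trim_his_tag(once), once)
  # no fuzzy matching: one substitution in the affix blocks trimming
  expect_equal(trim_his_tag("MRGSHHHHHATDPALRAMKV"), "MRGSHHHHHATDPALRAMKV")
})

test_that("label and cluster TSV readers validate their contents", {
  lab <- tempfile(fileext = ".tsv")
  writeLines(c("a\t1", "b\t0", "c\t53.2"), lab)
  df <- read_labels(lab)
  expect_equal(df$label, c(1, 0, 53.2))
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("a\t120"), bad)
  expect_error(read_labels(bad), "0, 100")
  cl <- tempfile(fileext = ".tsv")
  writeLines(c("a\tc1", "b\tc1"), cl)
  expect_equal(read_clusters(cl)$cluster, c("c1", "c1"))
})
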