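# shared fixtures and independent oracles

AA <- aa_alphabet()

# random protein sequence of length L from the current RNG stream
rseq <- function(L, alphabet = AA) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# O(n^2) pairwise brute-force AUC oracle (half credit for ties)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  sum(cmp) / (length(pos) * length(neg))
}

# exhaustive-search oracle for region optimization: best probability over all
# extensions of the seed region (start <= st, end >= en), via cumulative sums
exhaustive_best_prob <- function(seq, st, en,
                                 weights = get_scale("swi_final"),
                                 calibration = published_calibration()) {
  vals <- unname(weights$values[strsplit(seq, "", fixed = TRUE)[[1]]])
  cs <- cumsum(vals)
  L <- length(vals)
  best <- -Inf
  for (a in seq_len(st)) {
    for (b in en:L) {
      swi_ab <- (cs[b] - if (a > 1) cs[a - 1] else 0) / (b - a + 1)
      p <- probability_of_solubility(swi_ab, calibration)
      if (p > best) best <- p
    }
  }
  best
}

# write a small FASTA fixture, returning its path
write_fasta_fixture <- function(entries, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".fasta")
  writeLines(unlist(lapply(names(entries), function(id)
    c(paste0(">", id), entries[[id]]))), path)
  path
}
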