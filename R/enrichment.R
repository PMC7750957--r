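#' Residue frequencies of a sequence group
#'
#' Counts of each standard residue across all sequences, normalized by the
#' total residue count of the group. Residues absent from the input have
#' frequency 0.
#'
#' @param seqs Character vector of validated sequences (at least one residue
#'   in total), or a data.frame with a `seq` column.
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
#' @examples
#' residue_frequencies(c("AA", "CC"))[c("A", "C")]
residue_frequencies <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  stopifnot(is.character(seqs))
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  if (!length(chars)) stop("no residues in input")
  idx <- match(chars, AA20)
  if (anyNA(idx))
    stop("residue(s) outside the standard alphabet: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  setNames(tabulate(idx, nbins = 20L) / length(chars), AA20)
}

#' Per-residue enrichment bit scores of a group against a background
#'
#' For each residue `x`, `bits(x) = log2(f_group(x) / f_background(x))` where
#' the `f` are group-normalized residue counts. Positive bits mean the residue
#' is enriched in the group relative to the background. Residues with zero
#' frequency on either side are reported with `bits = NA` and `defined =
#' FALSE` rather than an infinite substitute — no pseudocount smoothing is
#' applied.
#'
#' @param group,background Character vectors of sequences (or data.frames with
#'   a `seq` column); both non-empty.
#' @param group_name,background_name Labels carried into the result.
#' @return Object of class `enrichment_table`: data.frame with columns
#'   `residue`, `group_freq`, `background_freq`, `bits`, `defined`, plus
#'   attributes `group_name` and `background_name`.
#' @export
#' @examples
#' bit_scores("AAC", "ACAC")["A", "bits"]  # log2((2/3) / (1/2))
bit_scores <- function(group, background,
                       group_name = "group", background_name = "background") {
  fg <- residue_frequencies(group)
  fb <- residue_frequencies(background)
  defined <- fg > 0 & fb > 0
  bits <- ifelse(defined, log2(fg / fb), NA_real_)
  out <- data.frame(residue = AA20, group_freq = unname(fg),
                    background_freq = unname(fb), bits = unname(bits),
                    defined = unname(defined),
                    row.names = AA20, stringsAsFactors = FALSE)
  attr(out, "group_name") <- group_name
  attr(out, "background_name") <- background_name
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Generate the random-sequence control set
#'
#' Random protein sequences at a grid of lengths, i.i.d. residues from a given
#' composition. At the defaults (lengths 50, 100, ..., 6000; 100 sequences per
#' length) this yields 12 000 unique random sequences, the control set used to
#' contrast SWI scores of biological versus random sequences. Duplicates (all
#' but impossible at these lengths) are resampled so the set is unique.
#'
#' @param min_len,max_len,step Length grid (inclusive).
#' @param n_per_len Sequences per length.
#' @param composition Named numeric vector of residue probabilities summing to
#'   1 (default uniform over the 20 standard residues).
#' @param seed Integer seed.
#' @return data.frame with columns `id`, `seq` and `length`.
#' @export
#' @examples
#' nrow(random_sequences(50, 200, 50, 2, seed = 7))  # 8
random_sequences <- function(min_len = 50L, max_len = 6000L, step = 50L,
                             n_per_len = 100L, composition = NULL, seed = 1L) {
  if (is.null(composition))
    composition <- setNames(rep(1 / 20, 20L), AA20)
  if (is.list(composition)) composition <- unlist(composition)
  if (!setequal(names(composition), AA20) || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9)
    stop("composition must be a probability vector over the 20 standard residues")
  composition <- composition[AA20]
  lens <- seq.int(min_len, max_len, by = step)
  withr::with_seed(seed, {
    seqs <- unlist(lapply(lens, function(L) {
      m <- matrix(sample(AA20, L * n_per_len, replace = TRUE, prob = composition),
                  nrow = n_per_len)
      apply(m, 1L, paste, collapse = "")
    }), use.names = FALSE)
    # uniqueness guard: resample any duplicate until the set is unique
    while (anyDuplicated(seqs)) {
      d <- which(duplicated(seqs))
      for (i in d) {
        L <- nchar(seqs[i])
        seqs[i] <- paste(sample(AA20, L, replace = TRUE, prob = composition),
                         collapse = "")
      }
    }
    data.frame(id = sprintf("rand_%d_%d", rep(lens, each = n_per_len),
                            rep(seq_len(n_per_len), length(lens))),
               seq = seqs, length = rep(lens, each = n_per_len),
               stringsAsFactors = FALSE)
  })
}
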