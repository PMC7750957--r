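#' Read protein sequences from a FASTA file
#'
#' Entries are uppercased and validated against the 20 standard amino-acid
#' codes. Characters outside the standard alphabet (B, J, O, U, X, Z, gaps,
#' ...) are handled according to `policy`:
#'
#' * `"error"` (default): abort, naming the record and the offending
#'   characters. SWI weights exist only for the 20 standard residues, so
#'   silent substitution would bias scores.
#' * `"drop"`: remove the offending characters, keeping the rest of the
#'   record. Intended for bulk training ingestion.
#' * `"reject"`: discard the whole record, with a warning.
#'
#' @param path Path to a FASTA file (multi-record; wrapped or unwrapped lines).
#' @param policy Nonstandard-residue policy, one of `"error"`, `"drop"`,
#'   `"reject"`.
#' @return A data.frame with columns `id` (word before the first whitespace of
#'   the header) and `seq`, one row per retained FASTA entry, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "MKV", ">s2", "MKWL"), fa)
#' read_fasta(fa)
read_fasta <- function(path, policy = c("error", "drop", "reject")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty FASTA file: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA ", path, ": line ", first, " is not a header ('",
         strtrim(lines[first], 30), "')")
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(chars), AA20)
    if (length(bad)) {
      if (policy == "error") {
        stop("record '", ids[i], "' contains nonstandard residue(s): ",
             paste(bad, collapse = ", "),
             " (use policy = 'drop' or 'reject' to handle them)")
      } else if (policy == "drop") {
        seqs[i] <- paste(chars[chars %in% AA20], collapse = "")
      } else {
        warning("rejecting record '", ids[i], "' (nonstandard residue(s): ",
                paste(bad, collapse = ", "), ")")
        keep[i] <- FALSE
      }
    }
  }
  out <- data.frame(id = unname(ids[keep]), seq = unname(seqs[keep]),
                    row.names = NULL, stringsAsFactors = FALSE)
  empty <- !nzchar(out$seq)
  if (any(empty))
    stop("record(s) empty after validation: ", paste(out$id[empty], collapse = ", "))
  out
}

#' Write sequences to a FASTA file
#'
#' @param x A data.frame with columns `id` and `seq` (as returned by
#'   [read_fasta()]), or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.data.frame(x)) {
    seqs <- setNames(x$seq, x$id)
  } else {
    seqs <- x
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Translate a sequence if it looks like a nucleotide sequence
#'
#' A sequence is treated as nucleotide when it consists only of A, C, G, T, U
#' and its length is a multiple of 3; it is then translated with the standard
#' genetic code, stopping at the first stop codon. Anything else is returned
#' unchanged, except the ambiguous case (nucleotide alphabet, length not a
#' multiple of 3), which errors and asks for an explicit type flag.
#'
#' @param seq Single character string.
#' @return The translated (or unchanged) sequence.
#' @export
#' @examples
#' translate_if_nucleotide("ATGAAAGTG")  # "MKV"
#' translate_if_nucleotide("MKVLW")      # unchanged
translate_if_nucleotide <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (!nzchar(s)) stop("empty sequence")
  if (!grepl("^[ACGTU]+$", s)) return(seq)
  if (nchar(s) %% 3L != 0L)
    stop("sequence uses only the nucleotide alphabet but its length (",
         nchar(s), ") is not a multiple of 3; ",
         "declare the sequence type explicitly (nucleotide or protein)")
  s <- chartr("U", "T", s)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
  aa <- sub("\\*.*$", "", aa)  # stop at first stop codon
  if (!nzchar(aa)) stop("translation is empty (sequence starts with a stop codon)")
  aa
}

#' Trim expression-vector His-tag affixes
#'
#' Removes the exact N-terminal affix `MRGSHHHHHHTDPALRA` and/or the exact
#' C-terminal affix `GLCGR` when present (the polyhistidine fusion affixes of
#' the pET NESG expression vectors). Matching is exact prefix/suffix only.
#' Trimming is idempotent.
#'
#' @param seq Single character string of validated residues.
#' @param nterm N-terminal affix to strip when the sequence starts with it.
#' @param cterm C-terminal affix to strip when the sequence ends with it.
#' @return The trimmed sequence.
#' @export
#' @examples
#' trim_his_tag("MRGSHHHHHHTDPALRAMKVGLCGR")  # "MKV"
trim_his_tag <- function(seq, nterm = "MRGSHHHHHHTDPALRA", cterm = "GLCGR") {
  stopifnot(is.character(seq), length(seq) == 1L)
  out <- seq
  if (nzchar(nterm) && startsWith(out, nterm))
    out <- substring(out, nchar(nterm) + 1L)
  if (nzchar(cterm) && nchar(out) >= nchar(cterm) && endsWith(out, cterm))
    out <- substring(out, 1L, nchar(out) - nchar(cterm))
  if (!nzchar(out))
    stop("trimming His-tag affixes would leave an empty sequence")
  out
}

#' Read a solubility-label TSV
#'
#' Two tab-separated columns without header: sequence id and label. Labels are
#' either binary (0 = insoluble, 1 = soluble) or continuous solubility
#' percentages in \[0, 100\].
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `id` (character) and `label` (numeric).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- read.delim(path, header = FALSE, col.names = c("id", "label"),
                   colClasses = c("character", "numeric"),
                   comment.char = "#")
  if (any(!is.finite(df$label)) || any(df$label < 0 | df$label > 100))
    stop("labels must be 0/1 or percentages in [0, 100]")
  df
}

#' Read a cluster-assignment TSV
#'
#' Two tab-separated columns without header: sequence id and cluster id.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `id` and `cluster` (both character).
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop("cluster file not found: ", path)
  read.delim(path, header = FALSE, col.names = c("id", "cluster"),
             colClasses = c("character", "character"), comment.char = "#")
}
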