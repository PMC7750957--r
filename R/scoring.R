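# map a validated sequence to per-residue scale values; errors name the residue
.aa_values <- function(seq, scale) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(chars, names(scale$values))
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("residue(s) not in scale '", scale$name, "': ", paste(bad, collapse = ", "))
  }
  unname(scale$values[idx])
}

# Eq. 1 window coefficients; they sum to the divisor 5.25, so each profile
# value is a convex combination of B values
.FLEX_COEF <- c(0.25, 0.4375, 0.625, 0.8125, 1, 0.8125, 0.625, 0.4375, 0.25)
.FLEX_DIV <- 5.25

#' Local flexibility profile of a protein sequence
#'
#' For every residue with four neighbors on each side (positions 5 ... L-4,
#' 1-based), the local flexibility is the weighted average of the normalized
#' B-factors over a 9-residue window with coefficients
#' 1, 0.8125, 0.625, 0.4375, 0.25 (center outwards), divided by 5.25 (the
#' coefficient sum). No mirrored or truncated edge windows are used.
#'
#' @param seq Single character string of validated residues (length >= 9).
#' @param scale Normalized B-factor [residue_scale()]; default Vihinen et al.
#' @param id Optional sequence identifier carried into the result.
#' @return An object of class `flexibility_profile`: list with `sequence_id`,
#'   `start_position` (always 5, 1-based index of the first scored residue)
#'   and `values` (numeric, length `nchar(seq) - 8`).
#' @export
#' @examples
#' p <- flexibility_profile("MKVLWAALLV")
#' length(p$values)  # 2
flexibility_profile <- function(seq, scale = get_scale("vihinen"), id = "") {
  b <- .aa_values(seq, scale)
  n <- length(b)
  if (n < 9L)
    stop("flexibility profile needs at least 9 residues (a full window); got ", n)
  f <- stats::filter(b, .FLEX_COEF / .FLEX_DIV, method = "convolution", sides = 2L)
  structure(list(sequence_id = id, start_position = 5L,
                 values = as.numeric(f[5:(n - 4L)])),
            class = "flexibility_profile")
}

#' @export
print.flexibility_profile <- function(x, ...) {
  cat("<flexibility_profile>", x$sequence_id, "\n")
  cat("  start_position:", x$start_position, " n:", length(x$values), "\n")
  print(head(round(x$values, 4), 10))
  invisible(x)
}

#' Global structural flexibility of a sequence
#'
#' `method = "window"` is the arithmetic mean of the local flexibility profile
#' (sliding-window average of normalized B-factors). `method = "mean"` is the
#' simplified form: the arithmetic mean of the per-residue normalized
#' B-factors themselves, i.e. plain sequence-composition scoring. The two are
#' nearly rank-identical on real and random sequences, which is what motivates
#' composition-based scoring.
#'
#' @inheritParams flexibility_profile
#' @param method `"window"` (needs >= 9 residues) or `"mean"` (needs >= 1).
#' @return Single numeric value.
#' @export
#' @examples
#' global_flexibility("MKVLWAALLV", method = "window")
#' global_flexibility("MKVLWAALLV", method = "mean")
global_flexibility <- function(seq, scale = get_scale("vihinen"),
                               method = c("window", "mean")) {
  method <- match.arg(method)
  if (method == "window") {
    mean(flexibility_profile(seq, scale)$values)
  } else {
    mean(.aa_values(seq, scale))
  }
}

#' Solubility-Weighted Index (SWI)
#'
#' The arithmetic mean of the per-residue weights over the sequence. SWI is
#' composition-based: permutation-invariant and, in expectation, independent
#' of length. With the default final weights it lies in
#' \[min(W), max(W)\] = \[0.521, 0.988\].
#'
#' @param seq Single character string of validated residues (length >= 1).
#' @param weights A [residue_scale()] of per-residue weights; default the
#'   final optimized SWI weights.
#' @return Single numeric value.
#' @export
#' @examples
#' swi("MKVLW")
#' swi("MKVLW") == swi("WLVKM")  # permutation invariant
swi <- function(seq, weights = get_scale("swi_final")) {
  mean(.aa_values(seq, weights))
}

#' Grand Average of Hydropathy (GRAVY)
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy index over the sequence.
#'
#' @param seq Single character string of validated residues (length >= 1).
#' @return Single numeric value.
#' @export
#' @examples
#' gravy("IR")  # 0
gravy <- function(seq) {
  mean(.aa_values(seq, get_scale("kyte_doolittle")))
}

#' Logistic calibration mapping SWI to a probability of solubility
#'
#' `logistic_calibration()` builds a calibration object; the published
#' calibration (`a = 81.05812`, `b = -62.7775`, fitted on 12 216 proteins
#' expressed in *E. coli*) is the default used throughout the package.
#' Trained weight scales are only identified up to an affine transform, so a
#' recalibrated logistic must always travel with its weight set.
#'
#' @param a Slope (finite).
#' @param b Intercept (finite).
#' @param converged Logical convergence flag (set by [fit_logistic()]).
#' @return Object of class `logistic_calibration`.
#' @export
#' @examples
#' published_calibration()
logistic_calibration <- function(a, b, converged = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L,
            is.finite(a), is.finite(b))
  structure(list(a = a, b = b, converged = isTRUE(converged)),
            class = "logistic_calibration")
}

#' @rdname logistic_calibration
#' @export
published_calibration <- function() logistic_calibration(a = 81.05812, b = -62.7775)

#' @export
print.logistic_calibration <- function(x, ...) {
  cat("<logistic_calibration> a =", x$a, " b =", x$b,
      if (!x$converged) " (not converged)" else "", "\n")
  invisible(x)
}

#' Probability of solubility from an SWI value
#'
#' Evaluates `1 / (1 + exp(-(a * x + b)))`. The evaluation is numerically
#' stable for large `|a * x + b|` (saturates to 0 or 1, never overflows).
#' Strictly increasing in `x` for `a > 0`, with value exactly 0.5 at
#' `x = -b / a`.
#'
#' @param x SWI value(s); vectorized.
#' @param calibration A [logistic_calibration()]; default the published one.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
#' @examples
#' probability_of_solubility(0.8)
probability_of_solubility <- function(x, calibration = published_calibration()) {
  stopifnot(inherits(calibration, "logistic_calibration"))
  z <- calibration$a * x + calibration$b
  # stable two-branch logistic: exp() is only ever taken of a non-positive value
  p <- numeric(length(z))
  pos <- !is.na(z) & z >= 0
  p[pos] <- 1 / (1 + exp(-z[pos]))
  p[!pos] <- exp(z[!pos]) / (1 + exp(z[!pos]))
  p[is.na(z)] <- NA_real_
  p
}

#' Full solubility report for a sequence or region
#'
#' Scores the substring `[start, end]` (1-based inclusive): SWI, probability
#' of solubility, windowed and simplified global flexibility, and GRAVY.
#' Windowed flexibility uses only windows fully inside the region and is `NA`
#' for regions shorter than 9 residues.
#'
#' @param seq Single character string of validated residues.
#' @param id Sequence identifier carried into the report.
#' @param start,end 1-based inclusive region bounds; default full length.
#' @param weights Residue weights for SWI (default final SWI weights).
#' @param calibration [logistic_calibration()] for the probability.
#' @param flex_scale Normalized B-factor scale for flexibility (default
#'   Vihinen et al.).
#' @return One-row data.frame with columns `id`, `start`, `end`, `length`,
#'   `swi`, `probability`, `flexibility_window`, `flexibility_mean`, `gravy`.
#' @export
#' @examples
#' solubility_report("MRGSHHHHHHTDPALRAMKVLWAALLVTFLAGCQA", id = "demo")
solubility_report <- function(seq, id = "", start = 1L, end = nchar(seq),
                              weights = get_scale("swi_final"),
                              calibration = published_calibration(),
                              flex_scale = get_scale("vihinen")) {
  n <- nchar(seq)
  if (!(is.numeric(start) && length(start) == 1L && start >= 1L && start <= n))
    stop("invalid region start ", start, " (sequence length ", n, ")")
  if (!(is.numeric(end) && length(end) == 1L && end >= start && end <= n))
    stop("invalid region end ", end, " (start ", start, ", sequence length ", n, ")")
  sub <- substring(seq, start, end)
  len <- nchar(sub)
  s <- swi(sub, weights)
  data.frame(
    id = id, start = as.integer(start), end = as.integer(end), length = len,
    swi = s,
    probability = probability_of_solubility(s, calibration),
    flexibility_window = if (len >= 9L) global_flexibility(sub, flex_scale, "window") else NA_real_,
    flexibility_mean = global_flexibility(sub, flex_scale, "mean"),
    gravy = gravy(sub),
    stringsAsFactors = FALSE
  )
}

#' Score every sequence of a FASTA data.frame
#'
#' Convenience wrapper applying [solubility_report()] to each row of a
#' sequence data.frame (full-length regions).
#'
#' @param seqs data.frame with columns `id` and `seq` (see [read_fasta()]).
#' @inheritParams solubility_report
#' @return data.frame with one report row per sequence.
#' @export
score_sequences <- function(seqs, weights = get_scale("swi_final"),
                            calibration = published_calibration()) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  do.call(rbind, lapply(seq_len(nrow(seqs)), function(i) {
    solubility_report(seqs$seq[i], id = seqs$id[i],
                      weights = weights, calibration = calibration)
  }))
}
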