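#' Score a sub-sequence region
#'
#' Scores the region `[start, end]` (1-based inclusive) of a sequence exactly
#' as if the extracted substring were scored on its own; flexibility uses only
#' windows fully inside the region.
#'
#' @inheritParams solubility_report
#' @return One-row data.frame (see [solubility_report()]).
#' @export
#' @examples
#' score_region("MKVLW", 2, 4)  # scores "KVL"
score_region <- function(seq, start, end, id = "",
                         weights = get_scale("swi_final"),
                         calibration = published_calibration()) {
  solubility_report(seq, id = id, start = start, end = end,
                    weights = weights, calibration = calibration)
}

#' Simulated-annealing configuration for region optimization
#'
#' The cooling schedule is geometric (`T <- cooling * T`) with a fixed number
#' of proposals per temperature. Boundary moves displace the region start
#' and/or end by up to `max_disp` residues. The initial temperature is matched
#' to the scale of probability differences between neighboring regions: the
#' published calibration is steep (a single boundary residue can move the
#' probability by a few tenths), so the walk starts warm enough to accept
#' such moves and only turns greedy as the temperature drops.
#'
#' @param t_init Initial temperature (> 0).
#' @param cooling Geometric cooling factor in (0, 1).
#' @param steps_per_temp Proposals evaluated at each temperature.
#' @param t_min Stopping temperature (> 0).
#' @param max_disp Maximum boundary displacement per move (residues).
#' @param seed Integer seed.
#' @param allow_shrink If `TRUE`, moves may also explore regions smaller than
#'   the seed. Default `FALSE`: every candidate contains the seed region
#'   (extensions only).
#' @return List of class `anneal_config`.
#' @export
anneal_config <- function(t_init = 0.25, cooling = 0.95, steps_per_temp = 50L,
                          t_min = 1e-4, max_disp = 3L, seed = 1L,
                          allow_shrink = FALSE) {
  stopifnot(t_init > 0, cooling > 0, cooling < 1, t_min > 0, t_min < t_init,
            steps_per_temp >= 1, max_disp >= 1)
  structure(list(t_init = t_init, cooling = cooling,
                 steps_per_temp = as.integer(steps_per_temp), t_min = t_min,
                 max_disp = as.integer(max_disp), seed = as.integer(seed),
                 allow_shrink = isTRUE(allow_shrink)),
            class = "anneal_config")
}

#' Maximize the probability of solubility of a region by simulated annealing
#'
#' Starting from a seed region, boundary moves displace the start and/or the
#' end by up to `config$max_disp` residues. The candidate region is always an
#' extension of the seed: the start stays at or before the seed start and the
#' end at or after the seed end (boundaries may step back toward the seed, but
#' never inside it, keeping the walk over extended regions reversible); with
#' `allow_shrink = TRUE` regions smaller than the seed are also explored.
#' Moves that do not decrease the probability of solubility are always
#' accepted; worse moves are accepted with probability `exp(dp / T)` under a
#' geometric cooling schedule. Every evaluated candidate is tracked, and the
#' best-ever region (ties broken toward shorter regions) is returned first,
#' followed by the remaining distinct accepted regions in descending
#' probability. The best returned probability is never below the seed
#' region's.
#'
#' @param seq Single character string of validated residues.
#' @param start,end Seed region, 1-based inclusive.
#' @param config An [anneal_config()].
#' @param id Sequence identifier carried into the reports.
#' @inheritParams solubility_report
#' @return data.frame of [solubility_report()] rows: best region first.
#' @export
#' @examples
#' fa <- "MKKKEDDEDKKAAAWWFYWWLLVVAAKEDE"
#' best <- anneal_region(fa, 10, 14, anneal_config(seed = 3))[1, ]
#' best$probability >= score_region(fa, 10, 14)$probability
anneal_region <- function(seq, start, end, config = anneal_config(), id = "",
                          weights = get_scale("swi_final"),
                          calibration = published_calibration()) {
  L <- nchar(seq)
  if (!(start >= 1 && end >= start && end <= L))
    stop("invalid seed region [", start, ", ", end, "] for sequence of length ", L)
  w <- .aa_values(seq, weights)
  cs <- cumsum(w)
  p_of <- function(s, e) {
    total <- cs[e] - if (s > 1L) cs[s - 1L] else 0
    probability_of_solubility(total / (e - s + 1L), calibration)
  }
  md <- config$max_disp

  withr::with_seed(config$seed, {
    cur_s <- as.integer(start); cur_e <- as.integer(end)
    cur_p <- p_of(cur_s, cur_e)
    best_s <- cur_s; best_e <- cur_e; best_p <- cur_p
    acc <- new.env(parent = emptyenv())
    assign(paste(cur_s, cur_e), cur_p, envir = acc)
    temp <- config$t_init
    while (temp >= config$t_min) {
      for (step in seq_len(config$steps_per_temp)) {
        ds <- sample.int(2L * md + 1L, 1L) - md - 1L  # uniform on [-md, md]
        de <- sample.int(2L * md + 1L, 1L) - md - 1L
        # positive ds/de push the boundaries outward; the candidate must stay
        # an extension of the seed unless shrink moves are enabled
        new_s <- max(1L, cur_s - ds)
        new_e <- min(L, cur_e + de)
        if (!config$allow_shrink) {
          new_s <- min(new_s, as.integer(start))
          new_e <- max(new_e, as.integer(end))
        } else {
          if (new_s > new_e) next
        }
        if (new_s == cur_s && new_e == cur_e) next
        cand_p <- p_of(new_s, new_e)
        if (cand_p > best_p ||
            (cand_p == best_p && (new_e - new_s) < (best_e - best_s))) {
          best_s <- new_s; best_e <- new_e; best_p <- cand_p
        }
        dp <- cand_p - cur_p
        if (dp >= 0 || runif(1L) < exp(dp / temp)) {
          cur_s <- new_s; cur_e <- new_e; cur_p <- cand_p
          assign(paste(cur_s, cur_e), cur_p, envir = acc)
        }
      }
      temp <- temp * config$cooling
    }
    keys <- ls(acc)
    regs <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
    df <- data.frame(s = as.integer(regs[, 1L]), e = as.integer(regs[, 2L]),
                     p = vapply(keys, get, numeric(1L), envir = acc))
    best_key <- paste(best_s, best_e)
    df <- df[order(-df$p, df$e - df$s), , drop = FALSE]
    df <- rbind(df[paste(df$s, df$e) == best_key, , drop = FALSE][1, ],
                df[paste(df$s, df$e) != best_key, , drop = FALSE])
    do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      score_region(seq, df$s[i], df$e[i], id = id,
                   weights = weights, calibration = calibration)
    }))
  })
}

#' Predict the solubility of a tag-target fusion
#'
#' Scores the concatenated construct (tag + target for an N-terminal tag,
#' target + tag for a C-terminal one). Because SWI is composition-based, the
#' fusion SWI is exactly the length-weighted mean of the component SWI values,
#' and the two termini give identical SWI and probability (the flexibility
#' profile may differ).
#'
#' @param tag Tag sequence (non-empty).
#' @param target Target sequence.
#' @param terminus `"N"` or `"C"`.
#' @param id Identifier carried into the report.
#' @inheritParams solubility_report
#' @return One-row data.frame (see [solubility_report()]).
#' @export
#' @examples
#' score_with_tag("MKKDDKK", "WWFYWWLL", terminus = "N")$swi
score_with_tag <- function(tag, target, terminus = c("N", "C"), id = "",
                           weights = get_scale("swi_final"),
                           calibration = published_calibration()) {
  terminus <- match.arg(terminus)
  stopifnot(is.character(tag), length(tag) == 1L)
  if (!nzchar(tag)) stop("empty tag sequence")
  if (!nzchar(target)) stop("empty target sequence")
  fused <- if (terminus == "N") paste0(tag, target) else paste0(target, tag)
  solubility_report(fused, id = id, weights = weights, calibration = calibration)
}
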