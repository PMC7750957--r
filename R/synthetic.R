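#' Specification of a synthetic labeled protein dataset
#'
#' Defines the generative model used to validate the training pipeline without
#' external data: sequence families descend from i.i.d. random ancestors by
#' point substitutions (emulating homology clusters), and solubility labels
#' are driven by a planted per-residue weight vector through a logistic link
#' (or a hard threshold) on the planted SWI. Labels are assigned per sequence,
#' not per family, so families can be label-mixed — as a minority of real
#' similarity clusters are.
#'
#' Default link slope: SWI values of length ~200 random sequences have a
#' standard deviation of roughly 0.008 under the default planted weights, so a
#' slope of 800 puts about six logistic standard deviations between typical
#' low- and high-SWI sequences — a strong but noisy link. The intercept
#' defaults to centering the link at the mean planted weight (base rate ~0.5).
#'
#' @param n_families Number of sequence families (similarity clusters).
#' @param family_size Sequences per family.
#' @param len_range Integer vector `c(min, max)` ancestor length range
#'   (>= 9 so every sequence is scorable by the flexibility window).
#' @param mutation_rate Per-residue substitution probability within a family,
#'   in \[0, 1).
#' @param planted_weights [residue_scale()] that drives the labels (default
#'   Smith et al. normalized B-factors).
#' @param link `"logistic"` (label ~ Bernoulli(plogis(slope * SWI +
#'   intercept))) or `"threshold"` (label = SWI >= -intercept / slope, with
#'   sequences closer than `threshold_margin` to the boundary resampled, so
#'   labels are perfectly separable by planted SWI).
#' @param link_slope Logistic slope on planted SWI.
#' @param link_intercept Logistic intercept; default `-link_slope *
#'   mean(planted weights)`.
#' @param threshold_margin Half-width of the exclusion band around the
#'   threshold (only for `link = "threshold"`).
#' @param composition Ancestor residue composition (default uniform).
#' @param seed Integer seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_families = 20L, family_size = 20L,
                           len_range = c(100L, 300L), mutation_rate = 0.1,
                           planted_weights = get_scale("smith"),
                           link = c("logistic", "threshold"),
                           link_slope = 800, link_intercept = NULL,
                           threshold_margin = 0.002,
                           composition = NULL, seed = 1L) {
  link <- match.arg(link)
  stopifnot(n_families >= 1, family_size >= 1,
            length(len_range) == 2L, len_range[1] >= 9L,
            len_range[2] >= len_range[1],
            mutation_rate >= 0, mutation_rate < 1,
            inherits(planted_weights, "residue_scale"))
  if (is.null(link_intercept))
    link_intercept <- -link_slope * mean(planted_weights$values)
  if (is.null(composition))
    composition <- setNames(rep(1 / 20, 20L), AA20)
  composition <- composition[AA20]
  if (any(is.na(composition)) || abs(sum(composition) - 1) > 1e-9)
    stop("composition must be a probability vector over the 20 standard residues")
  structure(list(n_families = as.integer(n_families),
                 family_size = as.integer(family_size),
                 len_range = as.integer(len_range),
                 mutation_rate = mutation_rate,
                 planted_weights = planted_weights,
                 link = link, link_slope = link_slope,
                 link_intercept = link_intercept,
                 threshold_margin = threshold_margin,
                 composition = composition, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic labeled, clustered dataset
#'
#' Draws each family's ancestor i.i.d. from the spec composition, derives
#' family members by point substitutions at the mutation rate (substitutions
#' draw from the 19 other residues), labels every sequence through the spec's
#' link on its planted-weight SWI, and sets `cluster` to the family id. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [labeled_dataset()] data.frame with columns `id`, `seq`, `label`,
#'   `cluster`, `planted_swi` and `p_soluble` (the link probability — a
#'   continuous solubility target).
#' @export
#' @examples
#' d <- generate_dataset(synthetic_spec(n_families = 4, family_size = 5, seed = 2))
#' table(d$label, d$cluster)
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  w <- spec$planted_weights
  thr <- -spec$link_intercept / spec$link_slope
  withr::with_seed(spec$seed, {
    rows <- vector("list", spec$n_families * spec$family_size)
    r <- 0L
    for (f in seq_len(spec$n_families)) {
      L <- sample(seq.int(spec$len_range[1], spec$len_range[2]), 1L)
      anc <- sample(AA20, L, replace = TRUE, prob = spec$composition)
      for (m in seq_len(spec$family_size)) {
        member <- anc
        if (spec$mutation_rate > 0) {
          hit <- which(runif(L) < spec$mutation_rate)
          if (length(hit)) {
            member[hit] <- vapply(member[hit], function(a)
              sample(setdiff(AA20, a), 1L), character(1L))
          }
        }
        if (spec$link == "threshold" && spec$threshold_margin > 0) {
          # resample members that land inside the exclusion band so labels
          # are perfectly separable by planted SWI
          tries <- 0L
          while (abs(mean(w$values[member]) - thr) < spec$threshold_margin &&
                 tries < 100L) {
            member <- anc
            hit <- which(runif(L) < max(spec$mutation_rate, 0.05))
            if (length(hit)) {
              member[hit] <- vapply(member[hit], function(a)
                sample(setdiff(AA20, a), 1L), character(1L))
            }
            tries <- tries + 1L
          }
        }
        s <- mean(unname(w$values[member]))
        p <- plogis(spec$link_slope * s + spec$link_intercept)
        label <- if (spec$link == "logistic") {
          as.integer(runif(1L) < p)
        } else {
          as.integer(s >= thr)
        }
        r <- r + 1L
        rows[[r]] <- data.frame(
          id = sprintf("fam%03d_m%03d", f, m),
          seq = paste(member, collapse = ""),
          label = label, cluster = sprintf("fam%03d", f),
          planted_swi = s, p_soluble = p, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    if (length(unique(out$label)) < 2L)
      warning("generated dataset contains a single class; ",
              "it cannot be used for training as-is")
    labeled_dataset(out, require_both_classes = FALSE)
  })
}

#' Multiplicatively perturb a residue scale
#'
#' Each value is multiplied by `1 + e` with `e` uniform on
#' `[-relative_noise, relative_noise]`. Used to produce imperfect initial
#' weights for parameter-recovery experiments.
#'
#' @param scale A [residue_scale()].
#' @param relative_noise Non-negative relative noise bound.
#' @param seed Integer seed.
#' @return A perturbed [residue_scale()].
#' @export
perturb_weights <- function(scale, relative_noise, seed = 1L) {
  stopifnot(inherits(scale, "residue_scale"), relative_noise >= 0)
  eps <- withr::with_seed(seed, runif(20L, -relative_noise, relative_noise))
  residue_scale(paste0(scale$name, "_perturbed"), scale$values * (1 + eps),
                provenance = sprintf("'%s' with +/-%.0f%% uniform multiplicative noise",
                                     scale$name, 100 * relative_noise))
}
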