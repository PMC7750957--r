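test_that("auc matches the examples and the pairwise brute-force oracle", {
  expect_equal(auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)  # all-tie convention
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(51)
  for (i in 1:50) {
    n <- sample(4:120, 1)
    scores <- sample(round(runif(n), 2))  # rounding forces ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc(scores, labels), brute_auc(scores, labels))
  }
  expect_error(auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("auc is invariant under shifting and positive scaling of weights", {
  set.seed(61)
  seqs <- vapply(rep(50, 60), rseq, character(1))
  labels <- sample(0:1, 60, replace = TRUE, prob = c(0.4, 0.6))
  w <- setNames(runif(20), aa_alphabet())
  base <- auc(vapply(seqs, function(s) mean(w[strsplit(s, "")[[1]]]), 1), labels)
  for (shift in c(-3, 7)) {
    ws <- w + shift
    expect_equal(auc(vapply(seqs, function(s) mean(ws[strsplit(s, "")[[1]]]), 1),
                     labels), base)
  }
  ws <- w * 42
  expect_equal(auc(vapply(seqs, function(s) mean(ws[strsplit(s, "")[[1]]]), 1),
                   labels), base)
})

test_that("build_folds packs whole clusters into balanced folds", {
  sizes <- c(5, 5, 4, 4, 3, 3, 2, 2, 1, 1)
  clusters <- rep(paste0("c", seq_along(sizes)), times = sizes)
  fa <- build_folds(clusters, 2, seed = 9)
  expect_equal(unname(table(fa$fold_of_record)), c(15L, 15L), ignore_attr = TRUE)
  # no cluster spans folds
  expect_true(all(tapply(fa$fold_of_record, clusters,
                         function(x) length(unique(x))) == 1))
  # one cluster per fold when n_folds equals the cluster count
  fa2 <- build_folds(clusters, 10, seed = 1)
  expect_equal(sort(unname(fa2$fold_of_cluster)), 1:10)
  expect_error(build_folds(rep("c1", 5), 2), "at least 2 clusters")
  # deterministic given seed
  expect_identical(build_folds(clusters, 3, seed = 4),
                   build_folds(clusters, 3, seed = 4))
})

test_that("bootstrap_resample draws class-balanced samples reproducibly", {
  d <- data.frame(id = 1:30, label = rep(c(0, 1), c(10, 20)))
  s1 <- bootstrap_resample(d, 15, seed = 3)
  expect_equal(nrow(s1), 30)
  expect_equal(sum(s1$label == 1), 15)
  expect_equal(sum(s1$label == 0), 15)
  expect_identical(s1, bootstrap_resample(d, 15, seed = 3))
  expect_error(bootstrap_resample(d[d$label == 1, ], 5), "both classes")
})

test_that("optimize_weights improves AUC and attains 1.0 on separable samples", {
  set.seed(71)
  planted <- residue_scale("planted", setNames(runif(20, 0.3, 1), aa_alphabet()))
  seqs <- vapply(rep(80, 120), rseq, character(1))
  s <- vapply(seqs, function(x) mean(planted$values[strsplit(x, "")[[1]]]), 1)
  labels <- as.integer(s >= median(s))  # separable by planted SWI with a gap
  sample_df <- data.frame(seq = seqs, label = labels)
  w <- optimize_weights(sample_df, initial = planted)
  expect_equal(attr(w, "auc"), 1)  # initial weights already separate perfectly
  init <- perturb_weights(planted, 0.4, seed = 5)
  scores0 <- vapply(seqs, function(x) mean(init$values[strsplit(x, "")[[1]]]), 1)
  w2 <- optimize_weights(sample_df, initial = init)
  expect_gte(attr(w2, "auc"), auc(scores0, labels))
  expect_gte(attr(w2, "auc"), 0.999)
  expect_error(optimize_weights(data.frame(seq = seqs, label = 1)), "both classes")
})

test_that("train_swi returns the documented structure deterministically", {
  d <- generate_dataset(synthetic_spec(n_families = 8, family_size = 10,
                                       len_range = c(60, 120), seed = 33))
  cfg <- training_config(n_folds = 2, n_bootstrap = 3, n_per_class = 25, seed = 7)
  tw <- train_swi(d, config = cfg)
  expect_equal(dim(tw$fold_means), c(20L, 2L))
  expect_length(tw$test_auc, 2L)
  expect_equal(tw$final$values,
               setNames(rowMeans(tw$fold_means), aa_alphabet()))
  tw2 <- train_swi(d, config = cfg)
  expect_identical(tw$fold_means, tw2$fold_means)
  expect_identical(tw$test_auc, tw2$test_auc)
})

test_that("fit_logistic recovers simulated calibrations and flags pathologies", {
  set.seed(81)
  a <- 8; b <- -4
  x <- runif(10000)
  y <- as.integer(runif(10000) < plogis(a * x + b))
  cal <- fit_logistic(x, y)
  expect_true(cal$converged)
  expect_lt(abs(cal$a - a) / a, 0.1)
  expect_lt(abs(cal$b - b) / abs(b), 0.1)
  # null case: slope indistinguishable from zero
  y0 <- sample(0:1, 2000, replace = TRUE)
  x0 <- runif(2000)
  cal0 <- fit_logistic(x0, y0)
  se <- summary(glm(y0 ~ x0, family = binomial()))$coefficients["x0", "Std. Error"]
  expect_lt(abs(cal0$a), 3 * se)
  # complete separation
  xs <- c(1:10, 21:30); ys <- rep(c(0, 1), each = 10)
  cs <- fit_logistic(xs, ys)
  expect_false(cs$converged)
  expect_error(fit_logistic(1:5, rep(1, 5)), "both classes")
})

test_that("greedy_cluster groups mutated families and separates unrelated sequences", {
  expect_equal(greedy_cluster(c(a = "MKVLWAAL", b = "MKVLWAAL"))$cluster,
               rep("a", 2))
  expect_length(unique(greedy_cluster(c(a = strrep("AC", 10),
                                        b = strrep("KE", 10)))$cluster), 2L)
  set.seed(91)
  anc <- strsplit(rseq(120), "")[[1]]
  fam <- vapply(1:10, function(i) {
    m <- anc
    hit <- which(runif(120) < 0.05)
    m[hit] <- sample(AA, length(hit), replace = TRUE)
    paste(m, collapse = "")
  }, character(1))
  rand <- vapply(rep(120, 10), rseq, character(1))
  cl <- greedy_cluster(setNames(c(fam, rand), paste0("s", 1:20)))
  fam_cl <- cl$cluster[1:10]
  expect_length(unique(fam_cl), 1L)              # the family co-clusters
  expect_false(any(cl$cluster[11:20] %in% fam_cl))  # randoms stay out
})
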