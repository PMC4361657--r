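test_that("stratified folds partition patients with balanced classes", {
  d <- generate_dataset(sim_config(n_probes = 50, n_tol_up = 0,
                                   n_tol_down = 0, n_ntol_up = 0,
                                   n_ntol_down = 0, n_confounded = 0,
                                   lineage_sets = c(none = 0), seed = 1))
  fold <- make_folds(d$annotation, n_folds = 10, seed = 2)
  pat <- d$annotation[d$annotation$group != "CTRL", ]
  # partition: every patient exactly once, controls excluded
  expect_setequal(names(fold), pat$sample_id)
  sizes <- table(fold)
  expect_true(all(sizes %in% c(3, 4)))   # 32 patients over 10 folds
  # within-class fold counts differ by at most one
  for (g in c("TOL", "NONTOL")) {
    cnt <- table(fold[pat$sample_id[pat$group == g]])
    expect_lte(diff(range(cnt)), 1)
  }
  expect_identical(fold, make_folds(d$annotation, 10, seed = 2))
  expect_error(make_folds(d$annotation[1:8, ], 10), "fewer")
})

test_that("feature selection separates planted probes without leakage", {
  d <- generate_dataset(sim_config(n_probes = 2000, n_tol_up = 10,
                                   n_tol_down = 10, n_ntol_up = 0,
                                   n_ntol_down = 0, n_confounded = 0,
                                   effect_log2 = 1.5,
                                   sd_range = c(0.4, 0.4 + 1e-9),
                                   lineage_sets = c(none = 0), seed = 61))
  p <- patients_of(d)
  planted <- d$truth$probe_id[d$truth$category != "NULL"]
  hits <- 0
  set.seed(62)
  for (s in 1:5) {
    sub <- sample(seq_along(p$labels), 28)  # a training fold's worth
    feats <- select_features(p$x[, sub], p$labels[sub], k = 20,
                             selector = "sam_d")
    if (all(planted %in% feats)) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # k = n returns everything; ties break lexicographically
  all_feats <- suppressWarnings(
    select_features(p$x[1:30, ], p$labels, k = 50))
  expect_setequal(all_feats, rownames(p$x)[1:30])
  xx <- matrix(c(1, 1, 2, 2, 1, 1, 2, 2), 2, byrow = TRUE,
               dimnames = list(c("b_probe", "a_probe"), sprintf("s%d", 1:4)))
  sel <- select_features(xx, factor(c("A", "A", "B", "B")), k = 2,
                         selector = "snr")
  expect_identical(sel, c("a_probe", "b_probe"))
  # leakage guard: corrupting held-out labels cannot change selection,
  # because selection sees only the training fold
  feats1 <- select_features(p$x[, 1:28], p$labels[1:28], k = 10)
  lab2 <- p$labels
  lab2[29:32] <- rev(lab2[29:32])
  feats2 <- select_features(p$x[, 1:28], lab2[1:28], k = 10)
  expect_identical(feats1, feats2)
})

test_that("cross-validation separates strong planted signal", {
  d <- generate_dataset(sim_config(n_probes = 1000, effect_log2 = 2.0,
                                   sd_range = c(0.4, 0.4 + 1e-9),
                                   lineage_sets = c(none = 0), seed = 71))
  rep <- cross_validate(d$x, d$annotation,
                        cv_config(bootstrap_ci_reps = 200, seed = 71))
  expect_gte(rep$weighted_accuracy, 0.9)
  expect_gte(rep$auc, 0.95)
  # conservation: confusion totals = 32 patients, each held out once
  expect_equal(sum(rep$confusion), 32)
  held <- unlist(lapply(rep$folds, `[[`, "held_out"))
  expect_equal(sort(held), sort(d$annotation$sample_id[
    d$annotation$group != "CTRL"]))
  # stability counts bounded by fold count; planted probes dominate
  expect_true(all(rep$stability <= 10))
  stab <- feature_stability(rep, min_count = 9)
  planted <- d$truth$probe_id[d$truth$category != "NULL"]
  expect_gte(mean(stab$feature %in% planted), 0.8)
  # weighted accuracy is pooled-correct over total
  expect_equal(rep$weighted_accuracy,
               sum(diag(rep$confusion)) / sum(rep$confusion))
})

test_that("feature_stability filters and orders counts", {
  fake <- list(stability = c(b = 10L, a = 10L, c = 9L, d = 3L))
  st <- feature_stability(fake, min_count = 9)
  expect_identical(st$feature, c("a", "b", "c"))
  expect_identical(st$count, c(10L, 10L, 9L))
  expect_equal(nrow(feature_stability(fake, min_count = 0)), 4)
})

test_that("ROC/AUC agree with brute-force pair counting", {
  # hand case with one swapped pair: 3 of 4 pairs concordant
  r <- roc_auc(c(0.9, 0.4, 0.8, 0.3), c(TRUE, TRUE, FALSE, FALSE),
               bootstrap_reps = 0)
  expect_equal(r$auc, 0.75)
  # perfect separation and all-tied scores
  expect_equal(roc_auc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE),
                       bootstrap_reps = 0)$auc, 1.0)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3),
                       bootstrap_reps = 0)$auc, 0.5)
  # oracle equivalence on random small inputs (with ties)
  set.seed(5)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(roc_auc(sc, truth, bootstrap_reps = 0)$auc,
                 oracle_auc_pairs(sc, truth))
  }
  # bootstrap CI brackets the point estimate and is seed-stable
  set.seed(6)
  sc <- c(rnorm(10, 1), rnorm(10))
  tr <- rep(c(TRUE, FALSE), each = 10)
  r1 <- roc_auc(sc, tr, bootstrap_reps = 300, seed = 4)
  r2 <- roc_auc(sc, tr, bootstrap_reps = 300, seed = 4)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci[1], r1$auc + 1e-12)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(17)
  sc <- c(rnorm(12, 0.8), rnorm(15, 0))
  tr <- rep(c(TRUE, FALSE), c(12, 15))
  ours <- roc_auc(sc, tr, bootstrap_reps = 0)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = tr, predictor = sc,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})
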