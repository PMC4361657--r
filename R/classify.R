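#' Cross-validation configuration
#'
#' Settings for the leave-10\%-out classifier: number of stratified folds,
#' number of features selected per fold, the selector statistic, the
#' classifier contract, and the bootstrap used for the AUC confidence
#' interval.
#'
#' @param n_folds number of folds (default 10, i.e. leave-10\%-out).
#' @param k_features features selected within each training fold (default
#'   20; the stability analysis spans 20-80).
#' @param selector \code{"sam_d"} (moderated d with per-fold s0) or
#'   \code{"snr"} (signal-to-noise).
#' @param model a classifier contract from \code{\link{mlp_classifier}} or
#'   any list with \code{fit(x, y)} and \code{score(fit, x)} functions
#'   (score = probability of the first class, TOL).
#' @param bootstrap_ci_reps stratified bootstrap replicates for the AUC CI.
#' @param seed integer seed.
#' @return an object of class \code{cv_config}.
#' @export
cv_config <- function(n_folds = 10L, k_features = 20L,
                      selector = c("sam_d", "snr"),
                      model = mlp_classifier(),
                      bootstrap_ci_reps = 2000L, seed = 1L) {
  selector <- match.arg(selector)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (k_features < 1) stop("k_features must be >= 1")
  structure(list(n_folds = as.integer(n_folds),
                 k_features = as.integer(k_features), selector = selector,
                 model = model,
                 bootstrap_ci_reps = as.integer(bootstrap_ci_reps),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Small feed-forward neural network classifier contract
#'
#' A single-hidden-layer network (3 logistic units by default) fitted with
#' \code{nnet}, wrapped in the fit/score contract \code{\link{cross_validate}}
#' expects. Features are standardized with training-fold statistics before
#' fitting; the same transform is applied at scoring time. The fit is
#' seed-deterministic; a non-finite fit is retried once with a perturbed
#' seed and then fails loudly.
#'
#' @param size hidden units (default 3).
#' @param decay weight decay (default 0.05, stabilizing the small-n fit).
#' @param maxit maximum training epochs (default 500).
#' @return list with \code{fit(x, y, seed)} and \code{score(fit, x)}.
#' @export
mlp_classifier <- function(size = 3L, decay = 0.05, maxit = 500L) {
  fit_once <- function(x, y, seed) {
    set.seed(seed)
    nnet::nnet(x, as.numeric(y == levels(y)[1]), size = size, decay = decay,
               maxit = maxit, entropy = TRUE, trace = FALSE)
  }
  list(
    fit = function(x, y, seed = 1L) {
      y <- droplevels(as.factor(y))
      mu <- colMeans(x); sg <- apply(x, 2, sd); sg[sg == 0] <- 1
      xs <- scale(x, mu, sg)
      net <- fit_once(xs, y, seed)
      if (any(!is.finite(net$wts))) net <- fit_once(xs, y, seed + 104729L)
      if (any(!is.finite(net$wts))) stop("classifier failed to converge")
      list(net = net, mu = mu, sg = sg, positive = levels(y)[1])
    },
    score = function(fit, x) {
      xs <- scale(x, fit$mu, fit$sg)
      as.numeric(predict(fit$net, xs))
    })
}

#' Stratified fold assignment for cross-validation
#'
#' Partitions the patient samples (controls excluded) into \code{n_folds}
#' folds, stratified by phenotype so every fold holds out a balanced mix:
#' within each class, fold sizes differ by at most one. Every sample is
#' held out exactly once.
#'
#' @param annotation sample annotation; only TOL/NONTOL rows are used.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return named integer vector: fold index per patient sample id.
#' @export
make_folds <- function(annotation, n_folds = 10L, seed = 1L) {
  pat <- annotation[annotation$group %in% c("TOL", "NONTOL"), ]
  if (nrow(pat) < n_folds) stop("fewer samples than folds")
  set.seed(as.integer(seed))
  fold <- integer(nrow(pat))
  names(fold) <- pat$sample_id
  offset <- 0L
  for (g in c("TOL", "NONTOL")) {
    idx <- sample(which(pat$group == g))
    # continue the round-robin across classes so fold totals stay even
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
    offset <- (offset + length(idx)) %% n_folds
  }
  fold
}

#' Select top discriminative features within a training fold
#'
#' Ranks features by the absolute moderated SAM d-statistic (with the fudge
#' factor chosen on the training fold only) or by absolute signal-to-noise,
#' and returns the top \code{k}. Only training-fold samples are used, so no
#' information leaks from held-out samples. Ties break lexicographically by
#' feature id.
#'
#' @param x training-fold expression matrix (probes x samples).
#' @param labels training-fold two-level assignment.
#' @param k number of features.
#' @param selector \code{"sam_d"} or \code{"snr"}.
#' @return character vector of feature ids, best first.
#' @export
select_features <- function(x, labels, k = 20, selector = c("sam_d", "snr")) {
  selector <- match.arg(selector)
  if (k > nrow(x)) {
    warning("k exceeds number of features; returning all")
    k <- nrow(x)
  }
  if (selector == "sam_d") {
    obs <- compute_dstat(x, labels, s0 = 0)
    s0 <- suppressWarnings(choose_s0(obs$mean_log2_diff, obs$s))
    score <- abs(obs$mean_log2_diff / (obs$s + s0))
    ids <- obs$probe_id
  } else {
    r <- rank_genes(x, labels)
    score <- abs(r$score)
    ids <- r$probe_id
  }
  ids[order(-score, ids)][seq_len(k)]
}

#' Leave-10\%-out cross-validated classification
#'
#' For each stratified fold: selects features and fits the classifier on
#' the training 90\%, then scores and classifies the held-out samples.
#' Pools the per-fold confusion counts into an overall confusion matrix,
#' reports the overall weighted accuracy (pooled correct / total) and the
#' macro-averaged per-class accuracy, tallies how often each feature was
#' selected across folds, and builds a ROC curve with bootstrap AUC
#' confidence interval from the pooled held-out scores.
#'
#' @param x log2 expression matrix (probes x samples).
#' @param annotation sample annotation; controls are excluded.
#' @param cfg a \code{\link{cv_config}}.
#' @return object of class \code{cv_report}: list with \code{folds}
#'   (per-fold held-out ids, selected features, predictions),
#'   \code{confusion}, \code{weighted_accuracy}, \code{balanced_accuracy},
#'   \code{per_class_accuracy}, \code{stability} (named selection counts),
#'   \code{scores}, \code{truth}, \code{roc}, \code{auc}, \code{auc_ci}.
#' @examples
#' d <- generate_dataset(sim_config(n_probes = 300, effect_log2 = 2, seed = 3))
#' rep <- cross_validate(d$x, d$annotation,
#'                       cv_config(k_features = 10, bootstrap_ci_reps = 200))
#' rep
#' @export
cross_validate <- function(x, annotation, cfg = cv_config()) {
  stopifnot(inherits(cfg, "cv_config"))
  pat <- annotation[annotation$group %in% c("TOL", "NONTOL"), ]
  if (min(table(pat$group)) < 2) stop("need >= 2 samples per class")
  fold <- make_folds(annotation, cfg$n_folds, cfg$seed)
  y_all <- factor(pat$group, levels = c("TOL", "NONTOL"))
  names(y_all) <- pat$sample_id
  scores <- numeric(0); truth <- character(0)
  folds <- vector("list", cfg$n_folds)
  stability <- integer(0)
  confusion <- matrix(0L, 2, 2,
                      dimnames = list(true = c("TOL", "NONTOL"),
                                      predicted = c("TOL", "NONTOL")))
  for (f in seq_len(cfg$n_folds)) {
    hold <- names(fold)[fold == f]
    train <- setdiff(names(fold), hold)
    feats <- select_features(x[, train, drop = FALSE], y_all[train],
                             cfg$k_features, cfg$selector)
    fit <- cfg$model$fit(t(x[feats, train, drop = FALSE]), y_all[train],
                         seed = cfg$seed + f)
    sc <- cfg$model$score(fit, t(x[feats, hold, drop = FALSE]))
    pred <- ifelse(sc >= 0.5, "TOL", "NONTOL")
    for (i in seq_along(hold))
      confusion[as.character(y_all[hold[i]]), pred[i]] <-
        confusion[as.character(y_all[hold[i]]), pred[i]] + 1L
    scores <- c(scores, sc)
    truth <- c(truth, as.character(y_all[hold]))
    for (ft in feats)
      stability[ft] <- (if (is.na(stability[ft])) 0L else stability[ft]) + 1L
    folds[[f]] <- list(held_out = hold, features = feats,
                       scores = setNames(sc, hold),
                       predicted = setNames(pred, hold),
                       n_correct = sum(pred == as.character(y_all[hold])),
                       n_incorrect = sum(pred != as.character(y_all[hold])))
  }
  per_class <- diag(confusion) / rowSums(confusion)
  roc <- roc_auc(scores, truth == "TOL", bootstrap_reps = cfg$bootstrap_ci_reps,
                 seed = cfg$seed)
  structure(list(folds = folds, confusion = confusion,
                 weighted_accuracy = sum(diag(confusion)) / sum(confusion),
                 balanced_accuracy = mean(per_class),
                 per_class_accuracy = per_class,
                 stability = sort(stability, decreasing = TRUE),
                 scores = scores, truth = truth,
                 roc = roc$roc, auc = roc$auc, auc_ci = roc$ci,
                 config = cfg),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validated classifier (%d folds, %d features/fold)\n",
              x$config$n_folds, x$config$k_features))
  print(x$confusion)
  cat(sprintf("  weighted accuracy %.3f (TOL %d/%d, non-TOL %d/%d), balanced %.3f\n",
              x$weighted_accuracy,
              x$confusion["TOL", "TOL"], sum(x$confusion["TOL", ]),
              x$confusion["NONTOL", "NONTOL"], sum(x$confusion["NONTOL", ]),
              x$balanced_accuracy))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[1],
              x$auc_ci[2]))
  invisible(x)
}

#' ROC plot for a cross-validation report
#'
#' @param x a \code{cv_report}.
#' @param ... passed to \code{plot}.
#' @export
plot.cv_report <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "false positive rate", ylab = "true positive rate",
       main = sprintf("ROC, AUC %.2f (95%% CI %.2f-%.2f)", x$auc,
                      x$auc_ci[1], x$auc_ci[2]), ...)
  abline(0, 1, col = "grey60", lty = 2)
  invisible(x)
}

#' Feature-selection stability table
#'
#' Features selected in at least \code{min_count} cross-validation rounds,
#' sorted by count (descending) then id — the "number of times selected"
#' view of classifier stability.
#'
#' @param report a \code{\link{cross_validate}} report.
#' @param min_count minimum selection count (default 9, i.e. 9-10 of 10).
#' @return data.frame with \code{feature} and \code{count}.
#' @export
feature_stability <- function(report, min_count = 9) {
  st <- report$stability[report$stability >= min_count]
  ord <- order(-st, names(st))
  data.frame(feature = names(st)[ord], count = unname(st[ord]),
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' Builds the empirical ROC from continuous scores, computes AUC by the
#' trapezoid rule (equivalent to the tie-corrected rank statistic), and a
#' stratified percentile-bootstrap confidence interval.
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param truth logical (or two-level) vector; \code{TRUE} = positive.
#' @param bootstrap_reps bootstrap replicates (0 skips the CI).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with \code{roc} (data.frame \code{fpr}, \code{tpr}),
#'   \code{auc}, \code{ci}.
#' @export
roc_auc <- function(scores, truth, bootstrap_reps = 2000, conf = 0.95,
                    seed = 1L) {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2) stop("both classes must be present")
  auc_of <- function(sc, tr) {
    # tie-corrected rank form of the Mann-Whitney statistic
    r <- rank(sc)
    n1 <- sum(tr); n0 <- sum(!tr)
    (sum(r[tr]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- t(vapply(thr, function(t) {
    c(fpr = mean(scores[!truth] >= t), tpr = mean(scores[truth] >= t))
  }, numeric(2)))
  auc <- auc_of(scores, truth)
  ci <- c(NA_real_, NA_real_)
  if (bootstrap_reps > 0) {
    set.seed(as.integer(seed))
    pos <- which(truth); neg <- which(!truth)
    boots <- vapply(seq_len(bootstrap_reps), function(b) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      auc_of(scores[idx], truth[idx])
    }, numeric(1))
    ci <- unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  list(roc = data.frame(fpr = roc[, "fpr"], tpr = roc[, "tpr"]),
       auc = auc, ci = ci)
}
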