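#' SAM configuration
#'
#' Settings for Significance Analysis of Microarrays: number of label
#' permutations, target false discovery rate, the natural-scale fold-change
#' floor, the fudge-factor (\code{s0}) selection rule and the permutation
#' summary used in the FDR estimate.
#'
#' @param n_perm number of label permutations (>= 10). When fewer distinct
#'   group assignments exist they are enumerated completely.
#' @param target_fdr target FDR for delta calibration (default 0.10, the
#'   threshold used for the discovery comparisons).
#' @param min_fold natural-scale fold-change floor (default 1.5); called
#'   probes must change at least this much between group geometric means.
#' @param s0 either \code{"auto"} (percentile search minimizing the
#'   coefficient of variation of windowed MADs of d) or a fixed
#'   non-negative number.
#' @param fdr_summary summary of permutation false-call counts:
#'   \code{"median"} (default) or \code{"pct90"}.
#' @param n_delta size of the delta calibration grid.
#' @param seed integer seed controlling permutation sampling.
#' @return an object of class \code{sam_config}.
#' @export
sam_config <- function(n_perm = 200L, target_fdr = 0.10, min_fold = 1.5,
                       s0 = "auto", fdr_summary = c("median", "pct90"),
                       n_delta = 200L, seed = 1L) {
  fdr_summary <- match.arg(fdr_summary)
  if (n_perm < 10) stop("n_perm must be >= 10")
  if (target_fdr <= 0 || target_fdr >= 1) stop("target_fdr must be in (0,1)")
  if (min_fold < 1) stop("min_fold must be >= 1")
  if (is.numeric(s0) && s0 < 0) stop("fixed s0 must be >= 0")
  structure(list(n_perm = as.integer(n_perm), target_fdr = target_fdr,
                 min_fold = min_fold, s0 = s0, fdr_summary = fdr_summary,
                 n_delta = as.integer(n_delta), seed = as.integer(seed)),
            class = "sam_config")
}

# two-group sums needed by the d-statistic, vectorized over probes
.group_stats <- function(x, grp_a, grp_b) {
  na <- length(grp_a); nb <- length(grp_b)
  xa <- x[, grp_a, drop = FALSE]; xb <- x[, grp_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2); ssb <- rowSums((xb - mb)^2)
  a <- (1 / na + 1 / nb) / (na + nb - 2)
  s <- sqrt(a * (ssa + ssb))
  list(diff = ma - mb, s = s)
}

#' SAM relative-difference statistic
#'
#' Computes, per probe, the moderated statistic
#' \code{d = (mean_A - mean_B) / (s + s0)} where \code{s} is the pooled
#' two-sample standard error with pooling constant
#' \code{a = (1/n_A + 1/n_B) / (n_A + n_B - 2)}. The fudge factor \code{s0}
#' stabilizes \code{d} for low-variance probes.
#'
#' @param x log2 expression matrix (probes x samples) with column names.
#' @param labels character/factor of length \code{ncol(x)} with exactly two
#'   levels; the first level (alphabetical unless a factor) is group A.
#' @param s0 non-negative fudge factor.
#' @return data.frame with \code{probe_id}, \code{d}, \code{s},
#'   \code{mean_log2_diff} (A minus B).
#' @export
compute_dstat <- function(x, labels, s0 = 0) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  grp_a <- which(labels == levels(labels)[1])
  grp_b <- which(labels == levels(labels)[2])
  if (length(grp_a) < 2 || length(grp_b) < 2)
    stop("each group needs >= 2 samples")
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("p%04d", seq_len(nrow(x)))
  st <- .group_stats(x, grp_a, grp_b)
  denom <- st$s + s0
  if (any(denom == 0))
    stop("zero-variance probe with s0 = 0; use a positive s0")
  data.frame(probe_id = rownames(x), d = st$diff / denom, s = st$s,
             mean_log2_diff = st$diff, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Choose the SAM fudge factor s0
#'
#' Evaluates candidate values of \code{s0} at the percentiles
#' \code{0, 5, ..., 100} of the per-probe standard errors. For each
#' candidate the probes are split into windows by quantiles of \code{s};
#' the candidate minimizing the coefficient of variation of the median
#' absolute deviation of \code{d} across windows is returned (ties go to
#' the smallest candidate, so homoscedastic data yields the 0th percentile).
#'
#' @param diff per-probe mean differences (numerator of d).
#' @param s per-probe pooled standard errors.
#' @param n_windows number of s-quantile windows (default 100, reduced when
#'   there are few probes).
#' @return the selected \code{s0} (a scalar >= 0).
#' @export
choose_s0 <- function(diff, s, n_windows = 100L) {
  if (length(unique(s)) == 1) {
    warning("all standard errors equal; s0 set to 0")
    return(0)
  }
  cand <- unname(quantile(s, probs = seq(0, 1, by = 0.05)))
  n_windows <- max(2L, min(as.integer(n_windows), floor(length(s) / 5)))
  win <- cut(rank(s, ties.method = "first"), breaks = n_windows,
             labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- diff / (s + s0)
    mads <- tapply(d, win, mad)
    m <- mean(mads)
    if (m == 0) return(0)
    sd(mads) / m
  }, numeric(1))
  cand[which.min(cv)]   # which.min takes the first (smallest) on ties
}

# all (or n_perm sampled) two-group label assignments; returns a matrix
# whose columns are permuted label vectors
.label_permutations <- function(labels, n_perm, seed) {
  labels <- as.factor(labels)
  n <- length(labels)
  na <- sum(labels == levels(labels)[1])
  total <- choose(n, na)
  if (total <= n_perm) {
    sets <- combn(n, na)
    perms <- apply(sets, 2, function(idx) {
      l <- rep(levels(labels)[2], n)
      l[idx] <- levels(labels)[1]
      l
    })
  } else {
    set.seed(seed)
    perms <- replicate(n_perm, as.character(labels[sample(n)]))
  }
  perms
}

# SAM cut rule: given sorted observed d and expected order statistics dbar,
# find the cut thresholds at a given delta and return them (Inf/-Inf when
# no probe crosses)
.sam_cuts <- function(d_sorted, dbar, delta) {
  n <- length(d_sorted)
  dev <- d_sorted - dbar
  # move outward from the origin of the expected quantiles
  upper <- which(dev > delta & dbar >= 0)
  lower <- which(-dev > delta & dbar <= 0)
  cutup <- if (length(upper)) d_sorted[min(upper)] else Inf
  cutlow <- if (length(lower)) d_sorted[max(lower)] else -Inf
  c(cutlow = cutlow, cutup = cutup)
}

#' Run SAM differential expression
#'
#' The full SAM procedure: observed d-statistics with an automatically (or
#' fixed) chosen fudge factor, expected order statistics from balanced label
#' permutations, calibration of the delta threshold to a target FDR using
#' the permutation false-call count, and a final fold-change filter (ratio
#' of group geometric means, \code{2^|mean log2 difference|}).
#'
#' At each candidate delta a probe is called if its sorted observed
#' d-statistic departs from the permutation-expected value by more than
#' delta; the classic cut rule then calls all probes beyond the first
#' crossing. The FDR estimate divides the median (or 90th percentile)
#' number of permutation d-values exceeding the same cuts by the number of
#' called probes (pi0 fixed at 1, conservative). The returned delta is the
#' smallest grid value whose estimated FDR is at or below target; if none
#' qualifies the call set is empty and \code{est_fdr} reports the best
#' achievable value.
#'
#' @param x log2 expression matrix (probes x samples).
#' @param labels two-level assignment of columns.
#' @param cfg a \code{\link{sam_config}}.
#' @return object of class \code{sam_fit}: a list with \code{stats}
#'   (per-probe d, s, mean_log2_diff, fold_change, direction),
#'   \code{s0}, \code{delta}, \code{est_fdr}, \code{called} (directional
#'   gene list data.frame with \code{probe_id}, \code{direction}),
#'   \code{perm_expected}, \code{cuts}, \code{config} and the group labels.
#' @examples
#' d <- generate_dataset(sim_config(n_probes = 300, seed = 2))
#' ann <- d$annotation
#' pat <- ann$group != "CTRL"
#' fit <- run_sam(d$x[, pat], ann$group[pat], sam_config(n_perm = 50))
#' fit
#' @export
run_sam <- function(x, labels, cfg = sam_config()) {
  stopifnot(inherits(cfg, "sam_config"))
  labels <- droplevels(as.factor(labels))
  obs <- compute_dstat(x, labels, s0 = 0)
  s0 <- if (identical(cfg$s0, "auto"))
    choose_s0(obs$mean_log2_diff, obs$s)
  else cfg$s0
  d <- obs$mean_log2_diff / (obs$s + s0)
  n <- length(d)
  ord <- order(d)
  d_sorted <- d[ord]

  perms <- .label_permutations(labels, cfg$n_perm, cfg$seed)
  n_used <- ncol(perms)
  perm_sorted <- matrix(NA_real_, n, n_used)
  for (b in seq_len(n_used)) {
    pb <- compute_dstat(x, factor(perms[, b], levels = levels(labels)), s0)
    perm_sorted[, b] <- sort(pb$d)
  }
  dbar <- rowMeans(perm_sorted)

  deltas <- seq(0, max(abs(d_sorted - dbar)), length.out = cfg$n_delta)
  summ_fun <- if (cfg$fdr_summary == "median") median else
    function(v) quantile(v, 0.9, names = FALSE)
  best <- NULL
  fdr_path <- rep(NA_real_, length(deltas))
  for (k in seq_along(deltas)) {
    cuts <- .sam_cuts(d_sorted, dbar, deltas[k])
    called_idx <- which(d >= cuts["cutup"] | d <= cuts["cutlow"])
    n_called <- length(called_idx)
    if (n_called == 0) { fdr_path[k] <- 0; next }
    false_calls <- vapply(seq_len(n_used), function(b)
      sum(perm_sorted[, b] >= cuts["cutup"] |
            perm_sorted[, b] <= cuts["cutlow"]), numeric(1))
    est <- min(1, summ_fun(false_calls) / n_called)
    fdr_path[k] <- est
    if (est <= cfg$target_fdr) {
      best <- list(delta = deltas[k], est_fdr = est, cuts = cuts,
                   called_idx = called_idx)
      break
    }
  }
  if (is.null(best)) {
    best <- list(delta = deltas[length(deltas)],
                 est_fdr = min(fdr_path[fdr_path > 0], 1, na.rm = TRUE),
                 cuts = c(cutlow = -Inf, cutup = Inf),
                 called_idx = integer(0))
  }

  fold <- 2^abs(obs$mean_log2_diff)
  stats <- data.frame(probe_id = obs$probe_id, d = d, s = obs$s,
                      mean_log2_diff = obs$mean_log2_diff,
                      fold_change = fold,
                      direction = ifelse(obs$mean_log2_diff >= 0, "up", "down"),
                      stringsAsFactors = FALSE)
  keep <- intersect(best$called_idx, which(fold >= cfg$min_fold))
  called <- gene_list(stats$probe_id[keep], stats$direction[keep],
                      label = sprintf("%s vs %s", levels(labels)[1],
                                      levels(labels)[2]))
  structure(list(stats = stats, s0 = s0, delta = best$delta,
                 est_fdr = best$est_fdr, called = called,
                 perm_expected = dbar, d_sorted = d_sorted,
                 cuts = best$cuts, n_perm_used = n_used,
                 groups = levels(labels), config = cfg),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat(sprintf("SAM fit: %s vs %s, %d probes, %d permutations\n",
              x$groups[1], x$groups[2], nrow(x$stats), x$n_perm_used))
  cat(sprintf("  s0 = %.4g, delta = %.4g, estimated FDR = %.3f\n",
              x$s0, x$delta, x$est_fdr))
  cat(sprintf("  called: %d probes (%d up, %d down) at fold >= %.2g\n",
              nrow(x$called), sum(x$called$direction == "up"),
              sum(x$called$direction == "down"), x$config$min_fold))
  invisible(x)
}

#' @export
summary.sam_fit <- function(object, ...) {
  print(object)
  cat("\nTop called probes by |d|:\n")
  st <- object$stats[object$stats$probe_id %in% object$called$probe_id, ]
  print(head(st[order(-abs(st$d)), ], 10), row.names = FALSE)
  invisible(object)
}

#' SAM quantile-quantile plot
#'
#' Observed sorted d-statistics against permutation-expected order
#' statistics, with the delta band and calibrated cuts.
#'
#' @param x a \code{sam_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.sam_fit <- function(x, ...) {
  plot(x$perm_expected, x$d_sorted, pch = 20, cex = 0.5,
       xlab = "expected d (permutation)", ylab = "observed d",
       main = "SAM", ...)
  abline(0, 1, col = "grey40")
  abline(x$delta, 1, lty = 2, col = "grey60")
  abline(-x$delta, 1, lty = 2, col = "grey60")
  if (is.finite(x$cuts["cutup"])) abline(h = x$cuts["cutup"], col = "red3")
  if (is.finite(x$cuts["cutlow"])) abline(h = x$cuts["cutlow"], col = "blue3")
  invisible(x)
}

#' SAM-based power simulation
#'
#' Simulates repeated two-group cohorts with a planted fraction of truly
#' differential probes, runs the full SAM procedure on each, and reports
#' the average fraction of true probes called (power) and the average
#' realized FDR. This mirrors the sample-size estimation approach of
#' running SAM on pilot-like data to gauge detectable effect sizes.
#'
#' @param n_per_group samples per group.
#' @param n_true number of truly differential probes.
#' @param effect_fold natural-scale fold change of true probes.
#' @param sd log2-scale noise sd.
#' @param n_probes total probes simulated (default 2000).
#' @param target_fdr target FDR passed to SAM.
#' @param n_reps simulation replicates.
#' @param n_perm permutations per SAM run.
#' @param seed integer seed.
#' @return list with \code{power} and \code{fdr_realized} (means over
#'   replicates) and the per-replicate values.
#' @export
estimate_power <- function(n_per_group = 10, n_true = 233, effect_fold = 1.5,
                           sd = 0.4, n_probes = 2000, target_fdr = 0.10,
                           n_reps = 5, n_perm = 100, seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  pw <- fdr <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_probes = n_probes,
                      group_sizes = c(TOL = n_per_group, NONTOL = n_per_group,
                                      CTRL = 2),
                      n_tol_up = ceiling(n_true / 2),
                      n_tol_down = floor(n_true / 2),
                      n_ntol_up = 0, n_ntol_down = 0, n_confounded = 0,
                      effect_log2 = log2(effect_fold),
                      sd_range = c(sd, sd + 1e-6),
                      lineage_sets = c(none = 0),
                      seed = seed + r)
    d <- generate_dataset(cfg)
    pat <- d$annotation$group != "CTRL"
    fit <- run_sam(d$x[, pat], d$annotation$group[pat],
                   sam_config(n_perm = n_perm, target_fdr = target_fdr,
                              seed = seed + r))
    true_ids <- d$truth$probe_id[d$truth$category %in% c("TOL_UP", "TOL_DOWN")]
    called <- fit$called$probe_id
    pw[r] <- if (length(true_ids)) mean(true_ids %in% called) else 0
    fdr[r] <- if (length(called)) mean(!(called %in% true_ids)) else 0
  }
  list(power = mean(pw), fdr_realized = mean(fdr),
       power_by_rep = pw, fdr_by_rep = fdr)
}
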