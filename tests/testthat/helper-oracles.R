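# Independent oracles, coded by brute force so they share no code path with
# the package implementations they check.

# SAM d-statistic from the closed form, one probe at a time with plain loops
oracle_dstat <- function(x, labels, s0 = 0) {
  labels <- as.factor(labels)
  a_idx <- which(labels == levels(labels)[1])
  b_idx <- which(labels == levels(labels)[2])
  na <- length(a_idx); nb <- length(b_idx)
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    xa <- x[i, a_idx]; xb <- x[i, b_idx]
    ma <- sum(xa) / na; mb <- sum(xb) / nb
    ss <- sum((xa - ma)^2) + sum((xb - mb)^2)
    si <- sqrt(((1 / na + 1 / nb) / (na + nb - 2)) * ss)
    out[i] <- (ma - mb) / (si + s0)
  }
  out
}

# weighted-KS enrichment score by explicit position-by-position walk
oracle_es <- function(ids, scores, gene_set, p = 1) {
  n <- length(ids)
  in_set <- ids %in% gene_set
  nh <- sum(in_set)
  denom <- sum(abs(scores[in_set])^p)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      run <- run + (if (denom > 0) abs(scores[i])^p / denom else 1 / nh)
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# upper-tail hypergeometric P(X >= k) by exhaustive enumeration of draws
oracle_hyper_enum <- function(universe_size, set_size, list_size, k) {
  draws <- combn(universe_size, list_size)
  hits <- colSums(draws <= set_size)   # members 1..set_size are "in set"
  mean(hits >= k)
}

# AUC as the fraction of concordant positive/negative pairs (ties = 1/2)
oracle_auc_pairs <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# small deterministic two-group matrix fixture
tiny_matrix <- function(n_probes = 20, na = 5, nb = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_probes * (na + nb)), n_probes,
              dimnames = list(sprintf("g%02d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(na + nb))))
  labels <- factor(rep(c("A", "B"), c(na, nb)))
  list(x = x, labels = labels)
}

# planted-cohort shorthand used across recovery tests
planted_cohort <- function(seed, n_probes = 2000, effect = 1.0, sd = 0.4,
                           n_tol = 100, n_ntol = 0, n_conf = 0, ...) {
  generate_dataset(sim_config(
    n_probes = n_probes,
    n_tol_up = ceiling(n_tol / 2), n_tol_down = floor(n_tol / 2),
    n_ntol_up = ceiling(n_ntol / 2), n_ntol_down = floor(n_ntol / 2),
    n_confounded = n_conf, effect_log2 = effect,
    sd_range = c(sd, sd + 1e-9), lineage_sets = c(none = 0),
    seed = seed, ...))
}

patients_of <- function(d) {
  keep <- d$annotation$group != "CTRL"
  list(x = d$x[, d$annotation$sample_id[keep], drop = FALSE],
       labels = factor(d$annotation$group[keep],
                       levels = c("TOL", "NONTOL")))
}

# a no-structure config for small fixtures (all planted counts zero)
small_cfg <- function(n_probes, seed, ...)
  sim_config(n_probes = n_probes, n_tol_up = 0, n_tol_down = 0,
             n_ntol_up = 0, n_ntol_down = 0, n_confounded = 0,
             lineage_sets = c(none = 0), seed = seed, ...)
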