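#' Rank genes by signal-to-noise ratio
#'
#' Scores every probe by \code{(mu_A - mu_B) / (sd_A + sd_B)} with each
#' standard deviation floored at \code{max(0.2 * |mu|, 0.2)} (the classic
#' GSEA floor preventing low-variance probes from dominating), and returns
#' the probes in descending score order. Ties are broken by probe id so the
#' ranking is deterministic.
#'
#' @param x log2 expression matrix.
#' @param labels two-level assignment of columns; first level is group A.
#' @return data.frame with \code{probe_id} and \code{score}, descending.
#' @export
rank_genes <- function(x, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  a <- which(labels == levels(labels)[1])
  b <- which(labels == levels(labels)[2])
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 samples")
  floor_sd <- function(s, m) pmax(s, 0.2 * abs(m), 0.2)
  row_sd <- function(m) {
    mu <- rowMeans(m)
    sqrt(pmax(rowSums((m - mu)^2) / (ncol(m) - 1), 0))
  }
  ma <- rowMeans(x[, a, drop = FALSE]); mb <- rowMeans(x[, b, drop = FALSE])
  sa <- floor_sd(row_sd(x[, a, drop = FALSE]), ma)
  sb <- floor_sd(row_sd(x[, b, drop = FALSE]), mb)
  score <- (ma - mb) / (sa + sb)
  ord <- order(-score, rownames(x))
  data.frame(probe_id = rownames(x)[ord], score = score[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating \code{|score|^p / sum_hits |score|^p}
#' at set members ("hits") and \code{-1 / (N - N_H)} at non-members. The
#' enrichment score is the signed maximal deviation of this running sum
#' from zero. ES is bounded in [-1, 1] and the running sum returns to zero
#' at the end of the list.
#'
#' @param ranked data.frame from \code{\link{rank_genes}} (or any ordered
#'   \code{probe_id}/\code{score} table).
#' @param gene_set character vector of member ids; must intersect the
#'   ranked universe and must not cover it entirely.
#' @param p hit weight exponent (default 1; 0 gives the classic KS walk).
#' @return list with \code{ES}, \code{running_sum}, \code{peak_index}.
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  hits <- ranked$probe_id %in% gene_set
  n <- length(hits); nh <- sum(hits)
  if (nh == 0) stop("gene set does not intersect the ranked universe")
  if (nh == n) stop("gene set equals the universe")
  w <- abs(ranked$score)^p
  denom_hit <- sum(w[hits])
  inc <- ifelse(hits,
                if (denom_hit > 0) w / denom_hit else 1 / nh,
                -1 / (n - nh))
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  list(ES = running[peak], running_sum = running, peak_index = peak)
}

# ES for every set against one ranking; sets as list of id vectors
.es_all <- function(ranked, sets, p = 1) {
  vapply(sets, function(s) enrichment_score(ranked, s, p)$ES, numeric(1))
}

#' Gene set enrichment analysis
#'
#' Weighted-KS GSEA with a permutation null. For each set the normalized
#' enrichment score divides the observed ES by the mean of same-signed
#' permuted ES values; the p-value is the fraction of same-signed permuted
#' ES at least as extreme; FDR uses the standard NES-ratio estimator
#' (fraction of permuted NES beyond the observed NES over the fraction of
#' observed NES beyond it), clipped to [0, 1].
#'
#' Phenotype permutation re-labels samples and re-ranks; it needs at least
#' 7 samples, below which the test auto-switches to gene-set (random
#' member) permutation with a warning.
#'
#' @param x log2 expression matrix.
#' @param labels two-level assignment.
#' @param sets named list of gene-set member vectors (see
#'   \code{\link{read_gmt}}).
#' @param n_perm number of permutations (default 1000).
#' @param perm_type \code{"phenotype"} or \code{"gene_set"}.
#' @param p weight exponent passed to \code{\link{enrichment_score}}.
#' @param seed integer seed.
#' @return object of class \code{gsea_result}: data.frame with one row per
#'   set (\code{set}, \code{size}, \code{ES}, \code{NES}, \code{p_value},
#'   \code{fdr_q}).
#' @export
gsea_test <- function(x, labels, sets, n_perm = 1000,
                      perm_type = c("phenotype", "gene_set"), p = 1,
                      seed = 1L) {
  perm_type <- match.arg(perm_type)
  labels <- droplevels(as.factor(labels))
  if (perm_type == "phenotype" && ncol(x) < 7) {
    warning("fewer than 7 samples; switching to gene_set permutation")
    perm_type <- "gene_set"
  }
  ranked <- rank_genes(x, labels)
  sets <- lapply(sets, function(s) intersect(s, ranked$probe_id))
  keep <- vapply(sets, length, integer(1)) >= 1
  sets <- sets[keep]
  if (!length(sets)) stop("no set intersects the ranked universe")
  es_obs <- .es_all(ranked, sets, p)

  set.seed(as.integer(seed))
  es_perm <- matrix(NA_real_, length(sets), n_perm,
                    dimnames = list(names(sets), NULL))
  if (perm_type == "phenotype") {
    for (b in seq_len(n_perm)) {
      rb <- rank_genes(x, labels[sample(ncol(x))])
      es_perm[, b] <- .es_all(rb, sets, p)
    }
  } else {
    sizes <- vapply(sets, length, integer(1))
    for (b in seq_len(n_perm)) {
      es_perm[, b] <- vapply(sizes, function(k)
        enrichment_score(ranked, sample(ranked$probe_id, k), p)$ES,
        numeric(1))
    }
  }

  norm_one <- function(es, perm) {
    same <- if (es >= 0) perm[perm >= 0] else -perm[perm < 0]
    m <- mean(same)
    if (!length(same) || m == 0) return(c(NA_real_, NA_real_))
    nes <- if (es >= 0) es / m else -(-es / m)
    pv <- (sum(same >= abs(es)) + 1) / (length(same) + 1)
    c(nes, pv)
  }
  np <- t(vapply(seq_along(sets), function(i)
    norm_one(es_obs[i], es_perm[i, ]), numeric(2)))
  nes <- np[, 1]; pval <- np[, 2]

  # NES-ratio FDR: normalize all permuted ES the same way, then compare tails
  nes_perm <- es_perm
  for (i in seq_along(sets)) {
    pos <- es_perm[i, ] >= 0
    mpos <- mean(es_perm[i, pos]); mneg <- mean(abs(es_perm[i, !pos]))
    nes_perm[i, pos] <- if (is.finite(mpos) && mpos > 0)
      es_perm[i, pos] / mpos else NA_real_
    nes_perm[i, !pos] <- if (is.finite(mneg) && mneg > 0)
      es_perm[i, !pos] / mneg else NA_real_
  }
  all_perm <- nes_perm[!is.na(nes_perm)]
  fdr <- vapply(seq_along(sets), function(i) {
    v <- nes[i]
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      num <- mean(all_perm >= v); den <- mean(nes[!is.na(nes)] >= v)
    } else {
      num <- mean(all_perm <= v); den <- mean(nes[!is.na(nes)] <= v)
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  structure(data.frame(set = names(sets),
                       size = vapply(sets, length, integer(1)),
                       ES = es_obs, NES = nes, p_value = pval, fdr_q = fdr,
                       stringsAsFactors = FALSE, row.names = NULL),
            perm_type = perm_type, n_perm = n_perm,
            class = c("gsea_result", "data.frame"))
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: %d sets, %d %s permutations\n", nrow(x),
              attr(x, "n_perm"), attr(x, "perm_type")))
  df <- as.data.frame(x)
  df$ES <- round(df$ES, 3); df$NES <- round(df$NES, 3)
  print(df[order(df$p_value), ], row.names = FALSE)
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For every gene set, tests whether the query list overlaps it more than
#' expected by chance within a fixed universe, using the upper-tail
#' hypergeometric probability \code{P(X >= k)}; Benjamini-Hochberg q-values
#' are computed across sets. A generic stand-in for proprietary
#' process-network enrichment tools.
#'
#' @param list_ids character vector (or \code{\link{gene_list}}) of query
#'   ids; must be a subset of \code{universe}.
#' @param sets named list of gene-set member vectors.
#' @param universe character vector of all testable ids.
#' @param fdr_alpha significance threshold on q (default 0.05).
#' @return object of class \code{ora_result}: data.frame per set with
#'   \code{k_overlap}, \code{set_size}, \code{list_size},
#'   \code{universe_size}, \code{p_hypergeom}, \code{fdr_q}, \code{ratio},
#'   \code{significant}; rows ordered by p ascending.
#' @export
ora_test <- function(list_ids, sets, universe, fdr_alpha = 0.05) {
  if (inherits(list_ids, "gene_list")) list_ids <- list_ids$probe_id
  list_ids <- unique(list_ids)
  if (!all(list_ids %in% universe))
    stop("query list must be a subset of the universe")
  n_u <- length(unique(universe)); n_l <- length(list_ids)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, list_ids))
    pv <- phyper(k - 1, length(s), n_u - length(s), n_l, lower.tail = FALSE)
    data.frame(set = nm, k_overlap = k, set_size = length(s),
               list_size = n_l, universe_size = n_u, p_hypergeom = pv,
               ratio = sprintf("%d/%d", k, length(s)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- p.adjust(out$p_hypergeom, "BH")
  out$significant <- out$fdr_q <= fdr_alpha
  out <- out[order(out$p_hypergeom), ]
  rownames(out) <- NULL
  structure(out, class = c("ora_result", "data.frame"))
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("Over-representation: %d sets tested, %d significant\n",
              nrow(x), sum(x$significant)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
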