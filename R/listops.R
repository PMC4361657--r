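#' Directional gene list
#'
#' A set of (probe_id, direction) pairs — the unit every filtering and
#' enrichment step consumes. A probe appears at most once.
#'
#' @param probe_id character vector of probe identifiers.
#' @param direction character vector, \code{"up"} or \code{"down"}.
#' @param label free-text description.
#' @return data.frame of class \code{gene_list} with columns
#'   \code{probe_id}, \code{direction} and a \code{label} attribute.
#' @export
gene_list <- function(probe_id = character(), direction = character(),
                      label = "") {
  if (length(probe_id) != length(direction))
    stop("probe_id and direction must have equal length")
  if (anyDuplicated(probe_id)) stop("a probe may appear at most once")
  if (length(direction) && !all(direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  structure(data.frame(probe_id = as.character(probe_id),
                       direction = as.character(direction),
                       stringsAsFactors = FALSE),
            label = label, class = c("gene_list", "data.frame"))
}

#' @export
print.gene_list <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("Directional gene list%s: %d probes (%d up, %d down)\n",
              if (nzchar(lab)) paste0(" [", lab, "]") else "",
              nrow(x), sum(x$direction == "up"), sum(x$direction == "down")))
  if (nrow(x)) print(head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}

# keyed representation for set algebra on (probe, direction) pairs
.gl_key <- function(gl) paste(gl$probe_id, gl$direction)

#' Split vs-control lists into shared and unique components
#'
#' Probes differential in \emph{both} patient groups versus control with
#' the \emph{same} direction are "shared" — attributable to transplantation
#' or immunosuppression generally, hence non-informative for the
#' tolerant/non-tolerant contrast — and are filtered out. Probes present in
#' both lists with \emph{opposite} directions are informative and stay in
#' both unique lists.
#'
#' @param tol_vs_ctrl,ntol_vs_ctrl \code{\link{gene_list}}s from the
#'   TOL-vs-control and non-TOL-vs-control comparisons.
#' @return list with \code{shared}, \code{unique_tol}, \code{unique_ntol}
#'   gene lists.
#' @export
derive_unique_lists <- function(tol_vs_ctrl, ntol_vs_ctrl) {
  kt <- .gl_key(tol_vs_ctrl); kn <- .gl_key(ntol_vs_ctrl)
  shared_keys <- intersect(kt, kn)
  shared <- tol_vs_ctrl[kt %in% shared_keys, ]
  unique_tol <- tol_vs_ctrl[!(kt %in% shared_keys), ]
  unique_ntol <- ntol_vs_ctrl[!(kn %in% shared_keys), ]
  list(shared = gene_list(shared$probe_id, shared$direction, "shared"),
       unique_tol = gene_list(unique_tol$probe_id, unique_tol$direction,
                              "unique TOL vs control"),
       unique_ntol = gene_list(unique_ntol$probe_id, unique_ntol$direction,
                               "unique non-TOL vs control"))
}

#' Derive the final tolerance and non-tolerance gene lists
#'
#' Retains, from the two-group (TOL vs non-TOL) list, only probes that are
#' also unique in the corresponding comparison to control. The final TOL
#' list therefore distinguishes TOL from both non-TOL and control; likewise
#' for non-TOL. Matching is by probe id; the reported direction comes from
#' the vs-control list, with a flag when it disagrees with the two-group
#' direction.
#'
#' @param two_group \code{\link{gene_list}} from the TOL vs non-TOL SAM run.
#' @param unique_tol,unique_ntol unique lists from
#'   \code{\link{derive_unique_lists}}.
#' @param tol_vs_ctrl,ntol_vs_ctrl optionally, the original vs-control
#'   lists (stored for reporting).
#' @return object of class \code{filter_result}: list with the input lists,
#'   \code{shared} (when derivable), \code{final_tol}, \code{final_ntol},
#'   and \code{direction_conflicts} (probe ids whose two-group and
#'   vs-control directions disagree).
#' @export
derive_final_lists <- function(two_group, unique_tol, unique_ntol,
                               tol_vs_ctrl = NULL, ntol_vs_ctrl = NULL) {
  final_of <- function(unique_list, lab) {
    hit <- unique_list$probe_id %in% two_group$probe_id
    gene_list(unique_list$probe_id[hit], unique_list$direction[hit], lab)
  }
  final_tol <- final_of(unique_tol, "final TOL")
  final_ntol <- final_of(unique_ntol, "final non-TOL")
  tg_dir <- setNames(two_group$direction, two_group$probe_id)
  conflicts <- c(
    final_tol$probe_id[final_tol$direction != tg_dir[final_tol$probe_id]],
    # two-group is TOL-vs-NONTOL, so a probe non-TOL-unique 'up' should be
    # 'down' in the two-group contrast
    final_ntol$probe_id[final_ntol$direction == tg_dir[final_ntol$probe_id]])
  structure(list(two_group = two_group, tol_vs_ctrl = tol_vs_ctrl,
                 ntol_vs_ctrl = ntol_vs_ctrl,
                 unique_tol = unique_tol, unique_ntol = unique_ntol,
                 final_tol = final_tol, final_ntol = final_ntol,
                 direction_conflicts = conflicts),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  n <- function(gl) if (is.null(gl)) NA_integer_ else nrow(gl)
  cat("Three-group confound filter\n")
  cat(sprintf("  two-group (TOL vs non-TOL): %d\n", n(x$two_group)))
  cat(sprintf("  unique TOL vs ctrl: %d   unique non-TOL vs ctrl: %d\n",
              n(x$unique_tol), n(x$unique_ntol)))
  cat(sprintf("  final TOL: %d   final non-TOL: %d   (direction conflicts: %d)\n",
              n(x$final_tol), n(x$final_ntol), length(x$direction_conflicts)))
  invisible(x)
}

#' Run the whole three-group filter from a matrix
#'
#' Convenience wrapper: runs SAM for TOL vs non-TOL, TOL vs control and
#' non-TOL vs control, then applies \code{\link{derive_unique_lists}} and
#' \code{\link{derive_final_lists}}.
#'
#' @param x log2 expression matrix.
#' @param annotation sample annotation with \code{group}.
#' @param cfg a \code{\link{sam_config}}.
#' @return a \code{filter_result}; the three \code{sam_fit}s are attached
#'   as the \code{fits} attribute.
#' @export
three_group_filter <- function(x, annotation, cfg = sam_config()) {
  sub_fit <- function(g1, g2) {
    keep <- annotation$group %in% c(g1, g2)
    run_sam(x[, annotation$sample_id[keep], drop = FALSE],
            factor(annotation$group[keep], levels = c(g1, g2)), cfg)
  }
  fit_tn <- sub_fit("TOL", "NONTOL")
  fit_tc <- sub_fit("TOL", "CTRL")
  fit_nc <- sub_fit("NONTOL", "CTRL")
  u <- derive_unique_lists(fit_tc$called, fit_nc$called)
  res <- derive_final_lists(fit_tn$called, u$unique_tol, u$unique_ntol,
                            fit_tc$called, fit_nc$called)
  res$shared <- u$shared
  attr(res, "fits") <- list(two_group = fit_tn, tol_vs_ctrl = fit_tc,
                            ntol_vs_ctrl = fit_nc)
  res
}

#' Check for confounding by individual immunosuppressant agents
#'
#' For each IS agent, runs SAM on exposed versus unexposed non-TOL samples
#' and intersects the resulting gene list with the phenotype list. An empty
#' overlap for every agent indicates the phenotype signature is not
#' explained by the presence or type of IS. Agents without at least 2
#' exposed and 2 unexposed samples are skipped with a warning.
#'
#' @param x log2 expression matrix.
#' @param annotation sample annotation with \code{group} and \code{agents}.
#' @param phenotype_list \code{\link{gene_list}} to test against.
#' @param cfg a \code{\link{sam_config}}.
#' @return named list per agent: \code{agent_list_size}, \code{overlap},
#'   \code{overlap_ids} (skipped agents are absent).
#' @export
agent_confound_check <- function(x, annotation, phenotype_list,
                                 cfg = sam_config()) {
  ntol <- annotation[annotation$group == "NONTOL", ]
  agents <- unique(unlist(strsplit(ntol$agents[ntol$agents != ""], ";")))
  out <- list()
  for (ag in agents) {
    exposed <- vapply(strsplit(ntol$agents, ";"), function(a) ag %in% a,
                      logical(1))
    if (sum(exposed) < 2 || sum(!exposed) < 2) {
      warning("agent '", ag, "' skipped: needs >= 2 exposed and 2 unexposed")
      next
    }
    lab <- factor(ifelse(exposed, "exposed", "unexposed"),
                  levels = c("exposed", "unexposed"))
    fit <- run_sam(x[, ntol$sample_id, drop = FALSE], lab, cfg)
    ov <- intersect(fit$called$probe_id, phenotype_list$probe_id)
    out[[ag]] <- list(agent_list_size = nrow(fit$called),
                      overlap = length(ov), overlap_ids = ov)
  }
  out
}

#' Matched-pair secondary analysis
#'
#' Per probe, forms log2 ratios (TOL minus non-TOL) across matched pairs
#' and calls a probe when the two-sided Wilcoxon signed-rank p-value is
#' below \code{alpha} and the geometric-mean ratio is at least
#' \code{min_fold}; direction follows the sign of the median ratio. Serves
#' as a heterogeneity check against the group-wise SAM analysis.
#'
#' @param x log2 expression matrix.
#' @param annotation sample annotation with complete \code{pair_id}s.
#' @param min_fold natural-scale fold floor (default 1.5).
#' @param alpha signed-rank significance level (default 0.05).
#' @param adjust p-value adjustment across probes: \code{"none"} (default,
#'   matching a fixed per-probe threshold) or \code{"BH"}.
#' @return a \code{\link{gene_list}} of called probes.
#' @export
paired_analysis <- function(x, annotation, min_fold = 1.5, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ann <- annotation[!is.na(annotation$pair_id), ]
  pairs <- split(ann, ann$pair_id)
  ok <- vapply(pairs, function(p)
    nrow(p) == 2 && setequal(p$group, c("TOL", "NONTOL")), logical(1))
  if (!all(ok)) stop("every pair_id must link exactly one TOL and one NONTOL sample")
  if (length(pairs) < 5) stop("need >= 5 complete pairs")
  ratio <- vapply(pairs, function(p) {
    x[, p$sample_id[p$group == "TOL"]] - x[, p$sample_id[p$group == "NONTOL"]]
  }, numeric(nrow(x)))
  p <- apply(ratio, 1, function(r) {
    if (all(r == 0)) return(1)
    suppressWarnings(wilcox.test(r, mu = 0, exact = TRUE)$p.value)
  })
  if (adjust == "BH") p <- p.adjust(p, "BH")
  med <- apply(ratio, 1, median)
  gm_fold <- 2^abs(rowMeans(ratio))
  hit <- p < alpha & gm_fold >= min_fold
  gene_list(rownames(x)[hit], ifelse(med[hit] >= 0, "up", "down"),
            label = "matched-pair TOL vs non-TOL")
}

#' Directional concordance between two gene lists
#'
#' Fraction of entries of \code{a} whose probe id appears in \code{b} with
#' the same direction.
#'
#' @param a,b \code{\link{gene_list}}s; \code{a} must be non-empty.
#' @return a fraction in [0, 1].
#' @export
concordance <- function(a, b) {
  if (nrow(a) == 0) stop("list 'a' must be non-empty")
  mean(.gl_key(a) %in% .gl_key(b))
}
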