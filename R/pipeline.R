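#' Run the full tolerance-signature pipeline
#'
#' Sequences every stage of the analysis on one cohort: the two-group SAM
#' comparison (TOL vs non-TOL), both vs-control SAM comparisons, the
#' three-group confound filter, the per-agent IS confounding check,
#' gene-set enrichment (GSEA on the supplied sets against the TOL vs
#' non-TOL ranking, plus hypergeometric over-representation of the final
#' TOL list), and the cross-validated classifier. Writes all result tables
#' plus a JSON manifest recording every cardinality, parameter and seed;
#' the manifest carries no timestamps, so identical inputs and seeds
#' reproduce it byte for byte.
#'
#' @param x log2 expression matrix (probes x samples), or a GCT path.
#' @param annotation sample annotation data.frame, or a TSV path.
#' @param sets named list of gene sets (or GMT path); \code{NULL} skips
#'   enrichment.
#' @param sam_cfg a \code{\link{sam_config}}.
#' @param cv_cfg a \code{\link{cv_config}}.
#' @param gsea_n_perm permutations for GSEA.
#' @param out_dir output directory (created if missing); \code{NULL} skips
#'   file output.
#' @param seed global seed, propagated to every stochastic stage.
#' @return list with components \code{filter} (a \code{filter_result}),
#'   \code{agent_check}, \code{gsea}, \code{ora}, \code{cv}
#'   (a \code{cv_report}) and \code{manifest} (the named list written as
#'   JSON).
#' @export
run_pipeline <- function(x, annotation, sets = NULL,
                         sam_cfg = sam_config(), cv_cfg = cv_config(),
                         gsea_n_perm = 1000, out_dir = NULL, seed = 1L) {
  if (is.character(x)) x <- read_gct(x)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (is.character(sets)) sets <- read_gmt(sets)
  if (!setequal(colnames(x), annotation$sample_id))
    stop("matrix columns and annotation sample_ids must match")
  x <- x[, annotation$sample_id, drop = FALSE]
  seed <- as.integer(seed)
  sam_cfg$seed <- seed
  cv_cfg$seed <- seed
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, writer) if (!is.null(out_dir))
    writer(file.path(out_dir, name))

  stage <- "three_group_filter"
  res <- tryCatch({
    filter <- three_group_filter(x, annotation, sam_cfg)
    emit("final_tol.tsv", function(p) write_lists(filter$final_tol, p))
    emit("final_ntol.tsv", function(p) write_lists(filter$final_ntol, p))
    emit("two_group.tsv", function(p) write_lists(filter$two_group, p))

    stage <- "agent_confound_check"
    agent_check <- if (any(annotation$agents != ""))
      agent_confound_check(x, annotation, filter$two_group, sam_cfg)
    else list()

    stage <- "enrichment"
    gsea <- ora <- NULL
    if (!is.null(sets) && length(sets)) {
      pat <- annotation$group %in% c("TOL", "NONTOL")
      gsea <- gsea_test(x[, annotation$sample_id[pat], drop = FALSE],
                        factor(annotation$group[pat],
                               levels = c("TOL", "NONTOL")),
                        sets, n_perm = gsea_n_perm, seed = seed)
      emit("gsea.tsv", function(p) write.table(as.data.frame(gsea), p,
                                               sep = "\t", quote = FALSE,
                                               row.names = FALSE))
      if (nrow(filter$final_tol) > 0) {
        ora <- ora_test(filter$final_tol, sets, rownames(x))
        emit("ora.tsv", function(p) write.table(as.data.frame(ora), p,
                                                sep = "\t", quote = FALSE,
                                                row.names = FALSE))
      }
    }

    stage <- "classification"
    cv <- cross_validate(x, annotation, cv_cfg)
    emit("roc.tsv", function(p) write.table(cv$roc, p, sep = "\t",
                                            quote = FALSE, row.names = FALSE))
    emit("stability.tsv", function(p)
      write.table(feature_stability(cv, min_count = 0), p, sep = "\t",
                  quote = FALSE, row.names = FALSE))

    list(filter = filter, agent_check = agent_check, gsea = gsea,
         ora = ora, cv = cv)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    seed = seed,
    n_probes = nrow(x),
    n_samples = unclass(table(annotation$group))[.GROUPS],
    sam = list(n_perm = sam_cfg$n_perm, target_fdr = sam_cfg$target_fdr,
               min_fold = sam_cfg$min_fold,
               fdr_summary = sam_cfg$fdr_summary),
    counts = list(
      two_group = nrow(res$filter$two_group),
      tol_vs_ctrl = nrow(res$filter$tol_vs_ctrl),
      ntol_vs_ctrl = nrow(res$filter$ntol_vs_ctrl),
      shared = if (!is.null(res$filter$shared)) nrow(res$filter$shared) else 0L,
      unique_tol = nrow(res$filter$unique_tol),
      unique_ntol = nrow(res$filter$unique_ntol),
      final_tol = nrow(res$filter$final_tol),
      final_ntol = nrow(res$filter$final_ntol)),
    agent_overlap = lapply(res$agent_check, function(a)
      list(agent_list_size = a$agent_list_size, overlap = a$overlap)),
    gsea = if (!is.null(res$gsea))
      lapply(seq_len(nrow(res$gsea)), function(i)
        as.list(as.data.frame(res$gsea)[i, ])),
    classifier = list(
      n_folds = cv_cfg$n_folds, k_features = cv_cfg$k_features,
      selector = cv_cfg$selector,
      confusion = as.list(setNames(as.vector(res$cv$confusion),
                                   c("tol_tol", "ntol_tol", "tol_ntol",
                                     "ntol_ntol"))),
      weighted_accuracy = res$cv$weighted_accuracy,
      balanced_accuracy = res$cv$balanced_accuracy,
      auc = res$cv$auc, auc_ci = res$cv$auc_ci))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(res, list(manifest = manifest))
}
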