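#' Simulation configuration for synthetic expression cohorts
#'
#' Describes a synthetic cross-sectional cohort with three phenotype groups
#' (tolerant \code{TOL}, non-tolerant \code{NONTOL}, healthy \code{CTRL}) and
#' planted probe categories: TOL-unique and non-TOL-unique differential
#' probes (per direction), probes confounded by immunosuppression (shifted
#' unidirectionally in \emph{both} patient groups versus control),
#' optional probes linked to individual immunosuppressant (IS) agents, and
#' lineage-tagged probe sets for enrichment tests.
#'
#' Defaults mirror the study design the package targets: 15 TOL / 17 non-TOL
#' / 10 control samples, a planted log2 effect of 1.0 (2-fold, comfortably
#' above the 1.5-fold detectability floor used in the analysis), and
#' heteroscedastic per-probe Gaussian noise with standard deviation drawn
#' uniformly from \code{sd_range}.
#'
#' @param n_probes total number of probe sets.
#' @param group_sizes named integer vector with elements \code{TOL},
#'   \code{NONTOL}, \code{CTRL}; each must be at least 2.
#' @param n_tol_up,n_tol_down planted TOL-unique probes per direction.
#' @param n_ntol_up,n_ntol_down planted non-TOL-unique probes per direction.
#' @param n_confounded probes shifted with the same sign in both patient
#'   groups versus control (split evenly between up and down).
#' @param effect_log2 planted mean shift in log2 units.
#' @param sd_range length-2 vector; per-probe noise sd drawn uniformly
#'   from this interval (lower bound must be positive).
#' @param lineage_sets named integer vector mapping lineage set name to size;
#'   lineage tags are placed on otherwise-null probes.
#' @param lineage_effect_log2 coherent shift of lineage-tagged probes in the
#'   TOL group (0 = lineage sets carry no signal).
#' @param agent_names character vector of IS agent labels assigned to
#'   non-TOL samples (tolerant patients are off all IS by definition).
#' @param n_agent_probes planted probes linked to each agent.
#' @param agent_effect_log2 shift of agent-linked probes in exposed samples.
#' @param pairing if \code{TRUE}, match each TOL sample to one non-TOL
#'   sample via a shared \code{pair_id}.
#' @param seed integer seed; fixed seed gives bitwise-identical output.
#' @return an object of class \code{sim_config} (a validated list).
#' @seealso \code{\link{generate_dataset}}
#' @export
sim_config <- function(n_probes = 2000,
                       group_sizes = c(TOL = 15, NONTOL = 17, CTRL = 10),
                       n_tol_up = 50, n_tol_down = 50,
                       n_ntol_up = 30, n_ntol_down = 30,
                       n_confounded = 100,
                       effect_log2 = 1.0,
                       sd_range = c(0.2, 0.6),
                       lineage_sets = c(CD4 = 50, CD8 = 50, CD14 = 50,
                                        CD19 = 50, CD56 = 50, CD66 = 50),
                       lineage_effect_log2 = 0,
                       agent_names = c("CNI", "MMF", "steroid", "sirolimus"),
                       n_agent_probes = 0,
                       agent_effect_log2 = 0,
                       pairing = FALSE,
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes),
              group_sizes = group_sizes,
              n_tol_up = as.integer(n_tol_up),
              n_tol_down = as.integer(n_tol_down),
              n_ntol_up = as.integer(n_ntol_up),
              n_ntol_down = as.integer(n_ntol_down),
              n_confounded = as.integer(n_confounded),
              effect_log2 = effect_log2,
              sd_range = sd_range,
              lineage_sets = lineage_sets,
              lineage_effect_log2 = lineage_effect_log2,
              agent_names = agent_names,
              n_agent_probes = as.integer(n_agent_probes),
              agent_effect_log2 = agent_effect_log2,
              pairing = isTRUE(pairing),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_probes, cfg$n_tol_up, cfg$n_tol_down, cfg$n_ntol_up,
              cfg$n_ntol_down, cfg$n_confounded, cfg$n_agent_probes)
  if (any(counts < 0)) stop("all probe counts must be >= 0")
  gs <- cfg$group_sizes
  if (!all(.GROUPS %in% names(gs)))
    stop("group_sizes must name TOL, NONTOL and CTRL")
  if (any(gs[.GROUPS] < 2)) stop("each group needs at least 2 samples")
  n_planted <- cfg$n_tol_up + cfg$n_tol_down + cfg$n_ntol_up +
    cfg$n_ntol_down + cfg$n_confounded +
    cfg$n_agent_probes * length(cfg$agent_names) * (cfg$n_agent_probes > 0)
  if (n_planted + sum(cfg$lineage_sets) > cfg$n_probes)
    stop("planted categories (incl. lineage sets) exceed n_probes; ",
         "categories must be disjoint")
  if (length(cfg$sd_range) != 2 || cfg$sd_range[1] <= 0 ||
      diff(cfg$sd_range) < 0)
    stop("sd_range must be (lo, hi) with lo > 0 and hi >= lo")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  probes: %d   samples: TOL %d / NONTOL %d / CTRL %d\n",
              x$n_probes, x$group_sizes[["TOL"]], x$group_sizes[["NONTOL"]],
              x$group_sizes[["CTRL"]]))
  cat(sprintf("  planted: TOL %d up / %d down, non-TOL %d up / %d down, confounded %d\n",
              x$n_tol_up, x$n_tol_down, x$n_ntol_up, x$n_ntol_down,
              x$n_confounded))
  cat(sprintf("  effect %.2f log2, noise sd U(%.2f, %.2f), seed %d\n",
              x$effect_log2, x$sd_range[1], x$sd_range[2], x$seed))
  invisible(x)
}

#' Generate a synthetic probe-set expression cohort with planted truth
#'
#' Draws a log2-scale expression matrix (probe sets x samples) under an
#' additive model: per-probe baseline ~ Uniform(4, 12) mimicking microarray
#' dynamic range, planted group-mean shifts of \code{effect_log2} in the
#' configured directions, and independent Gaussian noise with per-probe sd
#' drawn from \code{sd_range}. Confounded probes receive the same-signed
#' shift in both patient groups versus control, emulating
#' immunosuppression-driven expression that the three-group filter must
#' remove. Optional agent-linked probes are shifted only in non-TOL samples
#' exposed to that agent.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list with components
#'   \describe{
#'     \item{x}{numeric matrix, probes x samples, log2 scale, dimnames set.}
#'     \item{annotation}{data.frame with \code{sample_id}, \code{group},
#'       \code{pair_id} (NA when unpaired) and \code{agents}
#'       (\code{";"}-separated labels, empty for TOL and CTRL samples).}
#'     \item{truth}{data.frame with \code{probe_id}, \code{category} (one of
#'       TOL_UP, TOL_DOWN, NTOL_UP, NTOL_DOWN, CONFOUNDED_UP,
#'       CONFOUNDED_DOWN, AGENT:<name>, NULL), \code{lineage} (set name or
#'       NA) and \code{effect_log2} (0 for null probes).}
#'   }
#' @examples
#' d <- generate_dataset(sim_config(n_probes = 200, seed = 7))
#' dim(d$x)
#' table(d$truth$category)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_probes
  gs <- config$group_sizes
  probe_ids <- sprintf("probe_%04d", seq_len(n))
  sample_ids <- c(sprintf("TOL_%02d", seq_len(gs[["TOL"]])),
                  sprintf("NTOL_%02d", seq_len(gs[["NONTOL"]])),
                  sprintf("CTRL_%02d", seq_len(gs[["CTRL"]])))
  group <- rep(.GROUPS, times = gs[.GROUPS])

  # assign disjoint planted categories
  category <- rep("NULL", n)
  lineage <- rep(NA_character_, n)
  effect <- rep(0, n)
  pool <- seq_len(n)
  take <- function(k) {
    idx <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    idx
  }
  pool <- sample(pool)   # randomize placement
  plant <- list(TOL_UP = config$n_tol_up, TOL_DOWN = config$n_tol_down,
                NTOL_UP = config$n_ntol_up, NTOL_DOWN = config$n_ntol_down,
                CONFOUNDED_UP = ceiling(config$n_confounded / 2),
                CONFOUNDED_DOWN = floor(config$n_confounded / 2))
  for (cat_name in names(plant)) {
    if (plant[[cat_name]] > 0) {
      idx <- take(plant[[cat_name]])
      category[idx] <- cat_name
      effect[idx] <- config$effect_log2 *
        (if (grepl("DOWN$", cat_name)) -1 else 1)
    }
  }
  if (config$n_agent_probes > 0) {
    for (ag in config$agent_names) {
      idx <- take(config$n_agent_probes)
      category[idx] <- paste0("AGENT:", ag)
      effect[idx] <- config$agent_effect_log2
    }
  }
  for (ls in names(config$lineage_sets)) {
    k <- config$lineage_sets[[ls]]
    if (k > 0) {
      idx <- take(k)
      lineage[idx] <- ls
      if (config$lineage_effect_log2 != 0)
        effect[idx] <- config$lineage_effect_log2
    }
  }

  # agent exposure among non-TOL samples: exactly half exposed per agent so
  # the exposed/unexposed contrast is always testable
  agents <- rep("", length(sample_ids))
  ntol_idx <- which(group == "NONTOL")
  exposure <- list()
  for (ag in config$agent_names) {
    exposed <- sort(sample(ntol_idx, floor(length(ntol_idx) / 2)))
    exposure[[ag]] <- exposed
    agents[exposed] <- ifelse(agents[exposed] == "", ag,
                              paste(agents[exposed], ag, sep = ";"))
  }

  baseline <- runif(n, 4, 12)
  sds <- runif(n, config$sd_range[1], config$sd_range[2])
  mu <- matrix(baseline, n, length(sample_ids))
  is_tol <- group == "TOL"
  is_ntol <- group == "NONTOL"
  for (i in which(category %in% c("TOL_UP", "TOL_DOWN")))
    mu[i, is_tol] <- mu[i, is_tol] + effect[i]
  for (i in which(category %in% c("NTOL_UP", "NTOL_DOWN")))
    mu[i, is_ntol] <- mu[i, is_ntol] + effect[i]
  for (i in which(category %in% c("CONFOUNDED_UP", "CONFOUNDED_DOWN")))
    mu[i, is_tol | is_ntol] <- mu[i, is_tol | is_ntol] + effect[i]
  for (ag in config$agent_names) {
    rows <- which(category == paste0("AGENT:", ag))
    if (length(rows))
      mu[rows, exposure[[ag]]] <- mu[rows, exposure[[ag]]] +
        config$agent_effect_log2
  }
  if (config$lineage_effect_log2 != 0)
    for (i in which(!is.na(lineage)))
      mu[i, is_tol] <- mu[i, is_tol] + config$lineage_effect_log2

  noise <- matrix(rnorm(n * length(sample_ids), sd = rep(sds, length(sample_ids))),
                  n, length(sample_ids))
  x <- mu + noise
  dimnames(x) <- list(probe_ids, sample_ids)

  pair_id <- rep(NA_character_, length(sample_ids))
  if (config$pairing) {
    n_pairs <- min(gs[["TOL"]], gs[["NONTOL"]])
    tol_pick <- which(is_tol)[seq_len(n_pairs)]
    ntol_pick <- sample(which(is_ntol))[seq_len(n_pairs)]
    pid <- sprintf("pair_%02d", seq_len(n_pairs))
    pair_id[tol_pick] <- pid
    pair_id[ntol_pick] <- pid
  }

  annotation <- data.frame(sample_id = sample_ids, group = group,
                           pair_id = pair_id, agents = agents,
                           stringsAsFactors = FALSE)
  truth <- data.frame(probe_id = probe_ids, category = category,
                      lineage = lineage, effect_log2 = effect,
                      stringsAsFactors = FALSE)
  list(x = x, annotation = annotation, truth = truth)
}

#' Generate probe-level intensities for preprocessing fixtures
#'
#' Builds natural-scale probe-level intensities under the RMA additive
#' model: \code{intensity = 2^(true log2 signal + probe affinity + noise)}.
#' Probe affinities are drawn once per probe and held fixed across arrays,
#' exactly the structure median polish is designed to remove. With
#' \code{noise_sd = 0} and \code{affinity_sd = 0} the median-polish summary
#' recovers the true signal exactly.
#'
#' @param config a \code{\link{sim_config}}; its planted structure defines
#'   the true probe-set-level log2 signal.
#' @param probes_per_set member probes per probe set (>= 2).
#' @param affinity_sd sd of fixed per-probe affinity offsets (default 1).
#' @param noise_sd probe-level noise sd; \code{NULL} draws one per probe set
#'   from \code{config$sd_range}; 0 gives noiseless fixtures.
#' @return a list with \code{probe_set_id}, \code{probe_id} (parallel
#'   vectors), \code{intensities} (positive matrix, probes x arrays),
#'   \code{sample_ids}, \code{annotation}, \code{truth}, and
#'   \code{true_signal} (the probe-set x array log2 matrix the summaries
#'   should recover up to a per-set constant).
#' @export
generate_probe_level <- function(config, probes_per_set = 4,
                                 affinity_sd = 1, noise_sd = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (probes_per_set < 2) stop("probes_per_set must be >= 2")
  d <- generate_dataset(config)
  # true signal = noiseless group means (regenerate means without noise)
  set.seed(config$seed + 1L)
  n <- config$n_probes
  n_arr <- ncol(d$x)
  # use the realized per-set log2 values as the true signal so downstream
  # stages see the same cohort
  signal <- d$x
  aff <- rnorm(n * probes_per_set, sd = affinity_sd)
  if (is.null(noise_sd))
    noise_sd_set <- runif(n, config$sd_range[1], config$sd_range[2])
  else
    noise_sd_set <- rep(noise_sd, n)
  probe_set_id <- rep(rownames(signal), each = probes_per_set)
  probe_id <- paste0(probe_set_id, "_p", rep(seq_len(probes_per_set), n))
  log2_int <- signal[rep(seq_len(n), each = probes_per_set), , drop = FALSE] +
    matrix(aff, n * probes_per_set, n_arr) +
    matrix(rnorm(n * probes_per_set * n_arr,
                 sd = rep(rep(noise_sd_set, each = probes_per_set), n_arr)),
           n * probes_per_set, n_arr)
  intensities <- 2^log2_int
  rownames(intensities) <- probe_id
  colnames(intensities) <- colnames(signal)
  structure(list(probe_set_id = probe_set_id, probe_id = probe_id,
                 intensities = intensities, sample_ids = colnames(signal),
                 annotation = d$annotation, truth = d$truth,
                 true_signal = signal),
            class = "probe_level_set")
}

#' Permute phenotype labels within a scope
#'
#' Utility for building permutation-null cohorts: shuffles the \code{group}
#' column of a sample annotation among the samples in scope while leaving
#' pair and agent fields untouched. The multiset of labels is conserved.
#'
#' @param annotation a sample annotation data.frame (see
#'   \code{\link{generate_dataset}}).
#' @param scope \code{"patients_only"} permutes labels among TOL/NONTOL
#'   samples; \code{"all"} permutes among all samples.
#' @param seed integer seed.
#' @return the annotation with permuted \code{group}.
#' @export
permute_group_labels <- function(annotation, scope = c("patients_only", "all"),
                                 seed = 1L) {
  scope <- match.arg(scope)
  idx <- if (scope == "patients_only")
    which(annotation$group %in% c("TOL", "NONTOL"))
  else seq_len(nrow(annotation))
  if (length(idx) < 2) stop("need at least 2 samples in scope")
  set.seed(as.integer(seed))
  annotation$group[idx] <- annotation$group[sample(idx)]
  annotation
}
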