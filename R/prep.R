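#' Preprocessing configuration
#'
#' Settings for the three RMA-style steps: background adjustment, quantile
#' normalization and median-polish summarization.
#'
#' @param background \code{"none"} or \code{"shift"} (subtract the per-array
#'   \code{q}-quantile, then floor at \code{epsilon} to keep intensities
#'   positive). The full RMA normal+exponential convolution model is out of
#'   scope; the quantile shift is an explicit extension point.
#' @param q background quantile in [0, 1).
#' @param epsilon positive floor applied after background subtraction.
#' @param polish_max_iter,polish_tol median-polish stopping rule: iterate
#'   until the maximum absolute change is below \code{polish_tol} or
#'   \code{polish_max_iter} sweeps.
#' @return an object of class \code{prep_config}.
#' @export
prep_config <- function(background = c("none", "shift"), q = 0.05,
                        epsilon = 0.5, polish_max_iter = 20L,
                        polish_tol = 1e-8) {
  background <- match.arg(background)
  if (q < 0 || q >= 1) stop("background quantile q must be in [0, 1)")
  if (polish_max_iter < 1) stop("polish_max_iter must be >= 1")
  if (polish_tol <= 0) stop("polish_tol must be > 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(background = background, q = q, epsilon = epsilon,
                 polish_max_iter = as.integer(polish_max_iter),
                 polish_tol = polish_tol),
            class = "prep_config")
}

#' Background-adjust probe-level intensities
#'
#' Per array, subtracts the \code{q}-quantile of that array's intensities
#' and floors the result at \code{epsilon} so intensities stay positive.
#' With \code{background = "none"} the input is returned unchanged.
#'
#' @param data a probe-level set from \code{\link{generate_probe_level}} or
#'   \code{\link{read_probe_level}}.
#' @param cfg a \code{\link{prep_config}}.
#' @return the probe-level set with adjusted intensities.
#' @export
background_adjust <- function(data, cfg = prep_config()) {
  stopifnot(inherits(data, "probe_level_set"), inherits(cfg, "prep_config"))
  if (any(data$intensities <= 0)) stop("intensities must be positive")
  if (cfg$background == "none") return(data)
  bg <- apply(data$intensities, 2, quantile, probs = cfg$q, names = FALSE)
  adj <- sweep(data$intensities, 2, bg, "-")
  data$intensities <- pmax(adj, cfg$epsilon)
  data
}

#' Quantile-normalize an intensity matrix
#'
#' Forces every column (array) onto the same empirical distribution: the
#' row-wise mean of the column-sorted input. Ties within a column receive
#' the mean of the target values their tied ranks map to, so the operation
#' is well defined and idempotent.
#'
#' @param values numeric matrix, probes x arrays, at least 2 columns.
#' @return matrix of the same shape with identical column distributions.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(values) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (ncol(values) < 2) stop("quantile normalization needs >= 2 arrays")
  if (any(!is.finite(values))) stop("values must be finite")
  target <- rowMeans(apply(values, 2, sort))
  out <- values
  for (j in seq_len(ncol(values))) {
    res <- numeric(nrow(values))
    res[order(values[, j])] <- target
    # tied inputs all get the mean of the target values their ranks span
    out[, j] <- stats::ave(res, values[, j], FUN = mean)
  }
  dimnames(out) <- dimnames(values)
  out
}

# median polish of one probe set's log2 matrix (probes x arrays);
# returns per-array summaries mu + array effect
polish_one <- function(m, cfg) {
  fit <- medpolish(m, eps = cfg$polish_tol, maxiter = cfg$polish_max_iter,
                   trace.iter = FALSE)
  fit$overall + fit$col
}

#' Summarize probe sets by median polish
#'
#' Log2-transforms member-probe intensities and fits the additive model
#' \code{log2(I) = mu + probe effect + array effect} per probe set by
#' alternating median sweeps (rows first, then columns). The probe-set
#' summary for each array is \code{mu + array effect}; the fixed per-probe
#' affinities absorb into the probe effects and drop out.
#'
#' @param data a probe-level set (optionally background-adjusted and
#'   quantile-normalized via \code{\link{preprocess}}).
#' @param cfg a \code{\link{prep_config}}.
#' @return numeric matrix of log2 summaries, probe sets x arrays.
#' @export
median_polish_summarize <- function(data, cfg = prep_config()) {
  stopifnot(inherits(data, "probe_level_set"))
  if (any(data$intensities <= 0)) stop("intensities must be positive")
  sets <- unique(data$probe_set_id)
  l2 <- log2(data$intensities)
  out <- matrix(NA_real_, length(sets), ncol(l2),
                dimnames = list(sets, colnames(l2)))
  idx_by_set <- split(seq_along(data$probe_set_id), data$probe_set_id)
  for (s in sets) {
    rows <- idx_by_set[[s]]
    if (length(rows) < 2)
      stop("probe set '", s, "' has < 2 member probes")
    out[s, ] <- polish_one(l2[rows, , drop = FALSE], cfg)
  }
  out
}

#' Run the full RMA-style preprocessing chain
#'
#' Background adjustment, quantile normalization of probe-level intensities,
#' then median-polish summarization to a log2 probe-set matrix.
#'
#' @inheritParams median_polish_summarize
#' @return log2 expression matrix, probe sets x arrays.
#' @export
preprocess <- function(data, cfg = prep_config()) {
  data <- background_adjust(data, cfg)
  data$intensities <- quantile_normalize(data$intensities)
  median_polish_summarize(data, cfg)
}
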