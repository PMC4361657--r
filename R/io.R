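#' Read and write GCT 1.2 expression matrices
#'
#' GCT 1.2: a \code{#1.2} version line, a dimensions line
#' (\code{n_rows<TAB>n_cols}), then a header row
#' (\code{NAME, Description, <sample ids>}) and one row per probe. Values
#' round-trip at full double precision.
#'
#' @param path file path.
#' @return \code{read_gct}: numeric matrix with probe row names and sample
#'   column names.
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "#1.2")
    stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
  dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
  tab <- read.delim(text = lines[-(1:2)], check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tab) != dims[1] || ncol(tab) - 2L != dims[2])
    stop(sprintf("GCT dimension mismatch: header says %d x %d, found %d x %d",
                 dims[1], dims[2], nrow(tab), ncol(tab) - 2L))
  if (anyDuplicated(tab[[1]])) stop("duplicate probe ids in GCT: ", path)
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  if (any(is.na(m))) stop("missing values are not allowed in GCT matrices")
  rownames(m) <- tab[[1]]
  m
}

#' @param x numeric matrix with dimnames.
#' @param description optional per-probe description column.
#' @rdname read_gct
#' @export
write_gct <- function(x, path, description = NULL) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  desc <- description %||% rownames(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
  writeLines(paste(c("NAME", "Description", colnames(x)), collapse = "\t"),
             con)
  body <- apply(format(x, digits = 17, trim = TRUE, scientific = FALSE), 1,
                paste, collapse = "\t")
  writeLines(paste(rownames(x), desc, body, sep = "\t"), con)
  invisible(path)
}

#' Read and write CLS phenotype files
#'
#' Space-delimited CLS: first line \code{n_samples n_classes 1}, second
#' line \code{#} followed by class names in order, third line one label per
#' sample. Supports the three-class TOL/NONTOL/CTRL extension.
#'
#' @param path file path.
#' @return \code{read_cls}: list with \code{labels} (character vector) and
#'   \code{classes} (declared order).
#' @export
read_cls <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("CLS file must have 3 lines: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  classes <- strsplit(trimws(lines[2]), "\\s+")[[1]][-1]
  labels <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(labels) != hdr[1])
    stop(sprintf("CLS declares %d samples but lists %d labels", hdr[1],
                 length(labels)))
  if (length(classes) != hdr[2])
    stop(sprintf("CLS declares %d classes but names %d", hdr[2],
                 length(classes)))
  # numeric CLS encodes labels as class indices
  if (all(grepl("^[0-9]+$", labels))) labels <- classes[as.integer(labels) + 1]
  if (!all(labels %in% classes)) stop("CLS labels outside declared classes")
  list(labels = labels, classes = classes)
}

#' @param labels character vector of per-sample labels.
#' @param classes class order; defaults to order of first appearance.
#' @rdname read_cls
#' @export
write_cls <- function(labels, path, classes = unique(labels)) {
  writeLines(c(paste(length(labels), length(classes), "1"),
               paste(c("#", classes), collapse = " "),
               paste(labels, collapse = " ")), path)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' Tab-delimited GMT: one set per line — name, description, then member
#' ids. Set names must be unique and sets non-empty.
#'
#' @param path file path.
#' @return \code{read_gmt}: named list of member-id vectors, with a
#'   \code{description} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines[nzchar(lines)], "\t")
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("GMT lines need name, description and >= 1 member")
  nms <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nms)) stop("duplicate set names in GMT: ", path)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nms
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' @param sets named list of member-id vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Read and write directional gene lists
#'
#' Two-column TSV with header \code{probe_id<TAB>direction}.
#'
#' @param path file path.
#' @return \code{read_lists}: a \code{\link{gene_list}}.
#' @export
read_lists <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  gene_list(tab$probe_id, tab$direction)
}

#' @param gl a \code{\link{gene_list}}.
#' @rdname read_lists
#' @export
write_lists <- function(gl, path) {
  write.table(as.data.frame(gl), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read and write sample annotations
#'
#' TSV sidecar with columns \code{sample_id}, \code{group}, \code{pair_id},
#' \code{agents}.
#'
#' @param path file path.
#' @export
read_annotation <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("sample_id", "group", "pair_id", "agents")
  if (!all(need %in% names(tab)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  tab$agents[is.na(tab$agents)] <- ""
  tab[need]
}

#' @param annotation annotation data.frame.
#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probe-level intensities from TSV
#'
#' Expects columns \code{probe_set_id}, \code{probe_id}, then one column
#' per array with positive natural-scale intensities.
#'
#' @param path file path.
#' @return a \code{probe_level_set}.
#' @export
read_probe_level <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("probe_set_id", "probe_id") %in% names(tab)))
    stop("probe-level TSV needs probe_set_id and probe_id columns")
  m <- as.matrix(tab[, !(names(tab) %in% c("probe_set_id", "probe_id")),
                     drop = FALSE])
  rownames(m) <- tab$probe_id
  if (any(m <= 0)) stop("probe-level intensities must be positive")
  structure(list(probe_set_id = tab$probe_set_id, probe_id = tab$probe_id,
                 intensities = m, sample_ids = colnames(m)),
            class = "probe_level_set")
}

#' @param data a \code{probe_level_set}.
#' @rdname read_probe_level
#' @export
write_probe_level <- function(data, path) {
  tab <- data.frame(probe_set_id = data$probe_set_id,
                    probe_id = data$probe_id,
                    data$intensities, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare immune-subset proportions between groups
#'
#' Two-sided Wilcoxon rank-sum test per subset between two groups, with a
#' pre-defined significance level (default 0.01, guarding against multiple
#' comparisons across subsets).
#'
#' @param table data.frame with \code{group} plus one numeric column per
#'   subset (proportions of PBMC, 0-100 scale).
#' @param groups the two group labels to compare (default TOL vs NONTOL).
#' @param alpha significance level (default 0.01).
#' @return data.frame per subset: \code{statistic}, \code{p},
#'   \code{significant}; subsets with missing values are dropped with a
#'   warning.
#' @export
compare_subsets <- function(table, groups = c("TOL", "NONTOL"), alpha = 0.01) {
  stopifnot("group" %in% names(table))
  sub <- table[table$group %in% groups, ]
  subsets <- setdiff(names(sub), "group")
  rows <- list()
  for (s in subsets) {
    v <- sub[[s]]
    if (any(is.na(v))) {
      warning("subset '", s, "' dropped: missing values")
      next
    }
    if (min(table(sub$group)) < 2) stop("need >= 2 samples per group")
    w <- suppressWarnings(wilcox.test(v ~ factor(sub$group, levels = groups)))
    rows[[s]] <- data.frame(subset = s, statistic = unname(w$statistic),
                            p = w$p.value, significant = w$p.value < alpha,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
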