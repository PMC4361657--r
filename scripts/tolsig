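#!/usr/bin/env Rscript
# Thin command-line wrapper over the tolsig package.
#
#   tolsig simulate --out DIR [--seed N] [--probes N]
#   tolsig sam      --gct F --cls F --out DIR [--seed N] [--fdr X] [--fold X]
#   tolsig filter   --gct F --annotation F --out DIR [--seed N]
#   tolsig classify --gct F --annotation F --out DIR [--seed N] [--features K]
#   tolsig run      --gct F --annotation F [--gmt F] --out DIR [--seed N]
#
# Exit codes: 2 usage error, 3 data error, 1 other failure.

suppressPackageStartupMessages({
  library(optparse)
  library(tolsig)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  message("usage: tolsig <simulate|sam|filter|classify|run> [options]")
  quit(status = 2)
}
cmd <- args[1]

olist <- list(
  make_option("--gct", type = "character", default = NULL),
  make_option("--cls", type = "character", default = NULL),
  make_option("--annotation", type = "character", default = NULL),
  make_option("--gmt", type = "character", default = NULL),
  make_option("--out", type = "character", default = "tolsig_out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--probes", type = "integer", default = 2000L),
  make_option("--fdr", type = "double", default = 0.10),
  make_option("--fold", type = "double", default = 1.5),
  make_option("--features", type = "integer", default = 20L))
opt <- tryCatch(parse_args(OptionParser(option_list = olist), args[-1]),
                error = function(e) { message(conditionMessage(e)); quit(status = 2) })
dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)

need <- function(...) {
  for (a in c(...)) if (is.null(opt[[a]])) {
    message("missing required option --", a)
    quit(status = 2)
  }
}

run <- function(expr) tryCatch(expr, error = function(e) {
  message("error: ", conditionMessage(e))
  quit(status = 3)
})

if (cmd == "simulate") {
  run({
    d <- generate_dataset(sim_config(n_probes = opt$probes, seed = opt$seed))
    write_gct(d$x, file.path(opt$out, "expression.gct"))
    write_cls(d$annotation$group, file.path(opt$out, "phenotype.cls"),
              classes = c("TOL", "NONTOL", "CTRL"))
    write_annotation(d$annotation, file.path(opt$out, "annotation.tsv"))
    write.table(d$truth, file.path(opt$out, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
} else if (cmd == "sam") {
  need("gct", "cls")
  run({
    x <- read_gct(opt$gct)
    cls <- read_cls(opt$cls)
    keep <- cls$labels %in% c("TOL", "NONTOL")
    fit <- run_sam(x[, keep, drop = FALSE],
                   factor(cls$labels[keep], levels = c("TOL", "NONTOL")),
                   sam_config(target_fdr = opt$fdr, min_fold = opt$fold,
                              seed = opt$seed))
    write.table(fit$stats, file.path(opt$out, "sam_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_lists(fit$called, file.path(opt$out, "called.tsv"))
    jsonlite::write_json(list(s0 = fit$s0, delta = fit$delta,
                              n_called = nrow(fit$called),
                              est_fdr = fit$est_fdr),
                         file.path(opt$out, "sam_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })
} else if (cmd == "filter") {
  need("gct", "annotation")
  run({
    fr <- three_group_filter(read_gct(opt$gct),
                             read_annotation(opt$annotation),
                             sam_config(target_fdr = opt$fdr,
                                        min_fold = opt$fold,
                                        seed = opt$seed))
    write_lists(fr$final_tol, file.path(opt$out, "final_tol.tsv"))
    write_lists(fr$final_ntol, file.path(opt$out, "final_ntol.tsv"))
    print(fr)
  })
} else if (cmd == "classify") {
  need("gct", "annotation")
  run({
    rep <- cross_validate(read_gct(opt$gct), read_annotation(opt$annotation),
                          cv_config(k_features = opt$features,
                                    seed = opt$seed))
    write.table(feature_stability(rep, 0), file.path(opt$out, "stability.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rep$roc, file.path(opt$out, "roc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    print(rep)
  })
} else if (cmd == "run") {
  need("gct", "annotation")
  run({
    run_pipeline(opt$gct, opt$annotation, sets = opt$gmt,
                 sam_cfg = sam_config(target_fdr = opt$fdr,
                                      min_fold = opt$fold),
                 cv_cfg = cv_config(k_features = opt$features),
                 out_dir = opt$out, seed = opt$seed)
  })
} else {
  message("unknown subcommand: ", cmd)
  quit(status = 2)
}
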