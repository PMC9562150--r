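#!/usr/bin/env Rscript

# Thin command-line front end over the vaxscape package for batch use:
#
#   Rscript scripts/vaxscape-sim experiment --name influence_clustering \
#       --n 512 --reps 50 --seed 1 --out results/influence.csv
#   Rscript scripts/vaxscape-sim fixture --n 512 --beta 0.4 --alpha 0.2 \
#       --seed 1 --out runs/fix1
#
# `experiment` runs a named experiment over its default grid and writes the
# tidy per-run table plus a "<out>.summary.csv" of cell means; `fixture`
# generates a two-timepoint synthetic fixture directory.

suppressMessages(library(vaxscape))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("experiment", "fixture")) {
  stop("usage: vaxscape-sim {experiment|fixture} [--key value ...]", call. = FALSE)
}
cmd <- args[1]
opts <- list()
flags <- args[-1]
for (i in seq(1, length(flags), by = 2)) {
  if (i + 1 > length(flags)) stop("Missing value for ", flags[i], call. = FALSE)
  opts[[sub("^--", "", flags[i])]] <- flags[i + 1]
}
num <- function(key, default) as.numeric(opts[[key]] %||% default)
`%||%` <- function(a, b) if (is.null(a)) b else a

if (cmd == "experiment") {
  out <- opts[["out"]] %||% "results/experiment.csv"
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  res <- run_experiment(
    opts[["name"]] %||% "influence_clustering",
    n = num("n", 512), k = num("k", 6),
    reps = num("reps", 50), seed = as.integer(num("seed", 1))
  )
  readr::write_csv(res, out)
  readr::write_csv(summarize_experiment(res), paste0(out, ".summary.csv"))
  cat("wrote", out, "\n")
} else {
  out <- opts[["out"]] %||% "runs/fixture"
  spec <- fixture_spec(
    n = num("n", 512), k = num("k", 6), p_social = num("p", 0.2),
    beta_target = num("beta", 0.4), alpha_true = num("alpha", 0.2),
    seed = as.integer(num("seed", 1))
  )
  write_fixture(make_two_timepoint_fixture(spec), out)
  cat("wrote fixture to", out, "\n")
}
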