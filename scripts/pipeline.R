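#!/usr/bin/env Rscript
# Thin shell wrapper over the package pipeline:
#   Rscript scripts/pipeline.R simulate --outdir DIR [--seed N]
#   Rscript scripts/pipeline.R run-all --datadir DIR --outdir DIR [--seed N]
# Exit codes: 0 success, 1 validation error, 2 stage failure.

suppressMessages(library(paleoscape))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) {
  message("usage: pipeline.R <simulate|run-all> --outdir DIR ",
          "[--datadir DIR] [--seed N] [--scenario FILE]")
  quit(status = 1)
}
cmd <- args[1]
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) return(default)
  args[i + 1]
}
seed <- as.integer(get_arg("--seed", "1"))
outdir <- get_arg("--outdir")
if (is.null(outdir)) {
  message("--outdir is required")
  quit(status = 1)
}

status <- tryCatch({
  if (cmd == "simulate") {
    scen <- get_arg("--scenario")
    cfg <- if (is.null(scen)) mini_scenario() else read_scenario(scen)
    run_simulate(cfg, outdir, seed = seed)
    0L
  } else if (cmd == "run-all") {
    datadir <- get_arg("--datadir")
    if (is.null(datadir)) { message("--datadir is required"); 1L }
    else { run_all(datadir, outdir, seed = seed); 0L }
  } else {
    message("unknown subcommand: ", cmd)
    1L
  }
}, error = function(e) {
  message("stage failure: ", conditionMessage(e))
  2L
})
quit(status = status)
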