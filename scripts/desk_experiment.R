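#!/usr/bin/env Rscript

## Desk-scale learning-beats-chance experiment (not part of the default test
## suite: ~1-2 h per seed on one CPU). Trains the full model at 5e4
## iterations with 200-atom dictionaries, then compares the trained greedy
## policy against the RNDCTL random-action baseline on a 5-stimulus test
## grid, for 3 seeds. The expectation is that the trained medians of |dXi|
## and |dv| are at most half of the baseline's.
##
## Usage: Rscript scripts/desk_experiment.R [--seeds 1,2,3] [--out DIR]
##        [--iterations N]

suppressMessages({
  library(optparse)
  library(aecvision)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seeds", type = "character", default = "1,2,3"),
  make_option("--iterations", type = "integer", default = 50000L),
  make_option("--out", type = "character", default = "desk_experiment")
)))
seeds <- as.integer(strsplit(opts$seeds, ",")[[1]])
dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)

randomPolicy <- function(world, eyes, actions) {
  a <- sample(actions, 3, replace = TRUE)
  c(pan = a[1], tilt = a[2], vergence = a[3])
}

summaries <- list()
for (seed in seeds) {
  cfg <- deskProfile(totalIterations = opts$iterations)
  message("training seed ", seed, " (", opts$iterations, " iterations) ...")
  run <- trainAgent(cfg, seed = seed,
    checkpointDir = file.path(opts$out, paste0("seed", seed)))
  grid <- makeTestGrid(cfg$nTestStimuli)
  trained <- testPolicy(run, grid, seed = seed)
  baseline <- testPolicy(NULL, grid, seed = seed, policy = randomPolicy,
    config = cfg)
  med <- function(r) vapply(r[c("dvPan", "dvTilt", "dXi")],
    function(x) median(abs(x), na.rm = TRUE), numeric(1))
  summaries[[as.character(seed)]] <- data.frame(seed = seed,
    joint = c("pan", "tilt", "vergence"), trained = med(trained),
    baseline = med(baseline))
  utils::write.csv(trained,
    file.path(opts$out, sprintf("trained_seed%d.csv", seed)),
    row.names = FALSE)
  utils::write.csv(baseline,
    file.path(opts$out, sprintf("baseline_seed%d.csv", seed)),
    row.names = FALSE)
}

tab <- do.call(rbind, summaries)
tab$ratio <- tab$trained / tab$baseline
utils::write.csv(tab, file.path(opts$out, "summary.csv"), row.names = FALSE)
print(tab, row.names = FALSE)
ok <- with(aggregate(ratio ~ joint, tab, median), all(ratio <= 0.5))
message(if (ok) "trained policy beats chance by the required margin"
  else "trained policy did NOT reach half the baseline error")
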