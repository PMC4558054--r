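#!/usr/bin/env Rscript
# Morris elementary-effects screening of the kinetic parameters against the
# synthetic study data. By default screens the flagged sensitive subset with
# few repetitions so the script stays quick; pass "--full" to screen every
# parameter at the standard 35 repetitions (roughly 140 x 36 simulations).

suppressPackageStartupMessages(library(choflux))

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args)
  args[which(args == "--seed") + 1] else 1)
full <- "--full" %in% args
out_dir <- "results/sensitivity"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

net <- reference_network()
par <- reference_parameters()
exps <- reference_experiments()
meas <- read_measurements("results/synthetic/measurements.csv")
via <- read_viability("results/synthetic/viability.csv")
mw <- window_measurements(meas, via)

params_to_screen <- if (full) par$name else par$name[par$sensitive_flag == 1]
reps <- if (full) 35L else 3L
des <- morris_design(params_to_screen, param_values(par),
                     reps = reps, seed = seed)
cat(sprintf("screening %d parameters, %d repetitions (%d simulations)\n",
            length(params_to_screen), reps,
            reps * (length(params_to_screen) + 1)))

scr <- morris_screen(net, par, exps["biogro_batch"],
                     mw[mw$culture == "biogro_batch", ], design = des)
write_table(as.data.frame(scr), file.path(out_dir, "morris_screen.csv"))

sel <- select_sensitive(scr, threshold = 0.6, max_count = 20)
writeLines(sel, file.path(out_dir, "sensitive_subset.txt"))
write_manifest(file.path(out_dir, "manifest.yaml"), seed = seed,
               inputs = "results/synthetic/measurements.csv")

cat("top parameters by |mean elementary effect|:\n")
print(utils::head(as.data.frame(scr)[, c("parameter", "mean_ee", "sd_ee")], 10))
cat(length(sel), "parameters pass the |mean EE| >= 0.6 rule\n")
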