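#!/usr/bin/env Rscript
# Stage 1: generate the synthetic mesocosm experiment at the default study
# conditions (6 treatments x 5 tanks, 2 amphipod cages of 20 per tank,
# 15 tadpoles per tank), validate it, and write the tidy CSV tables that
# the later stages read back.

suppressMessages(library(mesotox))

seed <- 1L
config <- sim_config(seed = seed)
ds <- simulate_experiment(config)

v <- validate_dataset(ds)
print(v)
stopifnot(nrow(v$errors) == 0)

write_dataset(ds, "results/dataset")
print(ds)
cat("Dataset written to results/dataset (seed", seed, ")\n")
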