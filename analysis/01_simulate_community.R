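#!/usr/bin/env Rscript
# Stage 1: simulate the study community.
#
# Builds the default planted community -- 3 phage families x 2 genera x
# 2 species x 2 strains (~40 kb genomes, GC 0.35, 90% coding) -- and writes
# genomes, planted-gene table, tier truth labels and a checksum manifest
# under results/community/. Everything downstream reads these files.

suppressPackageStartupMessages(library(flavoscope))

cfg <- run_config(out = "results", seed = 42L)
paths <- run_simulate(cfg)

comm <- plant_taxonomy(community_spec(seed = cfg$seed))
cat(sprintf("Simulated %d genomes (%d families / %d genera / %d species / %d strains)\n",
            length(comm$genomes), length(unique(comm$truth$family)),
            length(unique(comm$truth$genus)),
            length(unique(comm$truth$species)),
            length(unique(comm$truth$strain))))
cat("Files written:\n")
print(unname(paths))
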