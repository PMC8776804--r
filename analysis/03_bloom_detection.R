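#!/usr/bin/env Rscript
# Stage 3: bloom detection and phage/host ratios.
#
# Two parts. (a) A simulated "bloom": metagenome reads drawn from one
# blooming phage (high abundance, exact), one host (low abundance), and one
# distant phage relative (25% divergence); the three presence rules
# (bacterium >60% breadth @ >=95% identity, phage >75% @ >=90%, relative
# >60% @ >=70%) and normalized abundances are evaluated from the read
# alignments. (b) The bundled table of normalized genome coverages from a
# 2018 North Sea spring bloom, from which the phage/host ratio table is
# recomputed.

suppressPackageStartupMessages(library(flavoscope))

cfg <- run_config(out = "results", seed = 42L)

## (a) simulated bloom: an early sample with the exact phage blooming, and a
## late sample where only distant relatives (25% diverged reads) remain
phage <- generate_ancestor(38000, 0.33, seed = 101, id = "phage_bloom")
host <- generate_ancestor(42000, 0.35, seed = 102, id = "host_bact")
genomes <- c(phage_bloom = unname(phage), host_bact = unname(host))
pairs <- data.frame(phage_id = "phage_bloom", host_id = "host_bact")

early_phage <- simulate_reads(genomes, c(phage_bloom = 50, host_bact = 0),
                              150, 0, 38000 * 60, seed = 104)
early_host <- simulate_reads(genomes, c(phage_bloom = 0, host_bact = 1),
                             150, 0, 42000 * 2, seed = 105)
aln_early <- rbind(alignments_from_readset(early_phage),
                   alignments_from_readset(early_host))
res_early <- run_detect(aln_early, genomes,
                        early_phage$library_size_gb +
                          early_host$library_size_gb,
                        pairs = pairs, cfg = cfg)
cat("early bloom sample (exact phage at 60x, host at 2x):\n")
print(res_early$detection[, c("genome_id", "kind", "covered_fraction",
                              "present")])
cat(sprintf("phage/host abundance ratio: %s\n\n",
            res_early$ratios$ratio_printed))

late_rel <- simulate_reads(genomes, c(phage_bloom = 1, host_bact = 0),
                           150, 0.25, 38000 * 10, seed = 106)
late_host <- simulate_reads(genomes, c(phage_bloom = 0, host_bact = 1),
                            150, 0, 42000 * 2, seed = 107)
aln_late <- rbind(alignments_from_readset(late_rel),
                  alignments_from_readset(late_host))
res_late <- run_detect(aln_late, genomes,
                       late_rel$library_size_gb + late_host$library_size_gb,
                       pairs = pairs, cfg = cfg)
cat("late bloom sample (only 25%-diverged phage relatives):\n")
print(res_late$detection[, c("genome_id", "kind", "covered_fraction",
                             "present")])

## (b) published bloom abundance table
cov <- read.delim(system.file("extdata", "bloom2018_coverage.tsv",
                              package = "flavoscope"))
tab <- bloom_ratio_table(cov)
write_tsv(tab, file.path(cfg$out, "bloom2018_ratios.tsv"))
cat("\nphage/host ratios recomputed from the 2018 bloom coverage table:\n")
print(tab[, c("julian_day", "name", "phage_abundance", "host_abundance",
              "ratio_printed")])
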