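#!/usr/bin/env Rscript
# Phytotoxkit scoring: seed germination (SG) and root growth (RI) inhibition
# on the printed inhibition table (species/hydrocarbon means) and on the
# synthetic per-seed trials.

suppressPackageStartupMessages(library(pahsoiltox))
dir.create("results", showWarnings = FALSE)

inh <- printed_inhibition_results()
species <- unique(inh$species)
sp_means <- data.frame(
  species = species,
  sg = sapply(species, function(s)
    round_half_up(species_mean_inhibition(inh, s, "sg_percent"), 1)),
  ri = sapply(species, function(s)
    round_half_up(species_mean_inhibition(inh, s, "ri_percent"), 1)))
hc_means <- data.frame(
  hydrocarbon = pah_types(),
  sg = sapply(pah_types(), function(h)
    round_half_up(hydrocarbon_mean_inhibition(inh, h, "sg_percent"), 1)),
  ri = sapply(pah_types(), function(h)
    round_half_up(hydrocarbon_mean_inhibition(inh, h, "ri_percent"), 1)))
write.csv(sp_means, "results/phytotox_species_means.csv", row.names = FALSE)
write.csv(hc_means, "results/phytotox_hydrocarbon_means.csv", row.names = FALSE)

cat("Mean inhibition per species (printed table, %):\n")
print(sp_means, row.names = FALSE)
cat("\nMean inhibition per hydrocarbon (printed table, %):\n")
print(hc_means, row.names = FALSE)
cat("\nSinapis alba is the most root-growth-sensitive species; Sorghum\n")
cat("saccharatum shows net stimulation (negative RI).\n")

trials <- read_phytotox_trials("results/synthetic/phytotox_trials.csv")
syn <- phytotox_summary(trials)
write.csv(syn, "results/phytotox_synthetic.csv", row.names = FALSE)
cat(sprintf("\nSynthetic trials scored: %d species x hydrocarbon cells -> results/phytotox_synthetic.csv\n",
            nrow(syn)))
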