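#!/usr/bin/env Rscript
# Generate the default synthetic cohort: 12 standard-code + 12 AYCU species,
# 2 families x 500 columns, with clade-inherited CUG placements, stray CUGs
# at variable columns, gap blocks and one zero-CUG species.  Writes the
# alignments, coding sequences and truth tables that the later steps read.

library(cugusage)

co <- simulate_cohort(sim_config(seed = 1))
dir <- "results/cohort"
write_cohort(co, dir)

cat("wrote", length(co$families), "families for",
    nrow(co$truth$species), "species to", dir, "\n")
cat("total CUG sites:", nrow(co$truth$sites),
    "| clade-inherited:", sum(co$truth$sites$inherited),
    "| strays:", sum(!co$truth$sites$inherited), "\n")
print(table(truth = co$truth$species$true_code,
            has_cug = co$truth$species$n_cug_true > 0))
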