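#!/usr/bin/env Rscript
# Stage 1: simulate the default synthetic study cohort.
#
# 34 patients (10 favorable / 24 unfavorable outcome), nominally 24 h of
# 1 Hz systolic pressure each, with the 23/5/5 complete/intermediate/short
# record-length split, injected artifacts and monitoring gaps. The group
# effect is confined to the midrange (1/20-1/5 min) band, power ratio ~1.9.
# The raw cohort is large, so it goes to scratch/; downstream stages read
# it from there.

library(bpvar)

seed <- as.integer(Sys.getenv("BPVAR_SEED", "1"))
out_dir <- "scratch/cohort"

cfg <- synth_config(seed = seed)
cat(sprintf("simulating %d + %d patients at %g Hz (seed %d)...\n",
            cfg$n_favorable, cfg$n_unfavorable, cfg$fs, seed))
cohort <- generate_cohort(cfg)
write_cohort(cohort, out_dir)

durs <- vapply(cohort_traces(cohort), function(tr) {
  length(tr$x) / tr$fs / 3600
}, numeric(1))
cat(sprintf("wrote %d traces to %s\n", length(cohort), out_dir))
cat(sprintf("record lengths: %d complete (24 h), %d in 12-24 h, %d under 12 h\n",
            sum(durs >= 24 - 1e-9), sum(durs >= 12 & durs < 24 - 1e-9),
            sum(durs < 12)))
cat(sprintf("median duration %.1f h\n", median(durs)))
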