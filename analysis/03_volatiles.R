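#!/usr/bin/env Rscript
# Stage 3: internal-standard semi-quantification of volatile compounds.
#
# Converts the simulated peak areas to ug/g against the 2-octanol internal
# standard, aggregates by chemical class, reports the compounds above 1 %
# relative abundance, and compares compound sets across samples.

library(maotofu)

dir.create("results", showWarnings = FALSE)
cfg <- synth_config(seed = 20260925)

peaks <- read_tsv("results/inputs/volatile_peaks.tsv")
quant <- quantify_volatiles(peaks, cis = cfg$internal_standard_conc)
write_tsv(quant, "results/volatile_quant.tsv")

# sanity against the simulator's planted truth
truth <- read_tsv("results/inputs/volatile_truth.tsv")
m <- merge(quant, truth, by = c("sample_id", "compound"))
message(sprintf("max |recovered - planted| concentration: %.2e ug/g",
                max(abs(m$conc_ug_per_g - m$true_conc_ug_per_g))))

classes <- aggregate_classes(quant)
write_tsv(classes, "results/volatile_classes.tsv")
message("\nComponents per sample and class:")
print(stats::xtabs(n_compounds ~ sample_id + chemical_class, classes))

major <- filter_relative(quant, min_pct = 1)
write_tsv(major, "results/volatile_major.tsv")
message("\nCompounds above 1% relative abundance: ", nrow(major), " of ",
        nrow(quant))

cmp <- compare_samples(quant)
write_tsv(cmp$shared, "results/volatile_shared.tsv")
jsonlite::write_json(
  list(unique_counts = as.list(cmp$unique_counts),
       presence = as.data.frame(cmp$presence)),
  "results/volatile_presence.json", auto_unbox = TRUE, digits = NA)
message("\nShared compounds per sample pair:")
print(cmp$shared)
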