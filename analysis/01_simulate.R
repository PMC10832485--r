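#!/usr/bin/env Rscript
# Stage 1: simulate every input of the analysis chain and write it to disk.
#
# Three sample classes are emulated: BB (commercial, unfermented control),
# MM (naturally fermented) and CC (artificially inoculated with Mucor).
# The amino-acid class means are anchored to the published class composition;
# volatiles, amplicon reads and the taxa/metabolite matrices carry planted
# ground truth that later stages are expected to recover.

library(maotofu)

outdir <- "results/inputs"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
cfg <- synth_config(seed = 20260925)

aa <- gen_amino_acid_profiles(cfg)
write_tsv(aa$table, file.path(outdir, "amino_acid_profiles.tsv"))
message("amino acids: ", length(aa$profiles), " samples x ",
        length(aa_codes()), " acids")

vol <- gen_volatile_table(cfg)
write_tsv(vol, file.path(outdir, "volatile_peaks.tsv"))
write_tsv(attr(vol, "truth"), file.path(outdir, "volatile_truth.tsv"))
message("volatiles: ", cfg$n_volatiles, " compounds + internal standard per sample")

amp <- gen_amplicon_reads(cfg)
write_amplicon_fastq(amp$reads, file.path(outdir, "reads.fastq"),
                     file.path(outdir, "reads_accuracy.tsv"))
write_tsv(amp$truth, file.path(outdir, "reads_truth.tsv"))
write_tsv(data.frame(barcode = names(amp$barcode_map),
                     sample_id = unname(amp$barcode_map)),
          file.path(outdir, "barcodes.tsv"))
message("amplicons: ", nrow(amp$reads), " reads across ",
        length(amp$barcode_map), " samples, ", cfg$n_taxa, " taxa")

ds <- gen_taxa_metabolite_dataset(cfg)
write_tsv(data.frame(taxon = rownames(ds$taxa), ds$taxa, check.names = FALSE),
          file.path(outdir, "taxa_abundance.tsv"))
write_tsv(data.frame(metabolite = rownames(ds$metabolites), ds$metabolites,
                     check.names = FALSE),
          file.path(outdir, "metabolite_abundance.tsv"))
write_tsv(ds$links, file.path(outdir, "planted_links.tsv"))
message("correlation dataset: ", nrow(ds$taxa), " taxa x ", ncol(ds$taxa),
        " samples, ", nrow(ds$links), " planted links")
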