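#!/usr/bin/env Rscript
# Stage 4: full-length 16S community profiling.
#
# Demultiplexes the simulated long reads by their 16-base barcodes, applies
# the length (1400-1800 bp inclusive) and predicted-accuracy (>= 0.90)
# filters, dereplicates at 100 %, clusters OTUs greedily at 97 % identity,
# and reports relative abundances, dominant taxa, Shannon diversity and
# rarefaction curves.

library(maotofu)

dir.create("results", showWarnings = FALSE)

reads <- read_amplicon_fastq("results/inputs/reads.fastq",
                             "results/inputs/reads_accuracy.tsv")
bc <- read_tsv("results/inputs/barcodes.tsv")
truth <- read_tsv("results/inputs/reads_truth.tsv")

dm <- demultiplex(reads, setNames(bc$sample_id, bc$barcode))
message("demultiplexed: ", nrow(dm$reads), " assigned, ",
        dm$n_unassigned, " unassigned")

qc <- qc_filter(dm$reads)
message(sprintf("QC: %d/%d pass (%d length fails, %d accuracy fails)",
                qc$stats$n_pass, qc$stats$n_input,
                qc$stats$n_fail_length, qc$stats$n_fail_accuracy))

otu <- build_otu_table(qc$reads, identity = 0.97, truth = truth)
otu$otus <- remove_chimeras(otu$otus)
message(nrow(otu$otus), " OTUs from ", sum(otu$counts), " reads (simulated taxa: ",
        length(unique(truth$species)), ")")
write_tsv(cbind(otu$otus[c("otu_id", "size")],
                rep_length = nchar(otu$otus$representative),
                otu$taxonomy[c("genus", "species")],
                as.data.frame(otu$counts)),
          "results/otu_table.tsv")

genus <- relative_abundance(otu$counts, otu$taxonomy, rank = "genus")
dom <- dominant_taxa(genus$average, min_pct = 1)
write_tsv(dom, "results/dominant_taxa.tsv")
message("\nDominant genera (>1% average relative abundance):")
print(dom, digits = 4)

sh <- shannon_index(otu$counts)
write_tsv(data.frame(sample_id = names(sh), shannon = unname(sh)),
          "results/shannon.tsv")
message("\nShannon diversity: ",
        paste(sprintf("%s = %.3f", names(sh), sh), collapse = ", "))

depth_max <- min(colSums(otu$counts))
rare <- rarefaction_curve(otu$counts,
                          depths = unique(c(5, 10, 25, 50, depth_max)),
                          n_reps = 200, seed = 20260925)
write_tsv(rare, "results/rarefaction.tsv")
message("\nRarefaction (mean observed OTUs at the deepest shared depth ",
        depth_max, "):")
print(rare[rare$depth == depth_max, ], digits = 3)
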