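test_that("synth_config validates its fields exhaustively", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(aa_class_means = list(BB = c(Xxx = 1), MM = c(Lys = 1),
                                                  CC = c(Lys = 1))),
               "unknown amino-acid")
  expect_error(synth_config(internal_standard_conc = 0), "internal_standard_conc")
  expect_error(synth_config(read_length_range = c(1800, 1400)), "read_length_range")
  expect_error(synth_config(read_length_range = c(100, 1800)), "read_length_range")
  expect_error(synth_config(planted_links = data.frame(
    taxon = "taxon_01", metabolite = "metab_01", sign = 1, strength = 1.2)),
    "strength")
  expect_error(synth_config(planted_links = data.frame(
    taxon = "taxon_99", metabolite = "metab_01", sign = 1, strength = 0.5)),
    "unknown taxon")
})

test_that("all four generators are deterministic under a fixed seed", {
  cfg <- synth_config(seed = 7, n_reads_per_sample = 20, n_samples_per_class = 1)
  expect_identical(gen_amino_acid_profiles(cfg), gen_amino_acid_profiles(cfg))
  expect_identical(gen_volatile_table(cfg), gen_volatile_table(cfg))
  expect_identical(gen_amplicon_reads(cfg), gen_amplicon_reads(cfg))
  expect_identical(gen_taxa_metabolite_dataset(cfg), gen_taxa_metabolite_dataset(cfg))
  # a different seed changes the draw
  expect_false(identical(gen_volatile_table(cfg),
                         gen_volatile_table(synth_config(seed = 8,
                                                         n_reads_per_sample = 20,
                                                         n_samples_per_class = 1))))
})

test_that("zero noise reproduces the class means exactly", {
  cfg <- synth_config(aa_noise_cv = 0)
  prof <- gen_amino_acid_profiles(cfg)$profiles
  # every CC replicate carries the anchored Lys mean of 7.35 g/100 g
  for (i in 1:3) expect_equal(prof[[paste0("CC_", i)]]$contents[["Lys"]], 7.35)
  # degenerate all-equal means
  ones <- lapply(c(BB = 1, MM = 1, CC = 1), function(x)
    stats::setNames(rep(1, 17), aa_codes()))
  u <- gen_amino_acid_profiles(synth_config(aa_noise_cv = 0, aa_class_means = ones))
  expect_true(all(u$table$g_per_100g == 1))
})

test_that("noisy profiles are strictly positive with the requested CV", {
  cfg <- synth_config(seed = 3, aa_noise_cv = 0.2, n_samples_per_class = 200)
  tab <- gen_amino_acid_profiles(cfg)$table
  expect_true(all(tab$g_per_100g > 0))
  lys <- tab$g_per_100g[tab$aa_code == "Lys" & tab$class == "CC"]
  expect_equal(mean(lys), 7.35, tolerance = 0.05)
  expect_equal(stats::sd(lys) / mean(lys), 0.2, tolerance = 0.05)
})

test_that("volatile tables carry one internal-standard row per sample and invert quantification", {
  cfg <- synth_config(n_volatiles = 3, n_samples_per_class = 1)
  tab <- gen_volatile_table(cfg)
  per_sample <- split(tab, tab$sample_id)
  expect_length(per_sample, 3)
  for (d in per_sample) {
    expect_equal(nrow(d), 4)  # 3 compounds + 1 IS row
    expect_equal(sum(d$compound == "2-octanol"), 1)
  }
  # areas are the exact inverse of C = (Ac/Ais) * Cis
  truth <- attr(tab, "truth")
  d <- per_sample[[1]]
  ais <- d$peak_area[d$compound == "2-octanol"]
  cmp <- d[d$compound != "2-octanol", ]
  tr <- truth[truth$sample_id == d$sample_id[1], ]
  expect_equal(cmp$peak_area,
               ais * tr$true_conc_ug_per_g / cfg$internal_standard_conc,
               tolerance = 1e-12)
})

test_that("amplicon reads carry 16-base barcodes, truth labels, and QC-clean defaults", {
  cfg <- synth_config(seed = 11, n_samples_per_class = 1, n_reads_per_sample = 25,
                      n_taxa = 3, accuracy_dist = c(mean = 0.99, sd = 0.005))
  amp <- gen_amplicon_reads(cfg)
  expect_equal(nrow(amp$reads), 75)
  expect_true(all(nchar(names(amp$barcode_map)) == 16))
  expect_false(anyDuplicated(names(amp$barcode_map)) > 0)
  # every read is prefixed by its sample's barcode
  bc_of_sample <- stats::setNames(names(amp$barcode_map), amp$barcode_map)
  expect_true(all(substr(amp$reads$sequence, 1, 16) ==
                    bc_of_sample[amp$truth$sample_id]))
  # zero decoys and a high accuracy floor: everything survives QC
  dm <- demultiplex(amp$reads, amp$barcode_map)
  expect_equal(dm$n_unassigned, 0)
  qc <- qc_filter(dm$reads)
  expect_equal(qc$stats$n_pass, 75)
  expect_true(all(amp$truth$read_id %in% amp$reads$read_id))
})

test_that("decoy reads fail QC at the configured fraction", {
  cfg <- synth_config(seed = 12, n_samples_per_class = 1, n_reads_per_sample = 40,
                      n_taxa = 2, decoy_fraction = 0.25,
                      accuracy_dist = c(mean = 0.99, sd = 0.002))
  amp <- gen_amplicon_reads(cfg)
  dm <- demultiplex(amp$reads, amp$barcode_map)
  qc <- qc_filter(dm$reads)
  n_decoy <- sum(amp$truth$is_decoy)
  expect_equal(n_decoy, 3 * 10)
  expect_equal(qc$stats$n_pass, nrow(amp$reads) - n_decoy)
})

test_that("taxon templates more than 3% divergent yield at least two OTUs", {
  cfg <- synth_config(seed = 5, n_samples_per_class = 1, n_reads_per_sample = 20,
                      n_taxa = 2, mutation_rate = 0)
  amp <- gen_amplicon_reads(cfg)
  # oracle: pairwise identity of the templates themselves
  ident <- seq_identity(amp$templates$sequence[1], amp$templates$sequence[2])
  expect_lt(ident, 0.97)
  dm <- demultiplex(amp$reads, amp$barcode_map)
  otu <- build_otu_table(dm$reads, identity = 0.97)
  expect_gte(nrow(otu$otus), 2)
})

test_that("planted monotone links control the Spearman correlation", {
  # strength 1: exact monotone link, rho = +/-1 by construction
  for (sg in c(1, -1)) {
    cfg <- synth_config(seed = 21, n_taxa = 2, n_metabolites = 2,
                        planted_links = data.frame(taxon = "taxon_01",
                                                   metabolite = "metab_01",
                                                   sign = sg, strength = 1))
    ds <- gen_taxa_metabolite_dataset(cfg)
    expect_equal(stats::cor(ds$taxa["taxon_01", ], ds$metabolites["metab_01", ],
                            method = "spearman"), sg)
  }
  # columns of the normalized matrix sum to 100 and everything is positive
  ds <- gen_taxa_metabolite_dataset(synth_config(seed = 22))
  expect_true(all(ds$taxa > 0))
  expect_equal(unname(colSums(ds$taxa_pct)), rep(100, ncol(ds$taxa_pct)),
               tolerance = 1e-9)
})

test_that("strength-zero links average to zero correlation over many replicates", {
  # oracle: mean Spearman rho over 1000 seeded replicates should sit within
  # +/-0.05 of zero
  rhos <- vapply(1:1000, function(s) {
    cfg <- synth_config(seed = s, n_taxa = 2, n_metabolites = 2,
                        n_assoc_samples = 20,
                        planted_links = data.frame(taxon = "taxon_01",
                                                   metabolite = "metab_01",
                                                   sign = 1, strength = 0))
    ds <- gen_taxa_metabolite_dataset(cfg)
    stats::cor(ds$taxa["taxon_01", ], ds$metabolites["metab_01", ],
               method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
})
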