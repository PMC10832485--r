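# 16-base barcodes
B1 <- paste0(strrep("A", 8), strrep("C", 8))
B2 <- paste0(strrep("G", 8), strrep("T", 8))

test_that("demultiplexing assigns by exact 5' barcode and strips both ends", {
  insert <- strrep("ACGT", 10)
  reads <- reads_df(c(paste0(B1, insert, revcomp(B1)),   # both ends tagged
                      paste0(B1, insert),                # 5' only
                      paste0(B2, insert, revcomp(B2)),
                      paste0(strrep("T", 16), insert)))  # novel 16-mer
  dm <- demultiplex(reads, c(stats::setNames("s1", B1), stats::setNames("s2", B2)))
  expect_equal(dm$n_unassigned, 1)
  expect_equal(dm$reads$sample_id, c("s1", "s1", "s2"))
  expect_equal(dm$reads$sequence, rep(insert, 3))
})

test_that("demultiplexing validates barcodes and splits counts correctly", {
  expect_error(demultiplex(reads_df("ACGT"), c(stats::setNames("s", "ACGT"))),
               "16 bases")
  dup <- stats::setNames(c("s1", "s2"), c(B1, B1))
  expect_error(demultiplex(reads_df("ACGT"), dup), "duplicate")
  # 3 + 2 reads over two barcodes
  insert <- strrep("GATTACA", 5)
  reads <- reads_df(c(rep(paste0(B1, insert), 3), rep(paste0(B2, insert), 2)))
  dm <- demultiplex(reads, c(stats::setNames("s1", B1), stats::setNames("s2", B2)))
  expect_equal(as.vector(table(dm$reads$sample_id)[c("s1", "s2")]), c(3L, 2L))
})

test_that("QC bounds are inclusive on length and accuracy", {
  reads <- reads_df(vapply(c(1399, 1400, 1800, 1650), function(n) strrep("A", n),
                           character(1)),
                    acc = c(0.95, 0.95, 0.89, 0.92))
  qc <- qc_filter(reads)
  expect_equal(qc$stats$n_pass, 2)
  expect_equal(qc$stats$n_fail_length, 1)
  expect_equal(qc$stats$n_fail_accuracy, 1)
  expect_equal(nchar(qc$reads$sequence), c(1400, 1650))

  empty <- qc_filter(reads_df(character(0), numeric(0)))
  expect_equal(empty$stats$n_pass, 0)
  expect_equal(empty$stats$n_input, 0)

  all_in <- qc_filter(reads_df(rep(strrep("C", 1500), 4), rep(1.0, 4)))
  expect_equal(all_in$stats$n_pass, 4)
})

test_that("dereplication groups exact duplicates with first-seen representatives", {
  d1 <- dereplicate(rep("ACGTACGT", 5))
  expect_equal(nrow(d1), 1)
  expect_equal(d1$size, 5)

  d2 <- dereplicate(c("AAA", "AAT", "AAA", "AAT", "AAA"))
  expect_equal(d2$sequence, c("AAA", "AAT"))
  expect_equal(d2$size, c(3, 2))
  expect_equal(sum(d2$size), 5)
  # assignment attribute maps each read to its unique row
  expect_equal(d2$sequence[attr(d2, "assignment")],
               c("AAA", "AAT", "AAA", "AAT", "AAA"))

  set.seed(2)
  distinct <- vapply(1:8, function(i) random_seq(30), character(1))
  expect_equal(nrow(dereplicate(distinct)), 8)
})

test_that("alignment identity matches hand-computed cases", {
  # equal sequences
  expect_equal(seq_identity("ACGTACGTAC", "ACGTACGTAC"), 1)
  # 2 substitutions in 10 columns
  expect_equal(seq_identity(mutate_at("ACGTACGTAC", c(3, 7)), "ACGTACGTAC"), 0.8)
  # one terminal gap: 3 matches over 4 alignment columns
  expect_equal(seq_identity("ACG", "ACGT"), 0.75)
})

test_that("greedy OTU clustering merges near-identical and splits divergent sequences", {
  expect_error(cluster_otus(dereplicate("ACGT"), identity = 1.5), "identity")

  set.seed(1)
  base <- random_seq(100)
  # 2 substitutions => 98% identity: one OTU
  one <- cluster_otus(dereplicate(c(rep(base, 3), rep(mutate_at(base, c(10, 20)), 2))))
  expect_equal(nrow(one), 1)
  expect_equal(one$size, 5)
  # 4 substitutions => 96% identity: two OTUs
  two <- cluster_otus(dereplicate(c(rep(base, 3),
                                    rep(mutate_at(base, c(10, 20, 30, 40)), 2))))
  expect_equal(nrow(two), 2)
  expect_equal(sort(two$size, decreasing = TRUE), c(3, 2))
  # the representative is a member of its cluster
  expect_true(all(two$representative %in% c(base, mutate_at(base, c(10, 20, 30, 40)))))
})

test_that("clustering agrees with the exhaustive greedy oracle on random instances", {
  set.seed(33)
  for (rep_i in 1:12) {
    founders <- vapply(1:sample(2:4, 1), function(i) random_seq(60), character(1))
    seqs <- unlist(lapply(founders, function(f) {
      vapply(1:sample(2:5, 1), function(i)
        mutate_at(f, sample(60, sample(0:4, 1))), character(1))
    }))
    uniq <- dereplicate(seqs)
    got <- cluster_otus(uniq, identity = 0.95)
    want <- oracle_greedy_cluster(uniq, identity = 0.95)
    expect_equal(nrow(got), want$n_otus)
    expect_equal(attr(got, "membership"), want$membership)
  }
})

test_that("OTU tables preserve read counts and majority taxonomy", {
  cfg <- synth_config(seed = 14, n_samples_per_class = 1, n_reads_per_sample = 30,
                      n_taxa = 3, mutation_rate = 0.005,
                      accuracy_dist = c(mean = 0.99, sd = 0.002))
  amp <- gen_amplicon_reads(cfg)
  dm <- demultiplex(amp$reads, amp$barcode_map)
  otu <- build_otu_table(dm$reads, truth = amp$truth)
  expect_equal(sum(otu$counts), nrow(dm$reads))
  # truth recovery: templates far apart, mutation below 1% => one OTU per taxon
  expect_equal(nrow(otu$otus), 3)
  expect_setequal(otu$taxonomy$genus, unique(amp$truth$genus))
})

test_that("relative abundance sums to 100 per sample and averages across samples", {
  counts <- matrix(c(80, 20, 60, 40), nrow = 2,
                   dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
  rep1 <- relative_abundance(counts)
  expect_equal(unname(rep1$pct[, "S1"]), c(80, 20))
  expect_equal(unname(colSums(rep1$pct)), c(100, 100), tolerance = 1e-6)
  expect_equal(unname(rep1$average), c(70, 30))

  single <- relative_abundance(matrix(5, 1, 1, dimnames = list("OTU1", "S1")))
  expect_equal(unname(single$pct[1, 1]), 100)

  zero <- matrix(c(1, 0), 1, 2, dimnames = list("OTU1", c("S1", "S2")))
  expect_error(relative_abundance(zero), "zero total")

  tax <- data.frame(otu_id = c("OTU1", "OTU2"), genus = c("G1", "G1"),
                    species = c("a", "b"), stringsAsFactors = FALSE)
  gen <- relative_abundance(counts, tax, rank = "genus")
  expect_equal(unname(gen$pct["G1", ]), c(100, 100))
})

test_that("dominant taxa use a strict threshold with descending cumulative order", {
  ab <- c(Low = 0.4, Edge = 1.0, Mid = 18.89, Big = 60.48, Small = 1.03)
  dom <- dominant_taxa(ab, min_pct = 1)
  expect_equal(dom$taxon, c("Big", "Mid", "Small"))
  expect_equal(dom$cumulative_pct, cumsum(c(60.48, 18.89, 1.03)))
  expect_equal(nrow(dominant_taxa(c(a = 0.2, b = 0.9))), 0)
})

test_that("Shannon index matches closed forms and vegan", {
  expect_equal(unname(shannon_index(rep(10, 4))), log(4), tolerance = 1e-12)
  expect_equal(unname(shannon_index(c(42, 0, 0))), 0)
  expect_equal(unname(shannon_index(c(2, 1, 1))),
               -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25))),
               tolerance = 1e-12)
  expect_equal(unname(shannon_index(c(2, 1, 1))), 1.0397, tolerance = 1e-4)
  expect_error(shannon_index(c(0, 0)), "all-zero")
  skip_if_not_installed("vegan")
  set.seed(8)
  x <- matrix(rpois(30, 20), nrow = 5,
              dimnames = list(paste0("O", 1:5), paste0("S", 1:6)))
  expect_equal(unname(shannon_index(x)),
               unname(vegan::diversity(t(x), index = "shannon")),
               tolerance = 1e-12)
})

test_that("rarefaction is exact at boundary depths and errors beyond the total", {
  counts <- matrix(c(5, 3, 2), ncol = 1, dimnames = list(paste0("O", 1:3), "S1"))
  full <- rarefaction_curve(counts, depths = 10, n_reps = 20, seed = 1)
  expect_equal(full$mean_otus, 3)
  expect_equal(full$sd_otus, 0)
  one <- rarefaction_curve(counts, depths = 1, n_reps = 20, seed = 1)
  expect_equal(one$mean_otus, 1)
  expect_error(rarefaction_curve(counts, depths = 11, n_reps = 2, seed = 1),
               "depth exceeds")
  # means are non-decreasing in depth
  set.seed(10)
  big <- matrix(rpois(8, 30), ncol = 1, dimnames = list(paste0("O", 1:8), "S1"))
  curve <- rarefaction_curve(big, depths = c(5, 20, 80, sum(big)), n_reps = 100,
                             seed = 2)
  expect_true(all(diff(curve$mean_otus) >= -0.2))
})

test_that("FASTQ round trip preserves sequences and sidecar accuracies", {
  set.seed(5)
  reads <- reads_df(vapply(1:4, function(i) random_seq(50), character(1)),
                    acc = c(0.99, 0.95, 0.9, 0.8))
  fq <- tempfile(fileext = ".fastq"); sc <- tempfile(fileext = ".tsv")
  write_amplicon_fastq(reads, fq, sc)
  back <- read_amplicon_fastq(fq, sc)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$accuracy, reads$accuracy)
  expect_equal(back$read_id, reads$read_id)
})
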