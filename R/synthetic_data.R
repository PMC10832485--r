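#' Default class-mean amino-acid contents (g/100 g)
#'
#' Mean 17-amino-acid contents for the three study classes: BB (commercial,
#' unfermented control), MM (naturally fermented) and CC (artificially
#' inoculated). The means are anchored to the reported marker values (Lys
#' and Pro in BB, Pro in MM, Lys in CC) and constructed so that, at the
#' class protein levels, the class totals and essential-amino-acid
#' fractions reproduce the reported TAA, EAA/TAA and EAA/NEAA levels, the
#' highest ratios to the WHO/FAO pattern are Val (7.69-fold) in CC and Thr
#' (6.03-fold) in MM, and Phe+Tyr is the limiting entry in every class.
#'
#' @return Named list of named numeric vectors, one per class.
#' @export
default_aa_class_means <- function() {
  list(
    BB = c(Asp = 6.8, Thr = 3.2, Ser = 2.6, Glu = 10.0, Gly = 2.4, Ala = 3.2,
           Cys = 0.7, Val = 4.94, Met = 1.2, Ile = 3.0, Leu = 4.6, Tyr = 1.5,
           Phe = 1.7, Lys = 3.26, His = 1.45, Arg = 1.8, Pro = 2.37),
    MM = c(Asp = 9.0, Thr = 6.049, Ser = 3.4, Glu = 12.08, Gly = 3.2, Ala = 3.8,
           Cys = 0.9, Val = 4.951, Met = 2.2, Ile = 4.6, Leu = 7.0, Tyr = 2.5,
           Phe = 2.2, Lys = 6.9, His = 1.8, Arg = 2.2, Pro = 5.29),
    CC = c(Asp = 8.5, Thr = 4.144, Ser = 3.2, Glu = 12.0, Gly = 3.0, Ala = 4.2,
           Cys = 0.8, Val = 8.486, Met = 2.0, Ile = 5.6, Leu = 6.8, Tyr = 2.0,
           Phe = 2.6, Lys = 7.35, His = 1.9, Arg = 2.3, Pro = 1.38)
  )
}

#' Configuration for the synthetic-data generators
#'
#' One seeded configuration drives all four generators (amino-acid
#' profiles, volatile peak tables, amplicon reads, taxa/metabolite
#' matrices); identical configurations give identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param n_samples_per_class Replicate samples per class.
#' @param class_names Class labels.
#' @param aa_class_means Named list class -> named amino-acid mean vector
#'   (g/100 g).
#' @param aa_protein_pct Named vector class -> crude protein percent.
#' @param aa_noise_cv Coefficient of variation of the log-normal
#'   measurement noise on amino-acid contents.
#' @param n_volatiles Number of volatile compounds per sample.
#' @param volatile_class_palette Chemical classes to draw compounds from.
#' @param internal_standard_conc Internal-standard concentration, ug/g.
#' @param n_reads_per_sample Amplicon reads per sample.
#' @param read_length_range Insert length range, bp (within [500, 3000]).
#' @param accuracy_dist `c(mean, sd)` of per-read predicted accuracy.
#' @param mutation_rate Per-base substitution rate applied to taxon
#'   templates when emitting reads.
#' @param decoy_fraction Fraction of reads made to fail QC (out-of-range
#'   length or sub-threshold accuracy), exercising filter boundaries.
#' @param n_taxa Number of taxa (amplicon templates / correlation rows).
#' @param n_metabolites Metabolite rows in the correlation dataset.
#' @param n_assoc_samples Paired samples in the correlation dataset.
#' @param planted_links Data frame `taxon`, `metabolite`, `sign` (+1/-1),
#'   `strength` in [0, 1]: monotone associations planted in the
#'   taxa/metabolite matrices.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_samples_per_class = 3,
                         class_names = c("BB", "MM", "CC"),
                         aa_class_means = default_aa_class_means(),
                         aa_protein_pct = c(BB = 18.40, MM = 25.08, CC = 22.07),
                         aa_noise_cv = 0.05,
                         n_volatiles = 40,
                         volatile_class_palette = setdiff(volatile_classes(), "other"),
                         internal_standard_conc = 0.0275,
                         n_reads_per_sample = 150,
                         read_length_range = c(1400, 1800),
                         accuracy_dist = c(mean = 0.98, sd = 0.03),
                         mutation_rate = 0.005,
                         decoy_fraction = 0,
                         n_taxa = 6,
                         n_metabolites = 10,
                         n_assoc_samples = 30,
                         planted_links = data.frame(
                           taxon = c("taxon_01", "taxon_02"),
                           metabolite = c("metab_01", "metab_02"),
                           sign = c(1, -1), strength = c(0.9, 0.9),
                           stringsAsFactors = FALSE)) {
  cfg <- list(seed = as.integer(seed), n_samples_per_class = n_samples_per_class,
              class_names = class_names, aa_class_means = aa_class_means,
              aa_protein_pct = aa_protein_pct, aa_noise_cv = aa_noise_cv,
              n_volatiles = n_volatiles,
              volatile_class_palette = volatile_class_palette,
              internal_standard_conc = internal_standard_conc,
              n_reads_per_sample = n_reads_per_sample,
              read_length_range = read_length_range,
              accuracy_dist = accuracy_dist, mutation_rate = mutation_rate,
              decoy_fraction = decoy_fraction, n_taxa = n_taxa,
              n_metabolites = n_metabolites, n_assoc_samples = n_assoc_samples,
              planted_links = planted_links)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (!setequal(names(cfg$aa_class_means), cfg$class_names))
    add("aa_class_means must have exactly one entry per class")
  for (cl in names(cfg$aa_class_means)) {
    bad <- setdiff(names(cfg$aa_class_means[[cl]]), aa_codes())
    if (length(bad))
      add(paste0("unknown amino-acid code(s) in class '", cl, "': ",
                 paste(bad, collapse = ", ")))
  }
  if (cfg$aa_noise_cv < 0) add("aa_noise_cv must be >= 0")
  if (cfg$n_volatiles < 1) add("n_volatiles must be >= 1")
  if (!all(cfg$volatile_class_palette %in% volatile_classes()))
    add("volatile_class_palette outside controlled vocabulary")
  if (cfg$internal_standard_conc <= 0) add("internal_standard_conc must be > 0")
  rng <- cfg$read_length_range
  if (length(rng) != 2 || rng[1] >= rng[2]) add("read_length_range must be (min, max) with min < max")
  if (rng[1] < 500 || rng[2] > 3000) add("read_length_range must lie within [500, 3000]")
  if (cfg$decoy_fraction < 0 || cfg$decoy_fraction > 1) add("decoy_fraction must lie in [0, 1]")
  pl <- cfg$planted_links
  if (nrow(pl)) {
    if (any(pl$strength < 0 | pl$strength > 1)) add("planted link strengths must lie in [0, 1]")
    if (!all(pl$sign %in% c(-1, 1))) add("planted link signs must be +1 or -1")
    taxa_names <- sprintf("taxon_%02d", seq_len(cfg$n_taxa))
    metab_names <- sprintf("metab_%02d", seq_len(cfg$n_metabolites))
    if (!all(pl$taxon %in% taxa_names)) add("planted link references unknown taxon")
    if (!all(pl$metabolite %in% metab_names)) add("planted link references unknown metabolite")
    if (anyDuplicated(pl$metabolite)) add("each metabolite may appear in at most one planted link")
  }
  if (length(errs)) stop("invalid synth_config:\n  - ", paste(errs, collapse = "\n  - "))
  invisible(cfg)
}

# log-normal draw with arithmetic mean m and coefficient of variation cv
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

synth_sample_ids <- function(cfg) {
  unlist(lapply(cfg$class_names, function(cl)
    sprintf("%s_%d", cl, seq_len(cfg$n_samples_per_class))))
}

#' Generate per-sample amino-acid profiles
#'
#' Draws each sample's 17 amino-acid contents from a log-normal
#' distribution around its class mean with coefficient of variation
#' `aa_noise_cv` (zero noise reproduces the class means exactly).
#'
#' @param config A [synth_config()].
#' @return List: `profiles` (list of [aa_profile()]), `table` (long data
#'   frame `sample_id`, `class`, `aa_code`, `g_per_100g`).
#' @export
gen_amino_acid_profiles <- function(config) {
  with_seed(config$seed + 101L, {
    rows <- list(); profiles <- list()
    for (cl in config$class_names) {
      means <- config$aa_class_means[[cl]][aa_codes()]
      for (i in seq_len(config$n_samples_per_class)) {
        sid <- sprintf("%s_%d", cl, i)
        contents <- vapply(means, function(m) rlnorm_cv(1, m, config$aa_noise_cv),
                           numeric(1))
        profiles[[sid]] <- aa_profile(sid, contents, config$aa_protein_pct[[cl]])
        rows[[sid]] <- data.frame(sample_id = sid, class = cl,
                                  aa_code = names(contents),
                                  g_per_100g = unname(contents),
                                  stringsAsFactors = FALSE)
      }
    }
    list(profiles = profiles, table = do.call(rbind, c(rows, make.row.names = FALSE)))
  })
}

#' Generate a volatile peak table with a 2-octanol internal standard
#'
#' Each sample gets `n_volatiles` compound rows (classes cycling through the
#' palette) plus one internal-standard row. True concentrations are drawn
#' log-normally per compound with a class-level multiplier; peak areas are
#' constructed as the exact inverse of the internal-standard quantification
#' formula (`Ac = Ais * C / Cis`), so quantification recovers the planted
#' truth exactly.
#'
#' @param config A [synth_config()].
#' @return Peak-table data frame `sample_id`, `compound`, `chemical_class`,
#'   `peak_area`; the planted concentrations are in the `truth` attribute
#'   (`sample_id`, `compound`, `true_conc_ug_per_g`).
#' @export
gen_volatile_table <- function(config) {
  with_seed(config$seed + 202L, {
    compounds <- sprintf("compound_%02d", seq_len(config$n_volatiles))
    classes <- rep_len(config$volatile_class_palette, config$n_volatiles)
    base_conc <- rlnorm_cv(config$n_volatiles, 0.5, 0.8)
    sample_ids <- synth_sample_ids(config)
    class_of <- rep(config$class_names, each = config$n_samples_per_class)
    class_fx <- stats::setNames(rlnorm_cv(length(config$class_names), 1, 0.4),
                                config$class_names)
    rows <- list(); truth <- list()
    for (k in seq_along(sample_ids)) {
      sid <- sample_ids[k]
      conc <- rlnorm_cv(config$n_volatiles, 1, 0.3) * base_conc * class_fx[[class_of[k]]]
      ais <- rlnorm_cv(1, 1e6, 0.1)
      rows[[sid]] <- data.frame(
        sample_id = sid,
        compound = c(compounds, "2-octanol"),
        chemical_class = c(classes, "other"),
        peak_area = c(ais * conc / config$internal_standard_conc, ais),
        stringsAsFactors = FALSE)
      truth[[sid]] <- data.frame(sample_id = sid, compound = compounds,
                                 true_conc_ug_per_g = conc,
                                 stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(rows, make.row.names = FALSE))
    attr(out, "truth") <- do.call(rbind, c(truth, make.row.names = FALSE))
    out
  })
}

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate == 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  paste(bases, collapse = "")
}

#' Generate barcoded full-length amplicon reads with known taxonomy
#'
#' Builds one random template per taxon (length drawn from
#' `read_length_range`; independent random templates of this length are far
#' below any OTU identity threshold), assigns each sample a 16-base barcode,
#' and emits reads as barcode + mutated template + reverse-complemented
#' barcode with a truncated-normal predicted accuracy. A `decoy_fraction`
#' of reads is corrupted to fail QC: alternately truncated below the length
#' range or assigned sub-threshold accuracy.
#'
#' @param config A [synth_config()].
#' @return List: `reads` (`read_id`, `sequence`, `accuracy`), `truth`
#'   (`read_id`, `sample_id`, `genus`, `species`, `is_decoy`),
#'   `barcode_map` (named vector barcode -> sample_id), `templates`
#'   (`genus`, `species`, `sequence`).
#' @export
gen_amplicon_reads <- function(config) {
  with_seed(config$seed + 303L, {
    sample_ids <- synth_sample_ids(config)
    n_samples <- length(sample_ids)
    # fixed random barcode table derived from the seed; 16 bases each
    barcodes <- character(0)
    for (i in seq_len(n_samples)) {
      repeat {
        b <- random_dna(16)
        if (!b %in% barcodes) break
      }
      barcodes <- c(barcodes, b)
    }
    barcode_map <- stats::setNames(sample_ids, barcodes)

    tmpl_len <- sample(seq(config$read_length_range[1], config$read_length_range[2]),
                       config$n_taxa, replace = TRUE)
    templates <- data.frame(
      genus = sprintf("Genus%s", LETTERS[seq_len(config$n_taxa)]),
      species = sprintf("Genus%s sp%d", LETTERS[seq_len(config$n_taxa)],
                        seq_len(config$n_taxa)),
      sequence = vapply(tmpl_len, random_dna, character(1)),
      stringsAsFactors = FALSE)

    reads <- list(); truth <- list(); rid <- 0L
    for (k in seq_len(n_samples)) {
      # sample-specific taxon abundances (Dirichlet via gamma)
      w <- stats::rgamma(config$n_taxa, shape = 2)
      probs <- w / sum(w)
      taxa <- sample.int(config$n_taxa, config$n_reads_per_sample,
                         replace = TRUE, prob = probs)
      n_decoy <- round(config$decoy_fraction * config$n_reads_per_sample)
      decoy <- seq_len(config$n_reads_per_sample) <= n_decoy
      for (r in seq_len(config$n_reads_per_sample)) {
        rid <- rid + 1L
        insert <- mutate_seq(templates$sequence[taxa[r]], config$mutation_rate)
        acc <- min(1, max(0, stats::rnorm(1, config$accuracy_dist[["mean"]],
                                          config$accuracy_dist[["sd"]])))
        if (decoy[r]) {
          if (r %% 2 == 0) {
            insert <- substr(insert, 1, config$read_length_range[1] - 50)
          } else {
            acc <- stats::runif(1, 0.5, 0.89)
          }
        }
        reads[[rid]] <- data.frame(
          read_id = sprintf("read_%06d", rid),
          sequence = paste0(barcodes[k], insert, revcomp(barcodes[k])),
          accuracy = acc, stringsAsFactors = FALSE)
        truth[[rid]] <- data.frame(
          read_id = sprintf("read_%06d", rid), sample_id = sample_ids[k],
          genus = templates$genus[taxa[r]], species = templates$species[taxa[r]],
          is_decoy = decoy[r], stringsAsFactors = FALSE)
      }
    }
    list(reads = do.call(rbind, c(reads, make.row.names = FALSE)),
         truth = do.call(rbind, c(truth, make.row.names = FALSE)),
         barcode_map = barcode_map, templates = templates)
  })
}

#' Generate taxa and metabolite matrices with planted monotone links
#'
#' Latent Gaussian copula: each taxon has a standard-normal latent vector;
#' a planted link with strength s builds the metabolite's latent as
#' `sign * (s * z_taxon + sqrt(1 - s^2) * noise)`, so the latent Pearson
#' correlation is `sign * s` and the Spearman correlation of the observed
#' (exponentiated, hence monotone) abundances increases with s, reaching
#' exactly +/-1 at s = 1. Unlinked metabolites are independent.
#'
#' @param config A [synth_config()].
#' @return List: `taxa` (taxa x sample positive abundance matrix),
#'   `taxa_pct` (columns normalized to 100), `metabolites`
#'   (metabolite x sample matrix), `links` (the planted-link table).
#' @export
gen_taxa_metabolite_dataset <- function(config) {
  with_seed(config$seed + 404L, {
    n <- config$n_assoc_samples
    taxa_names <- sprintf("taxon_%02d", seq_len(config$n_taxa))
    metab_names <- sprintf("metab_%02d", seq_len(config$n_metabolites))
    z_taxa <- matrix(stats::rnorm(config$n_taxa * n), nrow = config$n_taxa,
                     dimnames = list(taxa_names, sprintf("S%02d", seq_len(n))))
    z_met <- matrix(stats::rnorm(config$n_metabolites * n),
                    nrow = config$n_metabolites,
                    dimnames = list(metab_names, colnames(z_taxa)))
    pl <- config$planted_links
    for (i in seq_len(nrow(pl))) {
      s <- pl$strength[i]
      zt <- z_taxa[pl$taxon[i], ]
      z_met[pl$metabolite[i], ] <- pl$sign[i] * (s * zt + sqrt(1 - s^2) * z_met[pl$metabolite[i], ])
    }
    taxa <- exp(1 + 0.8 * z_taxa)
    metab <- exp(0.5 + 0.6 * z_met)
    taxa_pct <- sweep(taxa, 2, colSums(taxa), "/") * 100
    list(taxa = taxa, taxa_pct = taxa_pct, metabolites = metab, links = pl)
  })
}
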