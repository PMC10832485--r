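#' Configure an end-to-end analysis run
#'
#' @param synth A [synth_config()] driving the synthetic inputs.
#' @param stages Character vector of stages to run, a subset of
#'   `c("amino_acids", "volatiles", "community", "correlation")`.
#' @param cis Internal-standard concentration, ug/g.
#' @param qc Named list `min_len`, `max_len`, `min_acc` for read QC.
#' @param otu_identity OTU clustering identity in (0, 1].
#' @param dominant_min_pct Strict dominance threshold, percent.
#' @param cor_method `"spearman"` or `"pearson"`.
#' @param rho_threshold,p_threshold Network edge rule.
#' @param outdir Optional directory; when given, stage tables are written
#'   there as TSV.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            stages = c("amino_acids", "volatiles", "community",
                                       "correlation"),
                            cis = synth$internal_standard_conc,
                            qc = list(min_len = 1400, max_len = 1800, min_acc = 0.90),
                            otu_identity = 0.97,
                            dominant_min_pct = 1.0,
                            cor_method = "spearman",
                            rho_threshold = 0.6, p_threshold = 0.05,
                            outdir = NULL) {
  cfg <- list(synth = synth, stages = stages, cis = cis, qc = qc,
              otu_identity = otu_identity, dominant_min_pct = dominant_min_pct,
              cor_method = cor_method, rho_threshold = rho_threshold,
              p_threshold = p_threshold, outdir = outdir)
  errs <- character(0)
  known <- c("amino_acids", "volatiles", "community", "correlation")
  if (!all(stages %in% known))
    errs <- c(errs, paste("unknown stage(s):", paste(setdiff(stages, known), collapse = ", ")))
  if (!inherits(synth, "synth_config")) errs <- c(errs, "synth must be a synth_config")
  if (cis <= 0) errs <- c(errs, "cis must be > 0")
  if (otu_identity <= 0 || otu_identity > 1) errs <- c(errs, "otu_identity must lie in (0, 1]")
  if (rho_threshold < 0 || rho_threshold > 1) errs <- c(errs, "rho_threshold must lie in [0, 1]")
  if (p_threshold <= 0 || p_threshold > 1) errs <- c(errs, "p_threshold must lie in (0, 1]")
  if (!cor_method %in% c("spearman", "pearson")) errs <- c(errs, "unknown cor_method")
  if (length(errs)) stop("invalid pipeline_config:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis chain on synthetic inputs
#'
#' Executes the enabled stages in dependency order — input generation, then
#' amino-acid scoring, volatile quantification and community profiling, then
#' taxa-metabolite correlation — and collects per-stage summaries into a
#' report. The report carries a provenance block (config hash, seed) and is
#' byte-identical across runs of the same configuration.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list with one section per enabled stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(provenance = list(config_hash = object_hash(unclass(config)),
                                   seed = config$synth$seed,
                                   stages = config$stages))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  emit <- function(x, name) {
    if (!is.null(outdir)) write_tsv(x, file.path(outdir, paste0(name, ".tsv")))
  }

  if ("amino_acids" %in% config$stages) {
    aa <- gen_amino_acid_profiles(config$synth)
    evals <- lapply(aa$profiles, evaluate_amino_acids)
    tab <- do.call(rbind, lapply(evals, function(e) data.frame(
      sample_id = e$sample_id, taa = e$taa, eaa_taa_pct = e$eaa_taa_pct,
      eaa_neaa_pct = e$eaa_neaa_pct, src = e$src, limiting_aa = e$limiting_aa,
      closeness_mu = e$closeness_mu, stringsAsFactors = FALSE)))
    rownames(tab) <- NULL
    emit(aa$table, "amino_acid_profiles"); emit(tab, "amino_acid_evaluation")
    report$amino_acids <- list(evaluation = tab, details = evals)
  }

  if ("volatiles" %in% config$stages) {
    peaks <- gen_volatile_table(config$synth)
    quant <- quantify_volatiles(peaks, cis = config$cis)
    classes <- aggregate_classes(quant)
    major <- filter_relative(quant, min_pct = 1.0)
    comparison <- compare_samples(quant)
    emit(quant, "volatile_quant"); emit(classes, "volatile_classes")
    emit(major, "volatile_major")
    report$volatiles <- list(quant = quant, classes = classes, major = major,
                             shared = comparison$shared,
                             unique_counts = comparison$unique_counts)
  }

  if ("community" %in% config$stages) {
    amp <- gen_amplicon_reads(config$synth)
    dm <- demultiplex(amp$reads, amp$barcode_map)
    qc <- qc_filter(dm$reads, config$qc$min_len, config$qc$max_len, config$qc$min_acc)
    otu <- build_otu_table(qc$reads, identity = config$otu_identity,
                           truth = amp$truth)
    otu$otus <- remove_chimeras(otu$otus)
    genus <- relative_abundance(otu$counts, otu$taxonomy, rank = "genus")
    dom <- dominant_taxa(genus$average, min_pct = config$dominant_min_pct)
    shannon <- shannon_index(otu$counts)
    depth <- min(colSums(otu$counts))
    rare <- rarefaction_curve(otu$counts,
                              depths = unique(pmin(depth, c(10, 25, 50, depth))),
                              n_reps = 50, seed = config$synth$seed)
    emit(dom, "dominant_taxa"); emit(rare, "rarefaction")
    report$community <- list(
      n_unassigned = dm$n_unassigned, qc_stats = qc$stats,
      n_otus = nrow(otu$otus), counts = otu$counts, taxonomy = otu$taxonomy,
      genus_pct = genus$pct, genus_average = genus$average,
      dominant = dom, shannon = shannon, rarefaction = rare)
  }

  if ("correlation" %in% config$stages) {
    ds <- gen_taxa_metabolite_dataset(config$synth)
    kept <- filter_taxa(ds$taxa_pct, min_pct = 0.1)
    cor_res <- correlate_features(ds$taxa, ds$metabolites,
                                  method = config$cor_method)
    net <- build_network(ds$taxa, rho_threshold = config$rho_threshold,
                         p_threshold = config$p_threshold,
                         method = config$cor_method)
    deg <- network_degrees(net)
    hits <- which(cor_res$stars != "", arr.ind = TRUE)
    hit_tab <- data.frame(taxon = rownames(cor_res$rho)[hits[, 1]],
                          metabolite = colnames(cor_res$rho)[hits[, 2]],
                          rho = cor_res$rho[hits], p = cor_res$p[hits],
                          stars = cor_res$stars[hits], stringsAsFactors = FALSE)
    hit_tab <- hit_tab[order(hit_tab$p), , drop = FALSE]; rownames(hit_tab) <- NULL
    emit(hit_tab, "correlation_hits"); emit(deg, "network_degrees")
    report$correlation <- list(n_taxa_kept = nrow(kept), result = cor_res,
                               hits = hit_tab, degrees = deg,
                               n_edges = igraph::ecount(net))
  }

  structure(report, class = "run_report")
}

#' Render a pipeline report
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param format `"json"` (machine-readable; matrices as data frames) or
#'   `"text"` (human-readable summary with the headline tables).
#' @return A JSON string or a character vector of text lines.
#' @export
render_report <- function(report, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "run_report"))
  if (format == "json") {
    slim <- report
    if (!is.null(slim$amino_acids)) slim$amino_acids$details <- NULL
    for (sec in c("community", "correlation")) {
      if (!is.null(slim[[sec]])) {
        slim[[sec]] <- lapply(slim[[sec]], function(x) {
          if (is.matrix(x)) as.data.frame(x) else x
        })
      }
    }
    return(jsonlite::toJSON(unclass(slim), auto_unbox = TRUE, digits = NA,
                            pretty = TRUE))
  }
  lines <- c(sprintf("Pipeline report (seed %d, config %s)",
                     report$provenance$seed, report$provenance$config_hash))
  if (!is.null(report$amino_acids)) {
    e <- report$amino_acids$evaluation
    lines <- c(lines, "", "Amino-acid evaluation:",
               sprintf("  %s: TAA %.2f g/100g, EAA/TAA %.2f%%, SRC %.1f, limiting %s, mu %.3f",
                       e$sample_id, e$taa, e$eaa_taa_pct, e$src, e$limiting_aa,
                       e$closeness_mu))
  }
  if (!is.null(report$volatiles)) {
    cl <- report$volatiles$classes
    per_sample <- tapply(cl$n_compounds, cl$sample_id, sum)
    lines <- c(lines, "", "Volatiles:",
               sprintf("  %s: %d compounds, %d above 1%%", names(per_sample),
                       as.integer(per_sample),
                       as.integer(table(factor(report$volatiles$major$sample_id,
                                               levels = names(per_sample))))))
  }
  if (!is.null(report$community)) {
    cm <- report$community
    lines <- c(lines, "", sprintf("Community: %d OTUs; %d reads unassigned; QC pass %d/%d",
                                  cm$n_otus, cm$n_unassigned,
                                  cm$qc_stats$n_pass, cm$qc_stats$n_input),
               sprintf("  Shannon: %s",
                       paste(sprintf("%s=%.3f", names(cm$shannon), cm$shannon),
                             collapse = ", ")),
               "  Dominant taxa (>1%):",
               if (nrow(cm$dominant)) sprintf("    %s %.2f%% (cum %.2f%%)",
                                              cm$dominant$taxon, cm$dominant$pct,
                                              cm$dominant$cumulative_pct)
               else "    (none)")
  }
  if (!is.null(report$correlation)) {
    co <- report$correlation
    lines <- c(lines, "", sprintf("Correlation: %d starred pairs; network edges %d",
                                  nrow(co$hits), co$n_edges),
               if (nrow(co$hits)) sprintf("    %s ~ %s rho=%.2f p=%.2g %s",
                                          co$hits$taxon, co$hits$metabolite,
                                          co$hits$rho, co$hits$p, co$hits$stars)
               else "    (no significant pairs)",
               "  Top degrees:",
               sprintf("    %s: %d", utils::head(co$degrees$taxon, 5),
                       utils::head(co$degrees$degree, 5)))
  }
  lines
}
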