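#' Controlled vocabulary of volatile chemical classes
#' @return Character vector of class labels.
#' @export
volatile_classes <- function() {
  c("acid", "aldehyde", "alcohol", "ester", "phenol", "ketone",
    "sulfur", "heterocycle", "other")
}

# Compound identity matching across samples: case-fold and collapse
# whitespace; no spectral matching.
normalize_compound <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Internal-standard semi-quantification of volatile peak areas
#'
#' Converts GC-MS peak areas to concentrations against a spiked internal
#' standard of known concentration: for each analyte,
#' `C = (Ac / Ais) * Cis`, where Ac is the analyte's peak area and Ais the
#' internal standard's peak area in the same sample. The internal-standard
#' row (2-octanol by default) is consumed and excluded from the output;
#' relative percentages are computed over analyte concentrations within each
#' sample.
#'
#' @param peaks Data frame with columns `sample_id`, `compound`,
#'   `chemical_class`, `peak_area`; exactly one internal-standard row per
#'   sample.
#' @param cis Internal-standard concentration in the sample matrix, ug/g.
#'   The bundled default 0.0275 corresponds to 0.14 ug of standard spiked
#'   into about 5.1 mL of extract and is an assumption to be overridden with
#'   the true spike level when known.
#' @param is_name Internal-standard compound name (matched after
#'   case/whitespace normalization).
#' @return Data frame `sample_id`, `compound`, `chemical_class`,
#'   `conc_ug_per_g`, `rel_pct` (per-sample percentages summing to 100).
#' @export
quantify_volatiles <- function(peaks, cis = 0.0275, is_name = "2-octanol") {
  need <- c("sample_id", "compound", "chemical_class", "peak_area")
  missing <- setdiff(need, names(peaks))
  if (length(missing)) stop("peak table lacks column(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(cis) || cis <= 0) stop("internal-standard concentration must be > 0")
  if (any(peaks$peak_area < 0)) stop("peak areas must be >= 0")

  is_row <- normalize_compound(peaks$compound) == normalize_compound(is_name)
  out <- lapply(split(seq_len(nrow(peaks)), peaks$sample_id), function(idx) {
    is_idx <- idx[is_row[idx]]
    if (length(is_idx) == 0) {
      stop("sample '", peaks$sample_id[idx[1]], "' has no internal-standard row")
    }
    if (length(is_idx) > 1) {
      stop("sample '", peaks$sample_id[idx[1]], "' has duplicate internal-standard rows")
    }
    ais <- peaks$peak_area[is_idx]
    if (ais == 0) stop("internal-standard peak area is zero in sample '",
                       peaks$sample_id[idx[1]], "'")
    cmp <- setdiff(idx, is_idx)
    conc <- peaks$peak_area[cmp] / ais * cis
    total <- sum(conc)
    data.frame(sample_id = peaks$sample_id[cmp],
               compound = peaks$compound[cmp],
               chemical_class = peaks$chemical_class[cmp],
               conc_ug_per_g = conc,
               rel_pct = if (total > 0) 100 * conc / total else rep(0, length(conc)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample chemical-class counts and totals
#'
#' @param q Quantified volatile table from [quantify_volatiles()].
#' @param classes Allowed class vocabulary.
#' @return Data frame `sample_id`, `chemical_class`, `n_compounds`,
#'   `total_conc_ug_per_g`; per-sample counts sum to the sample's compound
#'   total.
#' @export
aggregate_classes <- function(q, classes = volatile_classes()) {
  bad <- setdiff(unique(q$chemical_class), classes)
  if (length(bad)) stop("unknown chemical class(es): ", paste(bad, collapse = ", "))
  if (nrow(q) == 0) {
    return(data.frame(sample_id = character(), chemical_class = character(),
                      n_compounds = integer(), total_conc_ug_per_g = numeric(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(conc_ug_per_g ~ sample_id + chemical_class, data = q,
                          FUN = function(x) c(n = length(x), total = sum(x)))
  data.frame(sample_id = agg$sample_id,
             chemical_class = agg$chemical_class,
             n_compounds = as.integer(agg$conc_ug_per_g[, "n"]),
             total_conc_ug_per_g = agg$conc_ug_per_g[, "total"],
             stringsAsFactors = FALSE)
}

#' Keep volatiles above a relative-abundance percentage
#'
#' Strict threshold ("surpassing"): rows at exactly `min_pct` are dropped.
#' Result ordered by descending relative percentage.
#'
#' @param q Quantified volatile table.
#' @param min_pct Threshold, percent (default 1).
#' @return Filtered, reordered table (possibly empty).
#' @export
filter_relative <- function(q, min_pct = 1.0) {
  keep <- q[q$rel_pct > min_pct, , drop = FALSE]
  keep <- keep[order(-keep$rel_pct), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Presence/absence comparison of volatile sets across samples
#'
#' @param q Quantified volatile table covering two or more samples.
#' @return List with `presence` (compound x sample logical matrix, compound
#'   names normalized), `shared` (sample-pair data frame with shared-compound
#'   counts), `unique_counts` (named vector of compounds found in exactly one
#'   sample, per sample).
#' @export
compare_samples <- function(q) {
  samples <- unique(q$sample_id)
  if (length(samples) < 2) stop("need at least two samples to compare")
  key <- normalize_compound(q$compound)
  compounds <- sort(unique(key))
  presence <- vapply(samples, function(s) compounds %in% key[q$sample_id == s],
                     logical(length(compounds)))
  presence <- matrix(presence, nrow = length(compounds),
                     dimnames = list(compounds, samples))
  pairs <- utils::combn(samples, 2)
  shared <- data.frame(sample_a = pairs[1, ], sample_b = pairs[2, ],
                       n_shared = apply(pairs, 2, function(p) {
                         sum(presence[, p[1]] & presence[, p[2]])
                       }), stringsAsFactors = FALSE)
  in_n <- rowSums(presence)
  unique_counts <- vapply(samples, function(s) sum(presence[, s] & in_n == 1L),
                          integer(1))
  list(presence = presence, shared = shared, unique_counts = unique_counts)
}
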