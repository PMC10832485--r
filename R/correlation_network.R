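#' Drop taxa whose mean relative abundance does not exceed a threshold
#'
#' Strict threshold ("higher than"): taxa whose cross-sample mean percentage
#' equals `min_pct` are dropped along with everything below.
#'
#' @param pct Taxa x sample matrix of relative abundances (percent).
#' @param min_pct Strict mean-percentage threshold (default 0.1).
#' @return The filtered matrix.
#' @export
filter_taxa <- function(pct, min_pct = 0.1) {
  pct[rowMeans(pct) > min_pct, , drop = FALSE]
}

star_label <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

# rho and two-sided p for one pair; exact permutation p for small n without
# ties, t-approximation otherwise. Constant vectors yield NA.
cor_pair <- function(x, y, method, exact_n = 8) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(rho = NA_real_, p = NA_real_))
  }
  exact <- method == "spearman" && length(x) <= exact_n &&
    !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = exact, alternative = "two.sided"))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Correlate taxa with metabolites
#'
#' Pairwise Spearman (default) or Pearson correlation of every taxon row
#' against every metabolite row across paired samples, with two-sided
#' p-values (exact permutation null for n <= 8 untied samples, t
#' approximation otherwise), significance stars at p < 0.05 / 0.01 / 0.001,
#' and optional Benjamini-Hochberg adjustment (off by default — heatmap
#' stars conventionally use raw p).
#'
#' @param taxa Taxa x sample numeric matrix.
#' @param metabolites Metabolite x sample numeric matrix, same sample
#'   columns in the same order.
#' @param method `"spearman"` or `"pearson"`.
#' @param adjust Add a BH-adjusted p matrix.
#' @return List of matrices `rho`, `p`, `stars` (and `p_adj` when
#'   requested); constant rows give NA entries.
#' @export
correlate_features <- function(taxa, metabolites, method = c("spearman", "pearson"),
                               adjust = FALSE) {
  method <- match.arg(method)
  if (ncol(taxa) != ncol(metabolites)) stop("sample columns do not match")
  if (ncol(taxa) < 3) stop("need at least 3 paired samples")
  rho <- p <- matrix(NA_real_, nrow(taxa), nrow(metabolites),
                     dimnames = list(rownames(taxa), rownames(metabolites)))
  for (i in seq_len(nrow(taxa))) {
    for (j in seq_len(nrow(metabolites))) {
      r <- cor_pair(taxa[i, ], metabolites[j, ], method)
      rho[i, j] <- r["rho"]; p[i, j] <- r["p"]
    }
  }
  out <- list(rho = rho, p = p, stars = matrix(star_label(p), nrow(rho),
                                               dimnames = dimnames(rho)))
  if (adjust) {
    out$p_adj <- matrix(stats::p.adjust(p, method = "BH"), nrow(rho),
                        dimnames = dimnames(rho))
  }
  out
}

#' Build a taxa co-occurrence network
#'
#' Correlates taxa rows pairwise and connects pairs whose correlation passes
#' `|rho| >= rho_threshold` and `p < p_threshold` (both configurable; the
#' defaults 0.6 and 0.05 are conventional, not derived from data). The graph
#' is undirected and simple; nodes carry their mean relative abundance.
#'
#' @param pct Taxa x sample relative-abundance matrix (ideally already
#'   through [filter_taxa()]).
#' @param rho_threshold Minimum absolute correlation in [0, 1].
#' @param p_threshold Maximum p-value in (0, 1].
#' @param method Correlation method.
#' @return An igraph graph with edge attributes `rho`, `p` and vertex
#'   attribute `mean_abundance`.
#' @export
build_network <- function(pct, rho_threshold = 0.6, p_threshold = 0.05,
                          method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (rho_threshold < 0 || rho_threshold > 1) stop("rho_threshold must lie in [0, 1]")
  if (p_threshold <= 0 || p_threshold > 1) stop("p_threshold must lie in (0, 1]")
  if (ncol(pct) < 3) stop("need at least 3 samples")
  taxa <- rownames(pct)
  g <- igraph::make_empty_graph(n = length(taxa), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = taxa)
  g <- igraph::set_vertex_attr(g, "mean_abundance", value = rowMeans(pct))
  edges <- list()
  n <- length(taxa)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- cor_pair(pct[i, ], pct[j, ], method)
        if (!is.na(r["rho"]) && abs(r["rho"]) >= rho_threshold && r["p"] < p_threshold) {
          edges[[length(edges) + 1]] <- data.frame(from = taxa[i], to = taxa[j],
                                                   rho = unname(r["rho"]),
                                                   p = unname(r["p"]))
        }
      }
    }
  }
  if (length(edges)) {
    ed <- do.call(rbind, edges)
    g <- igraph::add_edges(g, as.vector(rbind(ed$from, ed$to)),
                           rho = ed$rho, p = ed$p)
  }
  g
}

#' Node degrees of a co-occurrence network
#'
#' @param net An igraph graph from [build_network()].
#' @return Data frame `taxon`, `degree`, sorted by descending degree, ties
#'   alphabetical.
#' @export
network_degrees <- function(net) {
  d <- igraph::degree(net)
  out <- data.frame(taxon = names(d), degree = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a network as an edge-list TSV and GraphML
#'
#' @param net igraph graph.
#' @param edge_path Edge-list TSV path (`node1`, `node2`, `rho`, `p`).
#' @param graphml_path Optional GraphML path.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  ed <- igraph::as_data_frame(net, what = "edges")
  names(ed)[1:2] <- c("node1", "node2")
  write_tsv(ed, edge_path)
  if (!is.null(graphml_path)) igraph::write_graph(net, graphml_path, format = "graphml")
  invisible(edge_path)
}
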