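#' Demultiplex amplicon reads by exact 5' barcode match
#'
#' A read is assigned to a sample when its first 16 bases exactly match a
#' sample barcode (no mismatch tolerance, keeping the stage deterministic);
#' the barcode is stripped from the 5' end, and also from the 3' end when
#' the terminal 16-mer equals the barcode or its reverse complement (the tag
#' is ligated to both ends of the amplicon).
#'
#' @param reads Data frame with columns `read_id`, `sequence`, `accuracy`.
#' @param barcode_map Named character vector: names are 16-base barcodes,
#'   values are sample ids.
#' @return List: `reads` (assigned reads with `sample_id`, barcodes
#'   stripped), `n_unassigned`.
#' @export
demultiplex <- function(reads, barcode_map) {
  barcodes <- names(barcode_map)
  if (is.null(barcodes) || any(nchar(barcodes) != 16)) {
    stop("all barcodes must be 16 bases")
  }
  if (anyDuplicated(barcodes)) stop("duplicate barcode in barcode map")
  prefix <- substr(reads$sequence, 1, 16)
  hit <- match(prefix, barcodes)
  assigned <- !is.na(hit)
  out <- reads[assigned, , drop = FALSE]
  bc <- barcodes[hit[assigned]]
  seqs <- substr(out$sequence, 17, nchar(out$sequence))
  tail16 <- substr(seqs, nchar(seqs) - 15, nchar(seqs))
  strip_tail <- nchar(seqs) > 16 & (tail16 == bc | tail16 == revcomp(bc))
  seqs[strip_tail] <- substr(seqs[strip_tail], 1, nchar(seqs[strip_tail]) - 16)
  out$sequence <- seqs
  out$sample_id <- unname(barcode_map[hit[assigned]])
  rownames(out) <- NULL
  list(reads = out, n_unassigned = sum(!assigned))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Length and predicted-accuracy quality control
#'
#' A read survives when its length lies within `[min_len, max_len]`
#' (both ends inclusive) and its predicted accuracy is at least `min_acc`.
#'
#' @param reads Data frame with `sequence` and `accuracy` columns.
#' @param min_len,max_len Inclusive length bounds, bp.
#' @param min_acc Minimum per-read predicted accuracy, fraction.
#' @return List: `reads` (survivors), `stats` (n_input, n_pass,
#'   n_fail_length, n_fail_accuracy; a read failing both counts in both).
#' @export
qc_filter <- function(reads, min_len = 1400, max_len = 1800, min_acc = 0.90) {
  stopifnot(min_len > 0, max_len >= min_len, min_acc > 0)
  len <- nchar(reads$sequence)
  ok_len <- len >= min_len & len <= max_len
  ok_acc <- reads$accuracy >= min_acc
  keep <- ok_len & ok_acc
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out,
       stats = list(n_input = nrow(reads), n_pass = sum(keep),
                    n_fail_length = sum(!ok_len), n_fail_accuracy = sum(!ok_acc)))
}

#' Dereplicate reads at 100 % identity
#'
#' Exact-string grouping of sequences; the representative of each group is
#' the first-seen read. Output sorted by decreasing group size, ties broken
#' by sequence lexicographic order (the ordering greedy OTU clustering
#' expects).
#'
#' @param reads Data frame with a `sequence` column (and optionally
#'   `read_id`), or a character vector of sequences.
#' @return Data frame `sequence`, `size`, `rep_read_id`; the attribute
#'   `assignment` maps each input read to its output row. Sizes sum to the
#'   input read count.
#' @export
dereplicate <- function(reads) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = as.character(seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  }
  seqs <- reads$sequence
  first <- !duplicated(seqs)
  uniq <- seqs[first]
  idx <- match(seqs, uniq)
  size <- tabulate(idx, nbins = length(uniq))
  ord <- order(-size, uniq)
  out <- data.frame(sequence = uniq[ord], size = size[ord],
                    rep_read_id = (if (is.null(reads$read_id))
                      as.character(which(first)) else reads$read_id[first])[ord],
                    stringsAsFactors = FALSE)
  attr(out, "assignment") <- match(idx, ord)
  out
}

#' Global-alignment identity of query sequences to a centroid
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap -2 per
#' base, terminal gaps penalized) with identity defined as
#' matches / alignment columns. This definition is stated explicitly because
#' "97 % similarity" admits several; it is the one used throughout the OTU
#' clustering here.
#'
#' @param queries Character vector of query sequences.
#' @param centroid Single centroid sequence.
#' @return Numeric vector of identities in [0, 1].
#' @export
seq_identity <- function(queries, centroid) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE, type = "DNA")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(centroid),
    type = "global", substitutionMatrix = submat,
    gapOpening = 0, gapExtension = 2)
  ncols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / ncols
}

#' Greedy abundance-sorted centroid clustering of unique sequences
#'
#' UCLUST-style greedy scheme re-implemented from first principles: unique
#' sequences are visited in decreasing abundance (ties by lexicographic
#' sequence order); each query joins the first existing centroid whose
#' global-alignment identity reaches the threshold, otherwise it founds a
#' new centroid. Each OTU's representative is its centroid, a member of the
#' cluster by construction.
#'
#' @param uniques Dereplicated table from [dereplicate()] (`sequence`,
#'   `size`).
#' @param identity Identity threshold in (0, 1], default 0.97.
#' @return Data frame `otu_id`, `representative`, `size` (member read
#'   total); attribute `membership` maps rows of `uniques` (after abundance
#'   sorting, returned as attribute `order`) to OTU rows.
#' @export
cluster_otus <- function(uniques, identity = 0.97) {
  if (!is.numeric(identity) || identity <= 0 || identity > 1) {
    stop("identity threshold must lie in (0, 1]")
  }
  ord <- order(-uniques$size, uniques$sequence)
  seqs <- uniques$sequence[ord]
  sizes <- uniques$size[ord]
  centroid_idx <- integer(0)
  membership <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    if (length(centroid_idx)) {
      # identity is symmetric: score all current centroids against the query
      ident <- seq_identity(seqs[centroid_idx], seqs[i])
      hit <- which(ident >= identity)
    } else hit <- integer(0)
    if (length(hit)) {
      membership[i] <- hit[1]
    } else {
      centroid_idx <- c(centroid_idx, i)
      membership[i] <- length(centroid_idx)
    }
  }
  otu_size <- vapply(seq_along(centroid_idx),
                     function(k) sum(sizes[membership == k]), numeric(1))
  out <- data.frame(otu_id = sprintf("OTU%03d", seq_along(centroid_idx)),
                    representative = seqs[centroid_idx],
                    size = otu_size, stringsAsFactors = FALSE)
  memb_orig <- integer(length(seqs))
  memb_orig[ord] <- membership
  attr(out, "membership") <- memb_orig
  out
}

#' No-op chimera-removal hook
#'
#' Chimera detection is outside this package's scope; this hook keeps the
#' stage explicit in pipelines so a real implementation can be slotted in.
#'
#' @param otus OTU table.
#' @return The table, unchanged.
#' @export
remove_chimeras <- function(otus) otus

#' Build an OTU-by-sample count table from demultiplexed reads
#'
#' Dereplicates, clusters at the given identity, and tallies member reads
#' per sample. When a truth/annotation table is supplied, each OTU gets the
#' majority taxon among its member reads.
#'
#' @param reads Data frame `read_id`, `sequence`, `sample_id` (QC'd,
#'   demultiplexed).
#' @param identity OTU identity threshold.
#' @param truth Optional data frame `read_id`, `genus`, `species`.
#' @return List: `counts` (OTU x sample matrix), `otus` (cluster table),
#'   `taxonomy` (per-OTU `otu_id`, `genus`, `species`, or NULL).
#' @export
build_otu_table <- function(reads, identity = 0.97, truth = NULL) {
  derep <- dereplicate(reads)
  otus <- cluster_otus(derep, identity)
  read_unique <- attr(derep, "assignment")
  read_otu <- attr(otus, "membership")[read_unique]
  samples <- sort(unique(reads$sample_id))
  counts <- table(factor(otus$otu_id[read_otu], levels = otus$otu_id),
                  factor(reads$sample_id, levels = samples))
  counts <- matrix(as.integer(counts), nrow = nrow(otus),
                   dimnames = list(otus$otu_id, samples))
  taxonomy <- NULL
  if (!is.null(truth)) {
    tr <- truth[match(reads$read_id, truth$read_id), ]
    taxonomy <- do.call(rbind, lapply(seq_len(nrow(otus)), function(k) {
      members <- which(read_otu == k)
      lab <- paste(tr$genus[members], tr$species[members], sep = "\r")
      top <- names(sort(table(lab), decreasing = TRUE))[1]
      parts <- strsplit(top, "\r", fixed = TRUE)[[1]]
      data.frame(otu_id = otus$otu_id[k], genus = parts[1], species = parts[2],
                 stringsAsFactors = FALSE)
    }))
  }
  list(counts = counts, otus = otus, taxonomy = taxonomy)
}

#' Relative abundance report at a taxonomic rank
#'
#' @param counts OTU x sample count matrix.
#' @param taxonomy Per-OTU taxonomy (`otu_id`, `genus`, `species`) or NULL
#'   to report at OTU level.
#' @param rank `"genus"`, `"species"` or `"otu"`.
#' @return List: `pct` (taxon x sample matrix of percentages, columns sum to
#'   100), `average` (cross-sample mean percentage per taxon), `rank`.
#' @export
relative_abundance <- function(counts, taxonomy = NULL, rank = c("otu", "genus", "species")) {
  rank <- match.arg(rank)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  if (rank != "otu") {
    if (is.null(taxonomy)) stop("taxonomy labels required for rank '", rank, "'")
    lab <- taxonomy[[rank]][match(rownames(counts), taxonomy$otu_id)]
    if (rank == "species") lab <- paste(taxonomy$genus[match(rownames(counts), taxonomy$otu_id)], lab)
    counts <- rowsum(counts, lab)
  }
  pct <- sweep(counts, 2, totals, "/") * 100
  list(pct = pct, average = rowMeans(pct), rank = rank)
}

#' Dominant taxa above a relative-abundance threshold
#'
#' Taxa whose percentage strictly exceeds `min_pct`, in descending order
#' (ties alphabetical), with the running cumulative percentage.
#'
#' @param abundance Named numeric vector of percentages (one sample's column
#'   or the cross-sample average from [relative_abundance()]).
#' @param min_pct Strict threshold, percent.
#' @return Data frame `taxon`, `pct`, `cumulative_pct` (empty when nothing
#'   exceeds the threshold).
#' @export
dominant_taxa <- function(abundance, min_pct = 1.0) {
  keep <- abundance[abundance > min_pct]
  keep <- keep[order(-keep, names(keep))]
  data.frame(taxon = names(keep), pct = unname(keep),
             cumulative_pct = cumsum(unname(keep)), stringsAsFactors = FALSE)
}

#' Shannon diversity index
#'
#' `H = -sum p_i ln p_i` over taxa with nonzero counts (natural log).
#'
#' @param counts Count matrix (taxa x samples) or a single count vector.
#' @return Named numeric vector, one index per sample.
#' @export
shannon_index <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1, dimnames = list(NULL, "sample"))
  apply(counts, 2, function(x) {
    if (sum(x) == 0) stop("Shannon index undefined for an all-zero sample")
    p <- x[x > 0] / sum(x)
    -sum(p * log(p))
  })
}

#' Rarefaction curve by repeated subsampling without replacement
#'
#' @param counts OTU x sample count matrix.
#' @param depths Subsampling depths (each must not exceed every sample's
#'   total).
#' @param n_reps Replicates per depth.
#' @param seed RNG seed for reproducible curves.
#' @return Data frame `sample_id`, `depth`, `mean_otus`, `sd_otus`.
#' @export
rarefaction_curve <- function(counts, depths, n_reps = 100, seed = 1) {
  stopifnot(n_reps >= 1)
  with_seed(seed, {
    rows <- lapply(colnames(counts), function(s) {
      x <- counts[, s]
      pool <- rep(seq_along(x), x)
      if (any(depths > length(pool))) {
        stop("depth exceeds total count of sample '", s, "'")
      }
      do.call(rbind, lapply(depths, function(d) {
        obs <- vapply(seq_len(n_reps), function(i) {
          length(unique(sample(pool, d, replace = FALSE)))
        }, numeric(1))
        data.frame(sample_id = s, depth = d, mean_otus = mean(obs),
                   sd_otus = stats::sd(obs), stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
}
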