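# Fixtures and independent oracles shared across test files.

# A profile whose mg/g-protein EAA vector equals a reference pattern exactly
# (combined entries carried entirely by the first member; the second set to 0).
profile_matching_pattern <- function(ref, protein_pct = 20, sample_id = "ref") {
  filler <- stats::setNames(rep(0.5, length(aa_codes())), aa_codes())
  vals <- unclass(ref)
  for (code in names(vals)) {
    parts <- strsplit(code, "+", fixed = TRUE)[[1]]
    filler[parts[1]] <- vals[[code]] * protein_pct / 1000
    if (length(parts) > 1) filler[parts[-1]] <- 0
  }
  aa_profile(sample_id, filler, protein_pct)
}

# Random positive amino-acid profile.
random_profile <- function(sample_id = "r", protein_pct = 20) {
  aa_profile(sample_id,
             stats::setNames(stats::runif(length(aa_codes()), 0.1, 10), aa_codes()),
             protein_pct)
}

# Substitute bases of `seq` at 1-based positions, cycling through replacements
# different from the original base.
mutate_at <- function(seq, positions) {
  b <- strsplit(seq, "")[[1]]
  for (i in positions) b[i] <- setdiff(c("A", "C", "G", "T"), b[i])[1]
  paste(b, collapse = "")
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Independent greedy-clustering oracle: precomputes the full pairwise identity
# matrix, then walks the abundance-sorted list assigning each sequence to the
# first centroid meeting the threshold. Returns the membership partition in
# the same (sorted) order cluster_otus() uses internally.
oracle_greedy_cluster <- function(uniques, identity) {
  ord <- order(-uniques$size, uniques$sequence)
  seqs <- uniques$sequence[ord]
  n <- length(seqs)
  idm <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      idm[i, (i + 1):n] <- idm[(i + 1):n, i] <- seq_identity(seqs[(i + 1):n], seqs[i])
    }
  }
  centroids <- integer(0)
  memb <- integer(n)
  for (i in seq_len(n)) {
    hit <- centroids[idm[i, centroids] >= identity]
    if (length(hit)) memb[i] <- match(hit[1], centroids)
    else { centroids <- c(centroids, i); memb[i] <- length(centroids) }
  }
  memb_orig <- integer(n)
  memb_orig[ord] <- memb
  list(membership = memb_orig, n_otus = length(centroids))
}

# Closed-form expected number of distinct OTUs when drawing `d` reads without
# replacement from counts `x` (multivariate hypergeometric).
expected_distinct <- function(x, d) {
  N <- sum(x)
  sum(1 - exp(lchoose(N - x, d) - lchoose(N, d)))
}

# All n! permutations of 1:n as rows (recursive; used for exact-p oracles).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Tiny demultiplexed read table.
reads_df <- function(seqs, acc = rep(0.99, length(seqs)), sample_id = NULL) {
  out <- data.frame(read_id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
                    accuracy = acc, stringsAsFactors = FALSE)
  if (!is.null(sample_id)) out$sample_id <- sample_id
  out
}
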