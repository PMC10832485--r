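#' Write amplicon reads as FASTQ with an accuracy sidecar
#'
#' Emits Phred-33 FASTQ where every base of a read carries the quality
#' implied by the read's predicted accuracy (q = -10 log10(1 - acc), capped
#' at 40), plus a two-column TSV sidecar `read_id<TAB>accuracy` preserving
#' the exact per-read accuracy.
#'
#' @param reads Data frame `read_id`, `sequence`, `accuracy`.
#' @param fastq_path,sidecar_path Output paths.
#' @return `fastq_path`, invisibly.
#' @export
write_amplicon_fastq <- function(reads, fastq_path, sidecar_path) {
  q <- pmin(40L, as.integer(round(-10 * log10(pmax(1 - reads$accuracy, 1e-4)))))
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  quals <- Biostrings::PhredQuality(vapply(seq_len(nrow(reads)), function(i) {
    paste(rep(rawToChar(as.raw(q[i] + 33L)), nchar(reads$sequence[i])), collapse = "")
  }, character(1)))
  out <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
  Biostrings::writeQualityScaledXStringSet(out, fastq_path)
  write_tsv(data.frame(read_id = reads$read_id, accuracy = reads$accuracy),
            sidecar_path)
  invisible(fastq_path)
}

#' Read amplicon reads from FASTQ plus accuracy sidecar
#'
#' @param fastq_path FASTQ file.
#' @param sidecar_path TSV `read_id<TAB>accuracy`.
#' @return Data frame `read_id`, `sequence`, `accuracy`.
#' @export
read_amplicon_fastq <- function(fastq_path, sidecar_path) {
  seqs <- Biostrings::readDNAStringSet(fastq_path, format = "fastq")
  ids <- sub("\\s.*$", "", names(seqs))
  acc <- read_tsv(sidecar_path)
  m <- match(ids, acc$read_id)
  if (anyNA(m)) stop("sidecar lacks accuracy for ", sum(is.na(m)), " read(s)")
  data.frame(read_id = ids, sequence = as.character(seqs),
             accuracy = acc$accuracy[m], stringsAsFactors = FALSE)
}

#' Read amino-acid content tables (long or wide TSV)
#'
#' Long form has columns `sample_id`, `aa_code`, `g_per_100g`; wide form has
#' `sample_id` plus one column per amino-acid code. A `protein_pct` column
#' (wide) or a separate named vector supplies the protein basis.
#'
#' @param path TSV path.
#' @param protein_pct Named vector sample_id -> protein percent, used when
#'   the table has no `protein_pct` column.
#' @return List of [aa_profile()] objects, one per sample.
#' @export
read_aa_profiles <- function(path, protein_pct = NULL) {
  tab <- read_tsv(path)
  long <- all(c("sample_id", "aa_code", "g_per_100g") %in% names(tab))
  if (long) {
    split_tab <- split(tab, tab$sample_id)
    lapply(split_tab, function(d) {
      pp <- if (!is.null(d$protein_pct)) d$protein_pct[1] else protein_pct[[d$sample_id[1]]]
      aa_profile(d$sample_id[1], stats::setNames(d$g_per_100g, d$aa_code), pp)
    })
  } else {
    codes <- intersect(names(tab), aa_codes())
    lapply(seq_len(nrow(tab)), function(i) {
      pp <- if (!is.null(tab$protein_pct)) tab$protein_pct[i] else protein_pct[[tab$sample_id[i]]]
      aa_profile(tab$sample_id[i], unlist(tab[i, codes]), pp)
    })
  }
}
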