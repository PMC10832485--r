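#' The 17 acid-hydrolysis-measurable amino acids
#'
#' Standard three-letter codes for the amino acids quantified after HCl
#' hydrolysis. Tryptophan is destroyed by acid hydrolysis and is therefore
#' absent from the default set.
#'
#' @return Character vector of 17 amino-acid codes.
#' @export
aa_codes <- function() {
  c("Asp", "Thr", "Ser", "Glu", "Gly", "Ala", "Cys", "Val", "Met",
    "Ile", "Leu", "Tyr", "Phe", "Lys", "His", "Arg", "Pro")
}

#' Essential amino acids scored in hydrolysate profiles
#'
#' The seven classical essential amino acids measurable in an acid
#' hydrolysate (Trp excluded).
#'
#' @return Character vector of EAA codes.
#' @export
eaa_codes <- function() {
  c("Ile", "Leu", "Lys", "Met", "Phe", "Thr", "Val")
}

read_reference_tsv <- function(file) {
  path <- system.file("extdata", file, package = "maotofu", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reference amino-acid scoring patterns
#'
#' `who_fao_pattern()` returns the WHO/FAO (1973) essential amino-acid
#' requirement pattern and `egg_reference()` the whole-egg protein pattern,
#' both in mg per g protein. The sulfur (Met+Cys) and aromatic (Phe+Tyr)
#' pairs are combined entries, as in the original patterns. Both tables ship
#' as editable TSV files under `extdata/`.
#'
#' @return A `reference_pattern`: a named numeric vector (mg/g protein) with
#'   a `name` attribute.
#' @export
who_fao_pattern <- function() {
  tab <- read_reference_tsv("who_fao_1973_pattern.tsv")
  reference_pattern("WHO/FAO 1973", stats::setNames(tab$mg_per_g_protein, tab$code))
}

#' @rdname who_fao_pattern
#' @export
egg_reference <- function() {
  tab <- read_reference_tsv("egg_reference.tsv")
  reference_pattern("whole egg", stats::setNames(tab$mg_per_g_protein, tab$code))
}

#' Construct a reference scoring pattern
#'
#' @param name Label for the pattern.
#' @param values Named numeric vector, mg per g protein; names may be single
#'   codes or combined entries such as `"Met+Cys"`.
#' @return A `reference_pattern` object.
#' @export
reference_pattern <- function(name, values) {
  stopifnot(is.numeric(values), length(values) > 0, !is.null(names(values)))
  if (any(values <= 0)) stop("reference pattern values must be > 0")
  structure(values, name = name, class = c("reference_pattern", "numeric"))
}

#' Free amino-acid taste thresholds
#'
#' Taste (recognition) thresholds in mg per 100 g with taste class labels,
#' compiled from the free amino-acid taste literature. Values for Tyr and Cys
#' are weak/tasteless placeholders; the table is an editable TSV under
#' `extdata/` and can be replaced wholesale.
#'
#' @return Data frame with columns `code`, `threshold_mg_per_100g`,
#'   `taste_class`.
#' @export
taste_thresholds <- function() {
  tab <- read_reference_tsv("taste_thresholds.tsv")
  stopifnot(all(tab$threshold_mg_per_100g > 0))
  tab
}
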