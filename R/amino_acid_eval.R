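#' Construct an amino-acid profile for one sample
#'
#' Holds the measured contents of the (by default 17) acid-hydrolysis
#' amino acids in g per 100 g sample, together with the sample's crude
#' protein percentage, which is the basis for converting contents to
#' mg per g protein when scoring against a reference pattern.
#'
#' @param sample_id Sample label.
#' @param contents Named numeric vector, g per 100 g sample, one entry per
#'   amino-acid code.
#' @param protein_pct Crude protein content of the sample, percent (0, 100].
#' @param codes Expected amino-acid codes; defaults to the 17-acid set.
#' @return An `aa_profile` object (list with `sample_id`, `contents`,
#'   `protein_pct`).
#' @export
aa_profile <- function(sample_id, contents, protein_pct, codes = aa_codes()) {
  stopifnot(is.numeric(contents), !is.null(names(contents)))
  if (any(contents < 0)) stop("amino-acid contents must be >= 0")
  if (!is.numeric(protein_pct) || protein_pct <= 0 || protein_pct > 100) {
    stop("protein_pct must lie in (0, 100]")
  }
  missing <- setdiff(codes, names(contents))
  if (length(missing)) {
    stop("profile '", sample_id, "' lacks amino acids: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(contents), codes)
  if (length(extra)) {
    stop("unknown amino-acid code(s): ", paste(extra, collapse = ", "))
  }
  structure(list(sample_id = as.character(sample_id),
                 contents = contents[codes],
                 protein_pct = protein_pct),
            class = "aa_profile")
}

#' @export
print.aa_profile <- function(x, ...) {
  cat("Amino-acid profile:", x$sample_id,
      sprintf("(protein %.2f%%, TAA %.2f g/100 g)\n",
              x$protein_pct, sum(x$contents)))
  print(round(x$contents, 3))
  invisible(x)
}

# g/100 g sample -> mg/g protein: x g per 100 g = 1000*x mg per protein_pct g
# protein.
aa_mg_per_g_protein <- function(profile) {
  if (profile$protein_pct == 0) stop("protein_pct is zero: conversion basis undefined")
  profile$contents * 1000 / profile$protein_pct
}

# Sum profile terms for a (possibly combined, e.g. "Met+Cys") reference code.
combined_content <- function(values, code) {
  parts <- strsplit(code, "+", fixed = TRUE)[[1]]
  missing <- setdiff(parts, names(values))
  if (length(missing)) {
    stop("profile is missing EAA '", paste(missing, collapse = "','"),
         "' required by reference entry '", code, "'")
  }
  sum(values[parts])
}

#' Amino-acid ratios against a reference pattern (RAA)
#'
#' RAA for each essential amino acid is the sample content, expressed in
#' mg per g protein, divided by the reference pattern value. Combined
#' reference entries (Met+Cys, Phe+Tyr) are summed in the sample before
#' division.
#'
#' @param profile An [aa_profile()].
#' @param ref A [reference_pattern()]; defaults to the WHO/FAO 1973 pattern.
#' @return Named numeric vector of RAA values, one per reference entry.
#' @export
compute_raa <- function(profile, ref = who_fao_pattern()) {
  mg <- aa_mg_per_g_protein(profile)
  vapply(names(ref), function(code) {
    combined_content(mg, code) / unclass(ref)[[code]]
  }, numeric(1))
}

#' Ratio coefficients (RC), score (SRC) and the limiting amino acid
#'
#' RC is each RAA divided by the mean RAA, so `mean(RC) == 1` identically;
#' RC < 1 marks a relative essential amino-acid deficiency and the minimum
#' RC identifies the first limiting amino acid. The score is
#' `SRC = 100 - 100 * CV` where CV = sd(RC)/mean(RC); SRC reaches 100
#' exactly when all RC are equal (perfectly balanced profile).
#'
#' @param raa Named numeric vector of RAA values (all > 0).
#' @param sd_type `"population"` (n divisor, default: SRC = 100 at uniform RC
#'   for any n) or `"sample"` (n-1 divisor).
#' @return List with `rc` (named vector), `src`, `cv`, `limiting_aa` (ties
#'   broken by alphabetical code order).
#' @export
compute_rc_src <- function(raa, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(raa) == 0) stop("RAA vector is empty")
  if (any(!is.finite(raa)) || any(raa <= 0)) stop("RAA values must be finite and > 0")
  rc <- raa / mean(raa)
  n <- length(rc)
  s <- stats::sd(rc)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (n == 1) s <- 0
  cv <- s / mean(rc)
  ord <- order(rc, names(rc))  # ties: alphabetical code
  list(rc = rc, src = 100 - 100 * cv, cv = cv, limiting_aa = names(rc)[ord[1]])
}

#' Essential-to-total and essential-to-nonessential amino-acid ratios
#'
#' @param profile An [aa_profile()].
#' @param eaa_set Codes treated as essential; default the 7 hydrolysate EAAs.
#' @return List with `eaa_taa_pct`, `eaa_neaa_pct` (NA with
#'   `neaa_undefined = TRUE` when the non-essential total is zero), `taa`,
#'   `eaa_total`, `neaa_total` (all g/100 g except the percentages).
#' @export
compute_ratios <- function(profile, eaa_set = eaa_codes()) {
  cont <- profile$contents
  unknown <- setdiff(eaa_set, names(cont))
  if (length(unknown)) stop("eaa_set codes not in profile: ", paste(unknown, collapse = ", "))
  eaa_total <- sum(cont[eaa_set])
  taa <- sum(cont)
  neaa_total <- taa - eaa_total
  if (taa == 0) stop("profile has zero total amino-acid content")
  neaa_undefined <- neaa_total == 0
  list(eaa_taa_pct = 100 * eaa_total / taa,
       eaa_neaa_pct = if (neaa_undefined) NA_real_ else 100 * eaa_total / neaa_total,
       neaa_undefined = neaa_undefined,
       taa = taa, eaa_total = eaa_total, neaa_total = neaa_total)
}

#' Back-calculate a baseline from a percentage increase
#'
#' Given a value reported as a `pct` percent increase over an unstated
#' baseline, return that baseline (`value / (1 + pct/100)`). Used to check
#' internal consistency of reported totals and their fold increases.
#'
#' @param value The increased value.
#' @param pct Percent increase over the baseline.
#' @return The implied baseline.
#' @export
infer_baseline <- function(value, pct) value / (1 + pct / 100)

#' Fuzzy closeness of a profile to a model protein
#'
#' Lang's distance closeness between a sample's essential amino-acid vector
#' and a model protein (whole egg by default), both in mg per g protein over
#' the 7 combined EAA terms:
#' \deqn{\mu(\alpha, u) = 1 - c \sum_k |\alpha_k - u_k| / (\alpha_k + u_k)}
#' with the scaling constant c = 0.09 so that values fall in [1 - 7c, 1];
#' mu = 1 means the profile matches the model protein on every term.
#'
#' @param profile An [aa_profile()], or a named numeric vector already in
#'   mg/g protein on the reference's terms.
#' @param egg Model-protein [reference_pattern()] (default [egg_reference()]).
#' @param c Scaling constant (default 0.09).
#' @return Closeness mu, a single number.
#' @export
fuzzy_closeness <- function(profile, egg = egg_reference(), c = 0.09) {
  alpha <- unclass(egg)
  if (inherits(profile, "aa_profile")) {
    mg <- aa_mg_per_g_protein(profile)
    u <- vapply(names(alpha), function(code) combined_content(mg, code), numeric(1))
  } else {
    stopifnot(is.numeric(profile), !is.null(names(profile)))
    missing <- setdiff(names(alpha), names(profile))
    if (length(missing)) stop("profile lacks term(s): ", paste(missing, collapse = ", "))
    u <- profile[names(alpha)]
  }
  denom <- alpha + u
  if (any(denom == 0)) stop("degenerate term: alpha_k + u_k = 0")
  1 - c * sum(abs(alpha - u) / denom)
}

#' Taste activity values (TAV) of free amino acids
#'
#' TAV is the free content of a taste compound divided by its taste
#' threshold; a compound contributes to perceived taste when TAV is strictly
#' greater than 1. An `invert` flag computes threshold/content instead for
#' comparison with sources that define the ratio the other way round.
#'
#' @param free_aa Named numeric vector of free amino-acid contents,
#'   mg per 100 g.
#' @param thresholds Threshold table as from [taste_thresholds()].
#' @param invert Compute threshold/content instead of content/threshold.
#' @return List with `records` (data frame: code, content, threshold, tav,
#'   contributes, taste_class) and `summary` (contributing codes grouped by
#'   taste class).
#' @export
compute_tav <- function(free_aa, thresholds = taste_thresholds(), invert = FALSE) {
  stopifnot(is.numeric(free_aa), !is.null(names(free_aa)))
  idx <- match(names(free_aa), thresholds$code)
  if (anyNA(idx)) {
    stop("no taste threshold for: ",
         paste(names(free_aa)[is.na(idx)], collapse = ", "))
  }
  thr <- thresholds$threshold_mg_per_100g[idx]
  tav <- if (invert) thr / free_aa else free_aa / thr
  records <- data.frame(code = names(free_aa),
                        content_mg_per_100g = unname(free_aa),
                        threshold_mg_per_100g = thr,
                        tav = unname(tav),
                        contributes = unname(tav > 1),
                        taste_class = thresholds$taste_class[idx],
                        stringsAsFactors = FALSE)
  contributing <- records[records$contributes, ]
  summary <- split(contributing$code, contributing$taste_class)
  list(records = records, summary = summary)
}

#' Full nutritional and taste evaluation of one profile
#'
#' Convenience wrapper running RAA/RC/SRC scoring, EAA ratio computation and
#' fuzzy closeness for a single sample; TAV scoring is separate because it
#' operates on free (not hydrolysate) amino acids.
#'
#' @param profile An [aa_profile()].
#' @param ref Scoring pattern for RAA (default WHO/FAO 1973).
#' @param egg Model protein for closeness (default whole egg).
#' @param eaa_set EAA codes for the totals ratios.
#' @return List with `sample_id`, `raa`, `rc`, `src`, `cv`, `limiting_aa`,
#'   `eaa_taa_pct`, `eaa_neaa_pct`, `taa`, `closeness_mu`.
#' @export
evaluate_amino_acids <- function(profile, ref = who_fao_pattern(),
                                 egg = egg_reference(), eaa_set = eaa_codes()) {
  raa <- compute_raa(profile, ref)
  sc <- compute_rc_src(raa)
  ratios <- compute_ratios(profile, eaa_set)
  mu <- fuzzy_closeness(profile, egg)
  list(sample_id = profile$sample_id, raa = raa, rc = sc$rc, src = sc$src,
       cv = sc$cv, limiting_aa = sc$limiting_aa,
       eaa_taa_pct = ratios$eaa_taa_pct, eaa_neaa_pct = ratios$eaa_neaa_pct,
       taa = ratios$taa, closeness_mu = mu)
}
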