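#' Dataset curation filters
#'
#' A raw corpus is a list of records `list(mol, spectrum)` where
#' `spectrum` may be `NULL`. The full chain [curate()] applies, in this
#' fixed order: drop records without a carbon spectrum, drop
#' multi-fragment molecules (salts), drop molecules containing elements
#' outside the allowed 11-element set, and drop records where any
#' reference-predicted shift deviates from the observed shift by more than
#' the threshold (default 50 ppm), which flags erroneous interpretations
#' or assignments of the spectrum. Duplicates are deliberately retained as
#' independent entries. The chain is idempotent.
#'
#' @name curation
NULL

#' Assemble a raw (pre-curation) corpus
#'
#' Unlike [build_corpus()], spectra may be missing (`NULL`): that is what
#' the first curation filter removes.
#'
#' @param mols list of `mol_record`.
#' @param spectra list of [shift_spectrum()] or `NULL` entries, same
#'   length.
#' @return list of records `list(mol, spectrum)`.
#' @export
raw_corpus <- function(mols, spectra) {
  stopifnot(length(mols) == length(spectra))
  lapply(seq_along(mols), function(k)
    list(mol = mols[[k]], spectrum = spectra[[k]]))
}

#' Keep only records that carry a non-empty carbon spectrum
#' @param records list of `list(mol, spectrum)` records.
#' @return surviving records.
#' @export
filter_has_carbon_spectrum <- function(records) {
  Filter(function(r) !is.null(r$spectrum) && length(r$spectrum$shifts) > 0,
         records)
}

#' Keep only single-fragment molecules
#'
#' A record is removed iff its heavy-atom bond graph has more than one
#' connected component (e.g. salts stored as two fragments).
#' @inheritParams filter_has_carbon_spectrum
#' @return surviving records.
#' @export
filter_single_fragment <- function(records) {
  Filter(function(r) n_fragments(r$mol) == 1L, records)
}

#' Number of connected components of a molecule's bond graph
#' @param mol a `mol_record`.
#' @return integer component count.
#' @export
n_fragments <- function(mol) {
  g <- igraph::make_empty_graph(nrow(mol$atoms), directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, t(cbind(mol$bonds$i, mol$bonds$j)))
  igraph::count_components(g)
}

#' Keep only molecules within the allowed element set
#'
#' Allowed: H, B, C, N, O, F, P, S, Cl, Br, I. Rare elements hinder
#' training and are discarded.
#' @inheritParams filter_has_carbon_spectrum
#' @return surviving records.
#' @export
filter_elements <- function(records) {
  Filter(function(r) all(r$mol$atoms$element %in% ALLOWED_ELEMENTS), records)
}

#' Remove records with gross prediction-observation disagreement
#'
#' A record is removed iff any single `|predicted - observed|` exceeds the
#' threshold: one grossly wrong assignment is the failure mode being
#' caught, so the rule is per-peak max deviation with a strict boundary
#' (a deviation exactly at the threshold is kept). The reference
#' prediction source is pluggable: any per-record numeric vector aligned
#' with the observed peaks (a previously trained net, a surrogate model,
#' or an external prediction).
#'
#' @param records list of records.
#' @param reference list of numeric vectors, one per record, each the
#'   reference-predicted shift for every observed peak; or a function
#'   `record -> vector`. Defaults to the `ref_shifts` field of each
#'   record. A record with no reference prediction at all is kept (the
#'   filter is not applicable to it); a reference of the wrong length is
#'   an error.
#' @param threshold ppm (default 50); `Inf` keeps everything.
#' @return surviving records.
#' @export
filter_shift_outliers <- function(records, reference = NULL, threshold = 50) {
  get_ref <- function(r, k) {
    ref <- if (is.null(reference)) r$ref_shifts
           else if (is.function(reference)) reference(r)
           else reference[[k]]
    if (is.null(ref)) return(NULL)
    if (length(ref) != length(r$spectrum$shifts))
      stop("record ", k, ": ", length(ref), " reference predictions for ",
           length(r$spectrum$shifts), " observed shifts")
    ref
  }
  keep <- vapply(seq_along(records), function(k) {
    r <- records[[k]]
    if (is.infinite(threshold)) return(TRUE)
    ref <- get_ref(r, k)
    if (is.null(ref)) return(TRUE)
    all(abs(ref - r$spectrum$shifts) <= threshold)
  }, logical(1))
  records[keep]
}

#' Apply the full curation chain
#'
#' @param records raw corpus.
#' @param reference passed to [filter_shift_outliers()]; when `NULL` and
#'   records carry no `ref_shifts`, the outlier filter is skipped (its
#'   removed count reported as 0).
#' @param threshold outlier threshold in ppm (default 50).
#' @return surviving records, with attribute `"report"`: a `curation_report`
#'   (counts in, removed per filter, counts out; conserved by
#'   construction).
#' @export
curate <- function(records, reference = NULL, threshold = 50) {
  n_in <- length(records)
  r1 <- filter_has_carbon_spectrum(records)
  r2 <- filter_single_fragment(r1)
  r3 <- filter_elements(r2)
  has_ref <- !is.null(reference) ||
    any(vapply(r3, function(r) !is.null(r$ref_shifts), logical(1)))
  r4 <- if (has_ref) filter_shift_outliers(r3, reference, threshold) else r3
  report <- structure(list(
    records_in = n_in,
    removed_no_carbon_spectrum = n_in - length(r1),
    removed_multi_fragment = length(r1) - length(r2),
    removed_disallowed_element = length(r2) - length(r3),
    removed_shift_outlier = length(r3) - length(r4),
    records_out = length(r4),
    threshold = threshold,
    pairing = "assigned order (reference prediction k vs observed peak k)"),
    class = "curation_report")
  attr(r4, "report") <- report
  r4
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n")
  cat("  in:", x$records_in, "\n")
  cat("  removed: no-carbon-spectrum", x$removed_no_carbon_spectrum,
      "| multi-fragment", x$removed_multi_fragment,
      "| disallowed-element", x$removed_disallowed_element,
      "| shift-outlier(>", x$threshold, "ppm)", x$removed_shift_outlier, "\n")
  cat("  out:", x$records_out, "\n")
  invisible(x)
}
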