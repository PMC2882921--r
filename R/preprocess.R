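# Preprocessing: per-array scaling to a common average intensity, signal
# flooring, non-informative probe-set filtering, probe-set-to-gene selection
# and presence computation. A "marginal" (M) call is stored but counts as
# not-present everywhere, like an absent call.

#' Scale arrays to a common average intensity and floor low signals
#'
#' Each sample column is multiplied by `scale_target / mean(column)` (a
#' trimmed mean when `cfg$scale_trim > 0`), then every value below
#' `cfg$signal_floor` is set to the floor. Detection calls are unchanged.
#'
#' @param ds an [expression_dataset()].
#' @param cfg an [analysis_config()].
#' @return The scaled, floored `expression_dataset`.
#' @export
scale_dataset <- function(ds, cfg = analysis_config()) {
  stopifnot(inherits(ds, "expression_dataset"))
  means <- apply(ds$signal, 2, mean, trim = cfg$scale_trim)
  zero <- colnames(ds$signal)[means == 0]
  if (length(zero) > 0) {
    stop("cannot scale sample(s) with zero mean signal: ",
         paste(zero, collapse = ", "))
  }
  scaled <- sweep(ds$signal, 2, cfg$scale_target / means, "*")
  floored <- pmax(scaled, cfg$signal_floor)
  ds$signal <- floored
  ds
}

#' Fraction of present calls
#'
#' Marginal (`M`) and absent (`A`) calls both count as not-present.
#'
#' @param calls character vector of detection calls.
#' @return Fraction of `P` calls in `[0, 1]`.
#' @export
presence_fraction <- function(calls) {
  if (length(calls) == 0) stop("presence_fraction: empty call set")
  mean(calls == "P")
}

#' Informative probe sets
#'
#' A probe set with a not-present call in at least
#' `cfg$noninformative_absent_frac` of all samples carries no usable signal
#' and is excluded; all other probe sets are returned.
#'
#' @param ds a scaled [expression_dataset()].
#' @param cfg an [analysis_config()].
#' @return Character vector of retained probe-set identifiers.
#' @export
informative_probesets <- function(ds, cfg = analysis_config()) {
  stopifnot(inherits(ds, "expression_dataset"))
  not_present <- rowMeans(ds$call != "P")
  rownames(ds$call)[not_present < cfg$noninformative_absent_frac]
}

#' Select the reporting probe set for a gene
#'
#' Among the gene's candidate probe sets present in the dataset, selects the
#' one with the highest fraction of present calls over all samples; presence
#' ties (including several candidates at 100%) are broken by the highest
#' signal variance, and any remaining tie lexicographically by probe
#' identifier.
#'
#' @param gene a single-row subset of a `gene_catalog`, or a list with
#'   elements `gene` and `probe_sets`.
#' @param ds an [expression_dataset()].
#' @return A `gene_view`: a list with `gene_symbol`, `probe`, and the
#'   selected probe's `signal` and `call` vectors across all samples.
#' @export
select_probeset <- function(gene, ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.data.frame(gene)) {
    stopifnot(nrow(gene) == 1)
    sym <- gene$gene
    candidates <- gene$probe_sets[[1]]
  } else {
    sym <- gene$gene
    candidates <- gene$probe_sets
    if (is.list(candidates)) candidates <- candidates[[1]]
  }
  candidates <- intersect(candidates, rownames(ds$signal))
  if (length(candidates) == 0) {
    stop("no candidate probe set of gene ", sym, " is present in the dataset")
  }
  pres <- vapply(candidates, function(p) mean(ds$call[p, ] == "P"),
                 numeric(1))
  vars <- vapply(candidates, function(p) var(ds$signal[p, ]), numeric(1))
  ord <- order(-pres, -vars, candidates)
  chosen <- candidates[ord[1]]
  structure(list(gene_symbol = sym,
                 probe = chosen,
                 signal = ds$signal[chosen, ],
                 call = ds$call[chosen, ]),
            class = "gene_view")
}

#' Per-gene views for all interrogable catalog genes
#'
#' Applies [select_probeset()] to every interrogable catalog entry. Genes
#' whose candidate probe sets are all missing from the dataset raise an
#' error unless `skip_missing = TRUE`, in which case they are dropped.
#'
#' @param ds an [expression_dataset()].
#' @param catalog a `gene_catalog`.
#' @param skip_missing drop genes without any candidate probe in `ds`.
#' @return Named list of `gene_view` objects.
#' @export
gene_views <- function(ds, catalog, skip_missing = FALSE) {
  stopifnot(inherits(catalog, "gene_catalog"))
  idx <- which(catalog$interrogable)
  views <- list()
  for (i in idx) {
    row <- catalog[i, ]
    if (!any(row$probe_sets[[1]] %in% rownames(ds$signal))) {
      if (skip_missing) next
      stop("no candidate probe set of gene ", row$gene,
           " is present in the dataset")
    }
    views[[row$gene]] <- select_probeset(row, ds)
  }
  views
}
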