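# Receptor expression summaries in myeloma cells: per-receptor median,
# range and integer presence percentage over MMC samples, plus presence
# bucket counts.

new_receptor_summary <- function(rows, source) {
  structure(list(rows = rows, source = source), class = "receptor_summary")
}

#' Summarize receptor expression in myeloma cells
#'
#' For each receptor gene view, computes over the MMC samples only: the
#' median signal, the (min, max) signal range, and the presence percentage
#' rounded half-up to the nearest integer.
#'
#' @param ds a scaled [expression_dataset()] containing MMC samples.
#' @param views named list of `gene_view` objects for receptor genes.
#' @param cfg an [analysis_config()] (unused thresholds are ignored).
#' @return A `receptor_summary` with `source = "computed"`.
#' @export
summarize_receptors <- function(ds, views, cfg = analysis_config()) {
  stopifnot(inherits(ds, "expression_dataset"))
  mmc <- samples_of(ds, "MMC")
  if (length(mmc) == 0) stop("dataset contains no MMC samples")
  rows <- do.call(rbind, lapply(views, function(v) {
    s <- v$signal[mmc]
    data.frame(gene = v$gene_symbol, probe = v$probe,
               median_signal = median(s),
               range_min = min(s), range_max = max(s),
               presence_pct = as.integer(floor(
                 100 * presence_fraction(v$call[mmc]) + 0.5)),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  new_receptor_summary(rows, "computed")
}

#' Load a transcribed receptor expression table
#'
#' Reads a CSV transcription of a printed receptor table (columns `gene`,
#' `probe_sets`, `median_mmc`, `range_min`, `range_max`, `presence_pct`;
#' empty cells mean the value is not available, e.g. no informative probe
#' set or an ambiguously rendered cell). A `median_in_range` column flags
#' rows whose printed median lies inside the printed range; printed values
#' are preserved verbatim even when inconsistent.
#'
#' @param path CSV file path.
#' @return A `receptor_summary` with `source = "transcribed"`.
#' @export
read_receptor_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "probe_sets", "median_mmc", "range_min", "range_max",
            "presence_pct")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("receptor table lacks column(s): ", paste(miss, collapse = ", "))
  }
  rows <- data.frame(
    gene = raw$gene,
    probe = ifelse(is.na(raw$probe_sets) | raw$probe_sets == "",
                   NA_character_, raw$probe_sets),
    median_signal = as.numeric(raw$median_mmc),
    range_min = as.numeric(raw$range_min),
    range_max = as.numeric(raw$range_max),
    presence_pct = as.integer(raw$presence_pct),
    stringsAsFactors = FALSE
  )
  pp <- rows$presence_pct
  if (any(!is.na(pp) & (pp < 0 | pp > 100))) {
    stop("presence percentages must lie in [0, 100]")
  }
  rows$median_in_range <- ifelse(
    is.na(rows$median_signal) | is.na(rows$range_min) | is.na(rows$range_max),
    NA,
    rows$median_signal >= rows$range_min &
      rows$median_signal <= rows$range_max)
  new_receptor_summary(rows, "transcribed")
}

#' Presence bucket definition
#'
#' @param lower,upper bucket bounds on the integer presence percentage.
#' @param lower_inclusive,upper_inclusive whether each bound is included.
#' @param name optional bucket label.
#' @return One-row data frame describing the bucket.
#' @export
presence_bucket <- function(lower, upper, lower_inclusive = TRUE,
                            upper_inclusive = TRUE, name = NULL) {
  if (lower > upper) stop("malformed bucket: lower ", lower, " > upper ",
                          upper)
  data.frame(name = if (is.null(name)) paste0(lower, "_", upper) else name,
             lower = lower, upper = upper,
             lower_inclusive = lower_inclusive,
             upper_inclusive = upper_inclusive,
             stringsAsFactors = FALSE)
}

#' Standard presence buckets for the receptor report
#'
#' `ge50`: at least half of the samples (inclusive at 50, so a receptor
#' printed at exactly 50% counts). `eq100` and `eq99`: exact percentages.
#' `gt90_lt99`: strictly between 90 and 99.
#' @return Data frame of bucket definitions.
#' @export
receptor_presence_buckets <- function() {
  rbind(presence_bucket(50, 100, TRUE, TRUE, "ge50"),
        presence_bucket(100, 100, TRUE, TRUE, "eq100"),
        presence_bucket(99, 99, TRUE, TRUE, "eq99"),
        presence_bucket(90, 99, FALSE, FALSE, "gt90_lt99"))
}

#' Count receptors per presence bucket
#'
#' Rows with unknown presence percentage are excluded from every bucket and
#' reported separately; buckets may overlap and need not partition.
#'
#' @param summary a `receptor_summary`.
#' @param buckets data frame of bucket definitions (see
#'   [presence_bucket()]); defaults to [receptor_presence_buckets()].
#' @return List with `counts` (named integer vector, one per bucket) and
#'   `n_unknown` (rows without a presence percentage).
#' @export
bucket_counts <- function(summary, buckets = receptor_presence_buckets()) {
  stopifnot(inherits(summary, "receptor_summary"))
  if (any(buckets$lower > buckets$upper)) {
    bad <- which(buckets$lower > buckets$upper)[1]
    stop("malformed bucket: lower ", buckets$lower[bad], " > upper ",
         buckets$upper[bad])
  }
  pp <- summary$rows$presence_pct
  known <- pp[!is.na(pp)]
  counts <- vapply(seq_len(nrow(buckets)), function(i) {
    lo_ok <- if (buckets$lower_inclusive[i]) known >= buckets$lower[i]
             else known > buckets$lower[i]
    hi_ok <- if (buckets$upper_inclusive[i]) known <= buckets$upper[i]
             else known < buckets$upper[i]
    sum(lo_ok & hi_ok)
  }, integer(1))
  list(counts = setNames(counts, buckets$name),
       n_unknown = sum(is.na(pp)))
}

#' Write a receptor summary to TSV
#'
#' @param summary a `receptor_summary`.
#' @param path output path.
#' @export
write_receptor_summary <- function(summary, path) {
  utils::write.table(summary$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.receptor_summary <- function(x, ...) {
  cat("Receptor summary (", x$source, "): ", nrow(x$rows), " receptors, ",
      sum(!is.na(x$rows$presence_pct)), " with known presence\n", sep = "")
  invisible(x)
}
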