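# Expression dataset: a probe-set x sample signal matrix paired with a
# detection-call matrix (P/M/A) and one population label per sample.

#' Construct and validate an expression dataset
#'
#' @param signal numeric probe x sample matrix of non-negative intensities,
#'   with probe identifiers as rownames and sample identifiers as colnames.
#' @param call character matrix of the same shape over `P`, `M`, `A`.
#' @param samples either a data frame with columns `sample_id` and
#'   `population`, or a character vector of population labels named by
#'   sample identifier. Labels must be in [POPULATION_LABELS].
#' @return An `expression_dataset`: a list with elements `signal`, `call`
#'   and `samples`.
#' @export
expression_dataset <- function(signal, call, samples) {
  stopifnot(is.matrix(signal), is.numeric(signal))
  stopifnot(is.matrix(call), is.character(call))
  if (is.null(rownames(signal)) || is.null(colnames(signal))) {
    stop("signal matrix must have probe rownames and sample colnames")
  }
  if (!identical(dim(signal), dim(call)) ||
      !identical(dimnames(signal), dimnames(call))) {
    stop("signal and call matrices must have identical probe/sample axes")
  }
  if (anyDuplicated(rownames(signal))) stop("duplicate probe identifiers")
  if (anyDuplicated(colnames(signal))) stop("duplicate sample identifiers")
  if (any(signal < 0)) stop("signal values must be non-negative")
  ok <- matrix(call %in% VALID_CALLS, nrow = nrow(call))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    coords <- paste(rownames(signal)[bad[, 1]], colnames(signal)[bad[, 2]],
                    sep = ",")
    stop("invalid detection call(s) at: ", paste(coords, collapse = "; "))
  }
  if (is.character(samples)) {
    samples <- data.frame(sample_id = names(samples),
                          population = unname(samples),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "population") %in% names(samples)))
  samples <- data.frame(sample_id = as.character(samples$sample_id),
                        population = as.character(samples$population),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample_id)) {
    stop("each sample must have exactly one population label; duplicated: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  bad_pop <- setdiff(samples$population, POPULATION_LABELS)
  if (length(bad_pop) > 0) {
    stop("unknown population label(s): ", paste(bad_pop, collapse = ", "))
  }
  if (!setequal(samples$sample_id, colnames(signal))) {
    stop("sample sheet and matrices disagree; missing from sheet: ",
         paste(setdiff(colnames(signal), samples$sample_id), collapse = ", "),
         "; missing from matrices: ",
         paste(setdiff(samples$sample_id, colnames(signal)), collapse = ", "))
  }
  samples <- samples[match(colnames(signal), samples$sample_id), ]
  rownames(samples) <- NULL
  structure(list(signal = signal, call = call, samples = samples),
            class = "expression_dataset")
}

#' Load an expression dataset from tab-delimited files
#'
#' The signal and call files are tab-delimited matrices with probe
#' identifiers in the first column and a header row of sample identifiers;
#' calls are single characters in `P`/`M`/`A`. The call matrix is reconciled
#' to the signal matrix by identifier (row and column order in the call file
#' need not match the signal file). The sample sheet is a two-column
#' tab-delimited file mapping `sample_id` to `population`.
#'
#' @param signal_path,call_path,samples_path file paths.
#' @return An `expression_dataset`.
#' @export
load_dataset <- function(signal_path, call_path, samples_path) {
  signal <- as.matrix(read.delim(signal_path, row.names = 1,
                                 check.names = FALSE))
  call_df <- read.delim(call_path, row.names = 1, check.names = FALSE,
                        colClasses = "character")
  call <- as.matrix(call_df)
  probe_miss <- c(setdiff(rownames(signal), rownames(call)),
                  setdiff(rownames(call), rownames(signal)))
  sample_miss <- c(setdiff(colnames(signal), colnames(call)),
                   setdiff(colnames(call), colnames(signal)))
  if (length(probe_miss) > 0 || length(sample_miss) > 0) {
    stop("signal/call axis mismatch; probes: ",
         paste(unique(probe_miss), collapse = ", "),
         "; samples: ", paste(unique(sample_miss), collapse = ", "))
  }
  call <- call[rownames(signal), colnames(signal), drop = FALSE]
  samples <- read.delim(samples_path, colClasses = "character")
  expression_dataset(signal, call, samples)
}

#' Write an expression dataset to tab-delimited files
#'
#' Signals are written with 17 significant digits so that
#' [load_dataset()] round-trips doubles exactly.
#'
#' @param ds an `expression_dataset`.
#' @param signal_path,call_path,samples_path output paths.
#' @export
write_dataset <- function(ds, signal_path, call_path, samples_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  write_matrix <- function(m, path, fmt) {
    lines <- c(paste(c("probe_id", colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i) {
                 paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t")
               }, character(1)))
    writeLines(lines, path)
  }
  write_matrix(ds$signal, signal_path,
               function(x) formatC(x, format = "g", digits = 17))
  write_matrix(ds$call, call_path, identity)
  writeLines(c("sample_id\tpopulation",
               paste(ds$samples$sample_id, ds$samples$population,
                     sep = "\t")),
             samples_path)
  invisible(ds)
}

#' Sample identifiers belonging to given populations
#'
#' @param ds an `expression_dataset`.
#' @param populations character vector of population labels.
#' @return Character vector of sample identifiers.
#' @export
samples_of <- function(ds, populations) {
  stopifnot(inherits(ds, "expression_dataset"))
  bad <- setdiff(populations, POPULATION_LABELS)
  if (length(bad) > 0) stop("unknown population(s): ",
                            paste(bad, collapse = ", "))
  ds$samples$sample_id[ds$samples$population %in% populations]
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset: ", nrow(x$signal), " probe sets x ",
      ncol(x$signal), " samples\n", sep = "")
  tab <- table(x$samples$population)
  cat("  populations: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
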