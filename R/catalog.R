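# Gene catalog: genes mapped to family, role (ligand/receptor), candidate
# probe sets and, for receptors, the ligand they bind. A gene with no probe
# set on the array cannot be interrogated.

#' Load a gene catalog
#'
#' Reads one or more CSV catalog files and returns a validated gene catalog.
#' Required columns: `gene`, `family`, `role`, `probe_sets` (semicolon
#' separated probe-set identifiers, empty allowed). Optional columns:
#' `receptor_of` (ligand bound by a receptor) and `known_mgf` (0/1 flag for
#' genes previously reported as myeloma growth factors). A row with an empty
#' `probe_sets` cell is kept but marked non-interrogable.
#'
#' When several paths are given the files are concatenated into one catalog;
#' gene symbols must be unique across all of them.
#'
#' @param paths character vector of CSV file paths.
#' @return A `gene_catalog`: a data frame with columns `gene`, `family`,
#'   `role`, `probe_sets` (list column of character vectors), `receptor_of`,
#'   `known_mgf` and `interrogable`.
#' @export
load_catalog <- function(paths) {
  stopifnot(is.character(paths), length(paths) >= 1)
  raw <- do.call(rbind, lapply(paths, function(p) {
    df <- read.csv(p, stringsAsFactors = FALSE, colClasses = "character")
    need <- c("gene", "family", "role", "probe_sets")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0) {
      stop("catalog file ", p, " lacks required column(s): ",
           paste(miss, collapse = ", "))
    }
    if (!"receptor_of" %in% names(df)) {
      df$receptor_of <- rep("", nrow(df))
    }
    if (!"known_mgf" %in% names(df)) df$known_mgf <- rep("0", nrow(df))
    df[, c("gene", "family", "role", "probe_sets", "receptor_of", "known_mgf")]
  }))
  gene_catalog(
    gene = raw$gene,
    family = raw$family,
    role = raw$role,
    probe_sets = strsplit(replace(as.character(raw$probe_sets),
                                  is.na(raw$probe_sets), ""),
                          ";", fixed = TRUE),
    receptor_of = ifelse(is.na(raw$receptor_of) | raw$receptor_of == "",
                         NA_character_, raw$receptor_of),
    known_mgf = raw$known_mgf %in% c("1", "TRUE", "true")
  )
}

#' Construct and validate a gene catalog in memory
#'
#' @param gene character vector of unique gene symbols.
#' @param family family token per gene, one of [GENE_FAMILIES].
#' @param role role token per gene, one of [GENE_ROLES].
#' @param probe_sets list of character vectors of candidate probe-set
#'   identifiers (may be empty).
#' @param receptor_of for receptors, the symbol of the bound ligand
#'   (`NA` otherwise).
#' @param known_mgf logical; gene previously reported as an MGF.
#' @return A `gene_catalog` data frame.
#' @export
gene_catalog <- function(gene, family, role, probe_sets,
                         receptor_of = NA_character_, known_mgf = FALSE) {
  n <- length(gene)
  probe_sets <- lapply(probe_sets, function(x) x[nzchar(x)])
  names(probe_sets) <- as.character(gene)
  cat <- data.frame(gene = as.character(gene),
                    family = as.character(family),
                    role = as.character(role),
                    receptor_of = rep_len(as.character(receptor_of), n),
                    known_mgf = rep_len(as.logical(known_mgf), n),
                    stringsAsFactors = FALSE)
  cat$probe_sets <- probe_sets
  cat$interrogable <- vapply(probe_sets, function(x) length(x) > 0, logical(1))
  dup <- cat$gene[duplicated(cat$gene)]
  if (length(dup) > 0) {
    stop("duplicate gene symbol(s) in catalog: ",
         paste(unique(dup), collapse = ", "))
  }
  bad_fam <- setdiff(cat$family, GENE_FAMILIES)
  if (length(bad_fam) > 0) {
    stop("unknown family token(s): ", paste(bad_fam, collapse = ", "))
  }
  bad_role <- setdiff(cat$role, GENE_ROLES)
  if (length(bad_role) > 0) {
    stop("unknown role token(s): ", paste(bad_role, collapse = ", "))
  }
  # a receptor_of target present in the catalog must be a ligand; targets not
  # in the catalog are allowed (receptor lists can be loaded standalone)
  tgt <- cat$receptor_of[!is.na(cat$receptor_of)]
  in_cat <- tgt[tgt %in% cat$gene]
  if (length(in_cat) > 0) {
    not_ligand <- in_cat[cat$role[match(in_cat, cat$gene)] != "LIGAND"]
    if (length(not_ligand) > 0) {
      stop("receptor_of target(s) are not LIGAND entries: ",
           paste(unique(not_ligand), collapse = ", "))
    }
  }
  class(cat) <- c("gene_catalog", "data.frame")
  cat
}

#' Write a gene catalog to CSV
#'
#' Inverse of [load_catalog()]; probe sets are joined with semicolons.
#'
#' @param catalog a `gene_catalog`.
#' @param path output CSV path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  out <- data.frame(
    gene = catalog$gene,
    family = catalog$family,
    role = catalog$role,
    probe_sets = vapply(catalog$probe_sets, paste, character(1),
                        collapse = ";"),
    receptor_of = ifelse(is.na(catalog$receptor_of), "", catalog$receptor_of),
    known_mgf = as.integer(catalog$known_mgf),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count interrogable genes in a catalog
#'
#' A gene is interrogable when at least one probe set on the array targets
#' it. Counts are reported as interrogable over total within the selected
#' family/role; omitting `family` or `role` selects all values.
#'
#' @param catalog a `gene_catalog`.
#' @param family optional family token, one of [GENE_FAMILIES].
#' @param role optional role token, one of [GENE_ROLES].
#' @return Named integer vector `c(n_interrogable, n_total)`.
#' @export
count_interrogable <- function(catalog, family = NULL, role = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"))
  keep <- rep(TRUE, nrow(catalog))
  if (!is.null(family)) {
    stopifnot(family %in% GENE_FAMILIES)
    keep <- keep & catalog$family == family
  }
  if (!is.null(role)) {
    stopifnot(role %in% GENE_ROLES)
    keep <- keep & catalog$role == role
  }
  c(n_interrogable = sum(catalog$interrogable[keep]),
    n_total = sum(keep))
}

#' @export
print.gene_catalog <- function(x, ...) {
  cnt <- count_interrogable(x)
  cat("Gene catalog: ", nrow(x), " genes (",
      cnt[["n_interrogable"]], " interrogable)\n", sep = "")
  cat("  families: ", paste(names(table(x$family)), table(x$family),
                            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
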