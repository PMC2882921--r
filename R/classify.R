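# Compartment classification. Each interrogable gene is assigned to exactly
# one category by a deterministic rule cascade (first match wins):
#   1. NOT_EXPRESSED   below the presence floor in MMC and CD3/CD14/PMN and
#                      with no present call in BMSC and OC
#   2. MYELOMA         MMC significantly over each of CD3/CD14/PMN/BMSC/OC
#   3. NICHE_BMSC/OC   the niche population significantly over MMC and
#                      CD3/CD14/PMN (the other niche population is not
#                      required to be beaten unless configured)
#   4. ENVIRONMENT     at least one of CD3/CD14/PMN significantly over each
#                      of MMC, BMSC and OC
#   5. MYELOMA_RESCUED some present calls in MMC while absent in every
#                      other bone-marrow population
#   6. SHARED          the residual: expressed both by tumor cells and by
#                      at least part of the environment
# Whole bone marrow samples never enter the contrasts.

classify_required_pops <- c("MMC", "CD3", "CD14", "PMN", "BMSC", "OC")

#' Classify genes into bone-marrow expression compartments
#'
#' Runs all pairwise population contrasts needed by the rule cascade (each
#' with its own Benjamini-Hochberg family across the supplied genes) and
#' assigns one compartment category per gene, recording the rule that fired
#' and the winning population.
#'
#' @param ds a scaled [expression_dataset()] containing the populations
#'   MMC, CD3, CD14, PMN, BMSC and OC.
#' @param views named list of `gene_view` objects (see [gene_views()]).
#' @param cfg an [analysis_config()].
#' @return A `category_assignment` data frame with columns `gene`,
#'   `category`, `winner` and `rule`; the per-pair contrast tables are
#'   attached as `attr(x, "contrasts")`.
#' @export
classify_compartments <- function(ds, views, cfg = analysis_config()) {
  stopifnot(inherits(ds, "expression_dataset"))
  missing <- setdiff(classify_required_pops, unique(ds$samples$population))
  if (length(missing) > 0) {
    stop("dataset lacks required population(s): ",
         paste(missing, collapse = ", "))
  }
  if (length(views) == 0) stop("no gene views supplied")

  # ordered contrasts needed by the cascade; significance of "a over b"
  env3 <- ENVIRONMENT_POPULATIONS
  pairs <- list()
  for (b in c(env3, NICHE_POPULATIONS)) pairs[[length(pairs) + 1]] <- c("MMC", b)
  bmsc_vs <- c("MMC", env3, if (cfg$niche_requires_other_niche) "OC")
  for (b in bmsc_vs) pairs[[length(pairs) + 1]] <- c("BMSC", b)
  oc_vs <- c("MMC", env3, if (cfg$niche_requires_other_niche) "BMSC")
  for (b in oc_vs) pairs[[length(pairs) + 1]] <- c("OC", b)
  for (a in env3) for (b in c("MMC", "BMSC", "OC")) {
    pairs[[length(pairs) + 1]] <- c(a, b)
  }
  contrasts <- list()
  for (pr in pairs) {
    key <- paste(pr[1], "vs", pr[2], sep = "_")
    if (is.null(contrasts[[key]])) {
      contrasts[[key]] <- compare_groups(ds, views, pr[1], pr[2], cfg)
    }
  }
  genes <- vapply(views, function(v) v$gene_symbol, character(1))
  sig <- function(a, b) {
    tab <- contrasts[[paste(a, "vs", b, sep = "_")]]
    setNames(tab$significant_over_b, tab$gene)
  }
  sig_over_all <- function(a, bs) {
    Reduce(`&`, lapply(bs, function(b) sig(a, b)[genes]))
  }
  pres <- sapply(classify_required_pops, function(p) {
    ids <- samples_of(ds, p)
    vapply(views, function(v) presence_fraction(v$call[ids]), numeric(1))
  })
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = length(views),
                                         dimnames = list(genes,
                                                         classify_required_pops))
  rownames(pres) <- genes

  mye <- sig_over_all("MMC", c(env3, NICHE_POPULATIONS))
  bmsc <- sig_over_all("BMSC", bmsc_vs)
  oc <- sig_over_all("OC", oc_vs)
  env_win <- sapply(env3, function(a) sig_over_all(a, c("MMC", "BMSC", "OC")))
  if (is.null(dim(env_win))) env_win <- matrix(env_win, nrow = length(genes),
                                               dimnames = list(genes, env3))

  out <- data.frame(gene = genes, category = NA_character_,
                    winner = NA_character_, rule = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    pmax_env <- pres[g, env3]
    not_expr <- pres[g, "MMC"] < cfg$not_expressed_max_present_frac &&
      all(pmax_env < cfg$not_expressed_max_present_frac) &&
      all(pres[g, NICHE_POPULATIONS] <=
            cfg$not_expressed_niche_max_present_frac)
    if (not_expr) {
      out[i, c("category", "winner", "rule")] <-
        c("NOT_EXPRESSED", NA, "presence_floor")
    } else if (mye[g]) {
      out[i, c("category", "winner", "rule")] <-
        c("MYELOMA", "MMC", "mmc_over_all_populations")
    } else if (bmsc[g]) {
      out[i, c("category", "winner", "rule")] <-
        c("NICHE_BMSC", "BMSC", "bmsc_over_mmc_and_subpopulations")
    } else if (oc[g]) {
      out[i, c("category", "winner", "rule")] <-
        c("NICHE_OC", "OC", "oc_over_mmc_and_subpopulations")
    } else if (any(env_win[g, ])) {
      w <- env3[which(env_win[g, ])[1]]
      out[i, c("category", "winner", "rule")] <-
        c("ENVIRONMENT", w, "subpopulation_over_mmc_and_niche")
    } else if (pres[g, "MMC"] > cfg$rescue_min_present_frac &&
               all(pres[g, c(env3, NICHE_POPULATIONS)] == 0)) {
      out[i, c("category", "winner", "rule")] <-
        c("MYELOMA_RESCUED", "MMC", "present_only_in_mmc")
    } else {
      out[i, c("category", "winner", "rule")] <- c("SHARED", NA, "residual")
    }
  }
  rownames(out) <- NULL
  attr(out, "contrasts") <- contrasts
  attr(out, "presence") <- pres
  class(out) <- c("category_assignment", "data.frame")
  out
}

#' Count genes per compartment category
#'
#' Summary of a classification suitable for a Venn-style report.
#'
#' @param assignments a `category_assignment` from [classify_compartments()].
#' @return Named integer vector over [COMPARTMENT_CATEGORIES].
#' @export
category_counts <- function(assignments) {
  tab <- table(factor(assignments$category, levels = COMPARTMENT_CATEGORIES))
  setNames(as.integer(tab), names(tab))
}

#' Stage-wise contrasts across normal plasma-cell differentiation
#'
#' Three contrasts per gene: memory B cells against the pooled plasmablast
#' plus bone-marrow plasma-cell group (`B_vs_PPCBMPC`), plasmablasts against
#' bone-marrow plasma cells (`PPC_vs_BMPC`), and myeloma cells against
#' bone-marrow plasma cells (`MMC_vs_BMPC`). Direction is `up_in_first` or
#' `up_in_second` only when the contrast is significant that way at the
#' configured adjusted-p and fold-change thresholds, `none` otherwise.
#' The per-gene aberrant-expression flag (see [aberrant_in_mmc()]) is
#' repeated on each row.
#'
#' @param ds a scaled [expression_dataset()] with MB, PPC, BMPC and MMC.
#' @param views named list of `gene_view` objects.
#' @param cfg an [analysis_config()].
#' @return A data frame with one row per gene and contrast; the underlying
#'   contrast tables are attached as `attr(x, "contrasts")`.
#' @export
differentiation_analysis <- function(ds, views, cfg = analysis_config()) {
  stopifnot(inherits(ds, "expression_dataset"))
  missing <- setdiff(c("MB", "PPC", "BMPC", "MMC"),
                     unique(ds$samples$population))
  if (length(missing) > 0) {
    stop("dataset lacks required population(s): ",
         paste(missing, collapse = ", "))
  }
  defs <- list(
    B_vs_PPCBMPC = list(a = "MB", b = c("PPC", "BMPC")),
    PPC_vs_BMPC = list(a = "PPC", b = "BMPC"),
    MMC_vs_BMPC = list(a = "MMC", b = "BMPC")
  )
  aberrant <- vapply(views, function(v) aberrant_in_mmc(ds, v, cfg),
                     logical(1))
  contrasts <- list()
  out <- list()
  for (cn in names(defs)) {
    fwd <- compare_groups(ds, views, defs[[cn]]$a, defs[[cn]]$b, cfg)
    rev <- compare_groups(ds, views, defs[[cn]]$b, defs[[cn]]$a, cfg)
    contrasts[[cn]] <- fwd
    direction <- ifelse(fwd$significant_over_b, "up_in_first",
                        ifelse(rev$significant_over_b, "up_in_second",
                               "none"))
    out[[cn]] <- data.frame(gene = fwd$gene, contrast = cn,
                            direction = direction,
                            fold_change = fwd$fold_change,
                            p_raw = fwd$p_raw, p_adj = fwd$p_adj,
                            aberrant_in_mmc = unname(aberrant[fwd$gene]),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "contrasts") <- contrasts
  class(res) <- c("differentiation_result", "data.frame")
  res
}

#' Aberrant expression in myeloma cells relative to normal plasma cells
#'
#' A gene is aberrantly expressed in tumor cells when it has no present call
#' in any normal bone-marrow plasma-cell (BMPC) sample while being present
#' in strictly more than `cfg$aberrant_min_mmc_present_frac` of the myeloma
#' cell samples.
#'
#' @param ds an [expression_dataset()] containing BMPC and MMC samples.
#' @param view a `gene_view`.
#' @param cfg an [analysis_config()].
#' @return Logical scalar.
#' @export
aberrant_in_mmc <- function(ds, view, cfg = analysis_config()) {
  bmpc <- samples_of(ds, "BMPC")
  mmc <- samples_of(ds, "MMC")
  if (length(bmpc) == 0 || length(mmc) == 0) {
    stop("dataset must contain BMPC and MMC samples")
  }
  presence_fraction(view$call[bmpc]) == 0 &&
    presence_fraction(view$call[mmc]) > cfg$aberrant_min_mmc_present_frac
}

#' Write a category assignment table to TSV
#'
#' @param assignments a `category_assignment`.
#' @param path output path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(as.data.frame(assignments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
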