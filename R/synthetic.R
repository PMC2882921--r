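# Synthetic study-shaped datasets. Signals are log-normal around a
# population-specific log2 mean: expressing populations sit at the baseline
# (winner populations shifted up by log2(fold_elevation)), silent
# populations sit several log2 units below. Detection calls are Bernoulli
# draws whose present probability depends only on the expressing/silent
# state, which keeps presence fractions exactly controllable; a
# signal-linked call model is available for realism. Whole bone marrow
# samples, when requested, are tumor/environment mixtures and exist only to
# prove that they are excluded downstream.

#' Define a planted gene
#'
#' @param gene_symbol gene name.
#' @param planted_category target compartment category, one of
#'   [COMPARTMENT_CATEGORIES].
#' @param fold_elevation linear fold applied to the winner population(s)
#'   over the expressing baseline (>= 1; default 8).
#' @param expressing_populations populations in which the gene is expressed
#'   at baseline. Defaults by category: every non-WBM population for the
#'   expressed categories, none for `NOT_EXPRESSED` and `MYELOMA_RESCUED`
#'   (a rescued gene is signal-silent everywhere but receives present calls
#'   in a fraction of MMC samples).
#' @param winner_populations elevated population(s); defaults by category
#'   (`MYELOMA` -> MMC, `NICHE_BMSC` -> BMSC, `NICHE_OC` -> OC,
#'   `ENVIRONMENT` -> CD14). Must be a subset of the expressing populations.
#' @param n_probesets number of probe sets generated for the gene; probes
#'   beyond the first are decoys with degraded presence, exercising
#'   probe-set selection.
#' @return A `planted_gene` list.
#' @export
planted_gene <- function(gene_symbol, planted_category,
                         fold_elevation = 8,
                         expressing_populations = NULL,
                         winner_populations = NULL,
                         n_probesets = 1L) {
  stopifnot(planted_category %in% COMPARTMENT_CATEGORIES)
  all_bm <- setdiff(POPULATION_LABELS, "WBM")
  if (is.null(expressing_populations)) {
    expressing_populations <- switch(
      planted_category,
      NOT_EXPRESSED = character(0),
      MYELOMA_RESCUED = character(0),
      all_bm)
  }
  if (is.null(winner_populations)) {
    winner_populations <- switch(
      planted_category,
      MYELOMA = "MMC",
      NICHE_BMSC = "BMSC",
      NICHE_OC = "OC",
      ENVIRONMENT = "CD14",
      character(0))
  }
  g <- list(gene_symbol = gene_symbol,
            planted_category = planted_category,
            fold_elevation = fold_elevation,
            expressing_populations = expressing_populations,
            winner_populations = winner_populations,
            n_probesets = as.integer(n_probesets))
  if (g$fold_elevation < 1) stop("fold_elevation must be >= 1")
  if (g$n_probesets < 1) stop("n_probesets must be >= 1")
  bad <- setdiff(c(g$expressing_populations, g$winner_populations), all_bm)
  if (length(bad) > 0) stop("unknown population(s): ",
                            paste(bad, collapse = ", "))
  if (!all(g$winner_populations %in% g$expressing_populations)) {
    stop("winner populations of ", gene_symbol,
         " must be a subset of its expressing populations")
  }
  ok <- switch(planted_category,
    MYELOMA = identical(g$winner_populations, "MMC"),
    NICHE_BMSC = identical(g$winner_populations, "BMSC"),
    NICHE_OC = identical(g$winner_populations, "OC"),
    ENVIRONMENT = length(g$winner_populations) >= 1 &&
      all(g$winner_populations %in% ENVIRONMENT_POPULATIONS),
    SHARED = length(g$winner_populations) == 0,
    NOT_EXPRESSED = length(g$expressing_populations) == 0,
    MYELOMA_RESCUED = length(g$expressing_populations) == 0)
  if (!isTRUE(ok)) {
    stop("planted_category ", planted_category, " of ", gene_symbol,
         " is inconsistent with its expressing/winner populations")
  }
  structure(g, class = "planted_gene")
}

#' Default planted gene panel
#'
#' A 51-gene panel mirroring the compartment composition observed in the
#' study: 3 tumor-cell genes, 11 stromal-niche genes, 3 osteoclast-niche
#' genes, 8 environment genes (6 monocyte, 1 neutrophil, 1 T-cell winner),
#' 5 rescued tumor-cell genes, 12 shared genes and 9 not-expressed genes.
#' Every fifth gene carries one decoy probe set.
#'
#' @param fold_elevation fold applied to all winner populations (default 8).
#' @return List of [planted_gene()] objects.
#' @export
default_panel <- function(fold_elevation = 8) {
  spec <- list(
    c("MYELOMA", 3), c("NICHE_BMSC", 11), c("NICHE_OC", 3),
    c("ENVIRONMENT", 8), c("MYELOMA_RESCUED", 5), c("SHARED", 12),
    c("NOT_EXPRESSED", 9))
  env_winners <- c(rep("CD14", 6), "PMN", "CD3")
  genes <- list()
  i <- 0
  for (s in spec) {
    cat_tok <- s[1]; n <- as.integer(s[2])
    for (k in seq_len(n)) {
      i <- i + 1
      winner <- if (cat_tok == "ENVIRONMENT") env_winners[k] else NULL
      genes[[i]] <- planted_gene(
        gene_symbol = sprintf("G%02d_%s", i, cat_tok),
        planted_category = cat_tok,
        fold_elevation = fold_elevation,
        winner_populations = winner,
        n_probesets = if (i %% 5 == 0) 2L else 1L)
    }
  }
  genes
}

#' Null panel: no planted effects
#'
#' Genes expressed at baseline in every population with no winner, for
#' type-I-error calibration.
#'
#' @param n_genes number of genes (default 51).
#' @return List of [planted_gene()] objects, all `SHARED`.
#' @export
null_panel <- function(n_genes = 51) {
  lapply(seq_len(n_genes), function(i) {
    planted_gene(sprintf("NULL%02d", i), "SHARED", fold_elevation = 1)
  })
}

#' Synthetic generator configuration
#'
#' Defaults match the study design: 131 myeloma-cell samples, 5 each of
#' T cells, monocytes, neutrophils and stromal cells, 7 osteoclasts, 6
#' memory B-cell, 7 plasmablast and 7 bone-marrow plasma-cell samples, and
#' no whole-bone-marrow samples (set `WBM` > 0 only to test its exclusion).
#' Signals average ~100 scanner units at baseline (log2 scale mean
#' `log2(100)`), with within-population log2 s.d. 0.5; silent populations
#' sit `silent_log2_drop` (5) log2 units lower. Present-call probabilities
#' are 0.95 for expressing and 0.02 for silent gene/population pairs.
#'
#' @param population_sizes named integer vector of samples per population.
#' @param genes list of [planted_gene()] objects (default [default_panel()]).
#' @param baseline_log2_mean log2 signal mean of expressing populations.
#' @param silent_log2_drop log2 units subtracted for silent populations.
#' @param within_pop_log2_sd within-population log2 standard deviation.
#' @param present_prob_expressing,present_prob_silent Bernoulli present-call
#'   probabilities.
#' @param present_prob_rescued_mmc present-call probability in MMC for
#'   `MYELOMA_RESCUED` genes, whose signals stay silent (default 0.25,
#'   "present in some of the tumor samples").
#' @param decoy_present_scale multiplicative presence degradation per decoy
#'   probe set (default 0.5).
#' @param wbm_tumor_weight tumor weight of the whole-bone-marrow mixture
#'   (default 0.3 tumor / 0.7 environment).
#' @param call_model `"bernoulli"` (default; calls independent of the drawn
#'   signal given the expressing state) or `"signal_threshold"` (present iff
#'   signal exceeds `call_threshold`).
#' @param call_threshold signal threshold for the signal-linked call model.
#' @param seed integer RNG seed; the generator is fully reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(population_sizes = c(MMC = 131, CD3 = 5,
                                                  CD14 = 5, PMN = 5,
                                                  BMSC = 5, OC = 7, MB = 6,
                                                  PPC = 7, BMPC = 7,
                                                  WBM = 0),
                             genes = default_panel(),
                             baseline_log2_mean = log2(100),
                             silent_log2_drop = 5,
                             within_pop_log2_sd = 0.5,
                             present_prob_expressing = 0.95,
                             present_prob_silent = 0.02,
                             present_prob_rescued_mmc = 0.25,
                             decoy_present_scale = 0.5,
                             wbm_tumor_weight = 0.3,
                             call_model = c("bernoulli",
                                            "signal_threshold"),
                             call_threshold = 10,
                             seed = 1L) {
  call_model <- match.arg(call_model)
  bad <- setdiff(names(population_sizes), POPULATION_LABELS)
  if (length(bad) > 0) stop("unknown population(s): ",
                            paste(bad, collapse = ", "))
  if (any(population_sizes < 0)) stop("population sizes must be >= 0")
  probs <- c(present_prob_expressing, present_prob_silent,
             present_prob_rescued_mmc, wbm_tumor_weight)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (within_pop_log2_sd <= 0) stop("within_pop_log2_sd must be > 0")
  if (!all(vapply(genes, inherits, logical(1), "planted_gene"))) {
    stop("genes must be a list of planted_gene objects")
  }
  syms <- vapply(genes, `[[`, character(1), "gene_symbol")
  if (anyDuplicated(syms)) stop("duplicate planted gene symbols")
  structure(list(population_sizes = population_sizes, genes = genes,
                 baseline_log2_mean = baseline_log2_mean,
                 silent_log2_drop = silent_log2_drop,
                 within_pop_log2_sd = within_pop_log2_sd,
                 present_prob_expressing = present_prob_expressing,
                 present_prob_silent = present_prob_silent,
                 present_prob_rescued_mmc = present_prob_rescued_mmc,
                 decoy_present_scale = decoy_present_scale,
                 wbm_tumor_weight = wbm_tumor_weight,
                 call_model = call_model, call_threshold = call_threshold,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic dataset with planted compartment structure
#'
#' Draws signals as `2^N(mu, sd^2)` with `mu` determined by the planted
#' expressing/winner structure, draws detection calls per the configured
#' call model, and returns the dataset together with the planted truth and
#' a matching gene catalog, so the full pipeline can run end to end.
#'
#' @param cfg a [synthetic_config()].
#' @return List with elements `dataset` (an [expression_dataset()]),
#'   `truth` (data frame: gene, planted_category, winner, fold_elevation,
#'   realized mean log2 fold of the winner populations, n_probesets) and
#'   `catalog` (a `gene_catalog` mapping genes to their generated probes).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  sizes <- cfg$population_sizes[cfg$population_sizes > 0]
  if (length(sizes) == 0) stop("no samples requested")
  pops <- rep(names(sizes), sizes)
  ids <- unlist(lapply(names(sizes), function(p) {
    sprintf("%s_%03d", p, seq_len(sizes[[p]]))
  }), use.names = FALSE)
  n <- length(ids)
  all_bm <- setdiff(POPULATION_LABELS, "WBM")
  env5 <- c(ENVIRONMENT_POPULATIONS, NICHE_POPULATIONS)

  probe_rows <- list()
  truth_rows <- list()
  cat_genes <- character(0)
  cat_probes <- list()
  for (g in cfg$genes) {
    mu <- setNames(rep(cfg$baseline_log2_mean - cfg$silent_log2_drop,
                       length(all_bm)), all_bm)
    pp <- setNames(rep(cfg$present_prob_silent, length(all_bm)), all_bm)
    mu[g$expressing_populations] <- cfg$baseline_log2_mean
    pp[g$expressing_populations] <- cfg$present_prob_expressing
    mu[g$winner_populations] <- cfg$baseline_log2_mean +
      log2(g$fold_elevation)
    if (g$planted_category == "MYELOMA_RESCUED") {
      pp["MMC"] <- cfg$present_prob_rescued_mmc
    }
    # whole bone marrow is a linear tumor/environment mixture
    w <- cfg$wbm_tumor_weight
    mu_wbm <- log2(w * 2^mu[["MMC"]] + (1 - w) * mean(2^mu[env5]))
    pp_wbm <- w * pp[["MMC"]] + (1 - w) * mean(pp[env5])
    mu_s <- c(mu, WBM = mu_wbm)[pops]
    pp_s <- c(pp, WBM = pp_wbm)[pops]

    probes <- if (g$n_probesets == 1) {
      paste0(g$gene_symbol, "_at")
    } else {
      c(paste0(g$gene_symbol, "_at"),
        paste0(g$gene_symbol, "_d", seq_len(g$n_probesets - 1), "_at"))
    }
    for (k in seq_along(probes)) {
      sig <- 2^rnorm(n, mu_s, cfg$within_pop_log2_sd)
      p_present <- pp_s * cfg$decoy_present_scale^(k - 1)
      calls <- if (cfg$call_model == "bernoulli") {
        ifelse(runif(n) < p_present, "P", "A")
      } else {
        ifelse(sig > cfg$call_threshold, "P", "A")
      }
      probe_rows[[probes[k]]] <- list(signal = sig, call = calls)
    }
    realized <- if (length(g$winner_populations) > 0) {
      base_pops <- setdiff(g$expressing_populations, g$winner_populations)
      win_sig <- log2(probe_rows[[probes[1]]]$signal[
        pops %in% g$winner_populations])
      base_sig <- log2(probe_rows[[probes[1]]]$signal[pops %in% base_pops])
      if (length(base_sig) > 0) mean(win_sig) - mean(base_sig) else NA_real_
    } else NA_real_
    truth_rows[[g$gene_symbol]] <- data.frame(
      gene = g$gene_symbol,
      planted_category = g$planted_category,
      winner = paste(g$winner_populations, collapse = ";"),
      fold_elevation = g$fold_elevation,
      realized_log2_fc = realized,
      n_probesets = g$n_probesets,
      stringsAsFactors = FALSE)
    cat_genes <- c(cat_genes, g$gene_symbol)
    cat_probes[[g$gene_symbol]] <- probes
  }
  signal <- do.call(rbind, lapply(probe_rows, `[[`, "signal"))
  call <- do.call(rbind, lapply(probe_rows, `[[`, "call"))
  dimnames(signal) <- list(names(probe_rows), ids)
  dimnames(call) <- list(names(probe_rows), ids)
  ds <- expression_dataset(signal, call,
                           data.frame(sample_id = ids, population = pops,
                                      stringsAsFactors = FALSE))
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  catalog <- gene_catalog(gene = cat_genes, family = "OTHER",
                          role = "LIGAND", probe_sets = cat_probes)
  list(dataset = ds, truth = truth, catalog = catalog)
}

#' Confusion table and recall of a classification against the planted truth
#'
#' @param truth the `truth` data frame from [generate_dataset()].
#' @param assignments a `category_assignment` from
#'   [classify_compartments()] over the same genes.
#' @return List with `confusion` (planted x assigned table),
#'   `recall_by_category` (per planted category) and `overall_recall`
#'   (fraction of genes assigned their planted category).
#' @export
recovery_report <- function(truth, assignments) {
  if (!setequal(truth$gene, assignments$gene)) {
    stop("truth and assignments cover different gene sets; only in truth: ",
         paste(setdiff(truth$gene, assignments$gene), collapse = ", "),
         "; only in assignments: ",
         paste(setdiff(assignments$gene, truth$gene), collapse = ", "))
  }
  assigned <- assignments$category[match(truth$gene, assignments$gene)]
  planted <- factor(truth$planted_category, levels = COMPARTMENT_CATEGORIES)
  assigned <- factor(assigned, levels = COMPARTMENT_CATEGORIES)
  confusion <- table(planted = planted, assigned = assigned)
  per_cat <- diag(confusion) / rowSums(confusion)
  list(confusion = confusion,
       recall_by_category = per_cat[!is.nan(per_cat)],
       overall_recall = mean(as.character(planted) == as.character(assigned)))
}
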