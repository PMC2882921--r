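# Two-group contrast engine: Student t-test on log2 signals,
# Benjamini-Hochberg adjustment across the gene set of the contrast, linear
# fold change, and the all-absent-in-winner exclusion flag.

#' Two-sample Student t-test
#'
#' Pooled-variance two-sample t with `n_a + n_b - 2` degrees of freedom and
#' a two-sided p value (Welch's unequal-variance form when `welch = TRUE`).
#' Degenerate inputs follow fixed conventions: zero pooled variance with
#' equal means gives `t = 0, p = 1`; zero pooled variance with unequal means
#' gives `t = +/-Inf, p = 0`.
#'
#' @param a,b numeric vectors with at least two values each.
#' @param welch use the Welch t instead of the pooled Student t.
#' @return List with elements `t` and `p`.
#' @export
student_t <- function(a, b, welch = FALSE) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("student_t needs at least 2 values per group")
  ma <- mean(a); mb <- mean(b)
  va <- var(a); vb <- var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      if (ma == mb) return(list(t = 0, p = 1))
      return(list(t = sign(ma - mb) * Inf, p = 0))
    }
    tt <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) {
      if (ma == mb) return(list(t = 0, p = 1))
      return(list(t = sign(ma - mb) * Inf, p = 0))
    }
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  list(t = tt, p = 2 * pt(-abs(tt), df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' For ascending order statistics the adjusted value is
#' `min over j >= i of p_(j) * m / j`, capped at 1 and mapped back to the
#' input order; tied p values share an adjusted value.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

resolve_group <- function(ds, group, default_label = NULL) {
  group <- as.character(group)
  if (all(group %in% POPULATION_LABELS)) {
    ids <- samples_of(ds, group)
    label <- paste(group, collapse = "+")
  } else {
    missing <- setdiff(group, ds$samples$sample_id)
    if (length(missing) > 0) {
      stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    }
    ids <- group
    label <- if (is.null(default_label)) "custom" else default_label
  }
  if (!is.null(default_label)) label <- default_label
  list(ids = ids, label = label)
}

#' Compare two sample groups across a set of genes
#'
#' Runs one two-group contrast per gene: Student t on the (by default)
#' log2-transformed floored signals, Benjamini-Hochberg adjustment across
#' exactly the genes of this call, fold change as the ratio of linear-scale
#' means, presence fractions per group, and the biological-relevance flag
#' `all_absent_in_winner` (no present call in the group with the higher
#' mean). A gene is `significant_over_b` when the adjusted p is at most
#' `cfg$alpha`, the fold change is at least `cfg$min_fold_change`, and the
#' winner group is not all-absent. Whole bone marrow (WBM) samples are a
#' tumor/environment mixture and are rejected from either group.
#'
#' @param ds an [expression_dataset()] (scaled and floored).
#' @param views list of `gene_view` objects from [gene_views()].
#' @param group_a,group_b population label(s) or sample identifier vectors;
#'   the two groups must be disjoint, contain at least two samples each,
#'   and contain no WBM sample.
#' @param cfg an [analysis_config()].
#' @param label_a,label_b optional display labels for pooled groups.
#' @return A `contrast_result` data frame with one row per gene.
#' @export
compare_groups <- function(ds, views, group_a, group_b,
                           cfg = analysis_config(),
                           label_a = NULL, label_b = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  ga <- resolve_group(ds, group_a, label_a)
  gb <- resolve_group(ds, group_b, label_b)
  if (length(intersect(ga$ids, gb$ids)) > 0) {
    stop("groups overlap: ",
         paste(intersect(ga$ids, gb$ids), collapse = ", "))
  }
  pops <- ds$samples$population[match(c(ga$ids, gb$ids),
                                      ds$samples$sample_id)]
  if (any(pops == "WBM")) {
    stop("WBM samples are a tumor/environment mixture and cannot enter a ",
         "supervised contrast")
  }
  if (length(ga$ids) < 2 || length(gb$ids) < 2) {
    stop("each group needs at least 2 samples")
  }
  rows <- lapply(views, function(v) {
    sa <- v$signal[ga$ids]; sb <- v$signal[gb$ids]
    ta <- if (cfg$log2_test) log2(pmax(sa, cfg$signal_floor)) else sa
    tb <- if (cfg$log2_test) log2(pmax(sb, cfg$signal_floor)) else sb
    tst <- student_t(ta, tb, welch = cfg$welch)
    mean_a <- mean(sa); mean_b <- mean(sb)
    fc <- mean_a / mean_b
    pf_a <- presence_fraction(v$call[ga$ids])
    pf_b <- presence_fraction(v$call[gb$ids])
    data.frame(gene = v$gene_symbol, probe = v$probe,
               group_a = ga$label, group_b = gb$label,
               n_a = length(ga$ids), n_b = length(gb$ids),
               mean_a = mean_a, mean_b = mean_b,
               median_a = median(sa), median_b = median(sb),
               fold_change = fc,
               t_statistic = tst$t, p_raw = tst$p,
               present_frac_a = pf_a, present_frac_b = pf_b,
               all_absent_in_winner = if (fc >= 1) pf_a == 0 else pf_b == 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adj <- benjamini_hochberg(res$p_raw)
  res$significant_over_b <- res$p_adj <= cfg$alpha &
    res$fold_change >= cfg$min_fold_change &
    !res$all_absent_in_winner
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Write a contrast table to TSV
#'
#' @param res a `contrast_result`.
#' @param path output path.
#' @export
write_contrasts <- function(res, path) {
  cols <- c("gene", "probe", "group_a", "group_b", "n_a", "n_b",
            "mean_a", "mean_b", "median_a", "median_b", "fold_change",
            "t_statistic", "p_raw", "p_adj", "present_frac_a",
            "present_frac_b", "all_absent_in_winner", "significant_over_b")
  utils::write.table(as.data.frame(res)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
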