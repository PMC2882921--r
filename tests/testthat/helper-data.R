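# In-code fixtures shared across test files.

# Build a small expression dataset. `pops` is a named vector mapping sample
# id -> population; `signal` a probe x sample matrix (rownames/colnames set
# from probes/names(pops) when missing); `call` defaults to all present.
make_ds <- function(signal, pops, call = NULL) {
  if (is.null(rownames(signal))) {
    rownames(signal) <- sprintf("p%d", seq_len(nrow(signal)))
  }
  if (is.null(colnames(signal))) colnames(signal) <- names(pops)
  if (is.null(call)) {
    call <- matrix("P", nrow(signal), ncol(signal),
                   dimnames = dimnames(signal))
  } else {
    dimnames(call) <- dimnames(signal)
  }
  expression_dataset(signal, call, pops)
}

# Deterministic compartment fixture: constant within-population signals so
# every intended contrast is either exactly null (t = 0) or infinitely
# separated (t = Inf, p = 0), making the rule cascade decidable by hand.
# One gene per category plus a gene that probes rule precedence.
compartment_fixture <- function() {
  pops <- c(rep("MMC", 8), rep("CD3", 2), rep("CD14", 2), rep("PMN", 2),
            rep("BMSC", 2), rep("OC", 2))
  names(pops) <- sprintf("%s_%02d", pops, unlist(lapply(rle(pops)$lengths,
                                                        seq_len)))
  n <- length(pops)
  level <- function(vals) vals[match(pops, names(vals))]
  base <- c(MMC = 100, CD3 = 100, CD14 = 100, PMN = 100, BMSC = 100,
            OC = 100)
  rows <- list(
    # tumor-cell gene: 8-fold up in MMC, expressed everywhere
    MYE = level(replace(base, "MMC", 800)),
    # stromal-niche gene beaten by OC: still NICHE_BMSC because the cascade
    # never requires BMSC to beat the other niche population
    BN = level(replace(replace(base, "BMSC", 800), "OC", 1600)),
    # environment gene: monocytes over tumor and niche only
    ENVG = level(replace(base, "CD14", 800)),
    # silent gene
    NOEXP = rep(1, n),
    # rescued gene: flat signal, present calls only in some MMC samples
    RESC = rep(100, n),
    # expressed everywhere with no winner
    SHRD = rep(100, n),
    # precedence probe: overexpressed in MMC *and* absent everywhere else;
    # the significance rule must claim it before the rescue rule can
    PREC = level(replace(replace(base, "MMC", 800),
                         c("CD3", "CD14", "PMN", "BMSC", "OC"), 1))
  )
  signal <- do.call(rbind, lapply(rows, unname))
  colnames(signal) <- names(pops)
  call <- matrix("P", nrow(signal), n, dimnames = list(names(rows),
                                                       names(pops)))
  call["NOEXP", ] <- "A"
  call["RESC", ] <- "A"
  call["RESC", c("MMC_01", "MMC_02")] <- "P"
  call["PREC", pops != "MMC"] <- "A"
  list(ds = make_ds(signal, pops, call),
       expected = c(MYE = "MYELOMA", BN = "NICHE_BMSC",
                    ENVG = "ENVIRONMENT", NOEXP = "NOT_EXPRESSED",
                    RESC = "MYELOMA_RESCUED", SHRD = "SHARED",
                    PREC = "MYELOMA"))
}

views_from_probes <- function(ds) {
  views <- lapply(rownames(ds$signal), function(p) {
    structure(list(gene_symbol = p, probe = p, signal = ds$signal[p, ],
                   call = ds$call[p, ]), class = "gene_view")
  })
  names(views) <- rownames(ds$signal)
  views
}

# Independent step-up oracle for the Benjamini-Hochberg adjustment:
# adj_(i) = min over j >= i of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

gf_catalog_path <- function() {
  system.file("extdata", "growth_factor_catalog.csv", package = "mgfscreen")
}
receptor_table_path <- function() {
  system.file("extdata", "receptor_expression_mmc.csv", package = "mgfscreen")
}
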