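test_that("the growth-factor catalog transcription yields the printed family counts", {
  cat1 <- load_catalog(gf_catalog_path())
  expect_equal(unname(count_interrogable(cat1, "FGF", "LIGAND")), c(13, 22))
  expect_equal(unname(count_interrogable(cat1, "WNT", "LIGAND")), c(11, 19))
  expect_equal(unname(count_interrogable(cat1, "VEGF", "LIGAND")), c(3, 4))
  # 32 previously reported MGF, 28 interrogable, of which 4 belong to the
  # extended families; reassigning those leaves 24 known-MGF genes
  known <- cat1[cat1$known_mgf, ]
  expect_equal(nrow(known), 32)
  expect_equal(sum(known$interrogable), 28)
  overlap <- known$gene[known$interrogable &
                          known$family %in% c("FGF", "VEGF", "WNT")]
  expect_setequal(overlap, c("FGF2", "VEGFA", "Wnt5A", "Wnt16"))
  # 51 growth factors interrogable in total
  expect_equal(count_interrogable(cat1, role = "LIGAND")[["n_interrogable"]],
               51)
  # Wnt3A has no probe set at all
  expect_false(cat1$interrogable[cat1$gene == "Wnt3A"])
})

test_that("family counts partition the catalog total", {
  cat1 <- load_catalog(gf_catalog_path())
  per_family <- sapply(GENE_FAMILIES, function(f) {
    count_interrogable(cat1, f, "LIGAND")
  })
  expect_equal(sum(per_family["n_total", ]),
               count_interrogable(cat1, role = "LIGAND")[["n_total"]])
  expect_equal(sum(per_family["n_interrogable", ]),
               count_interrogable(cat1, role = "LIGAND")[["n_interrogable"]])
})

test_that("catalog validation rejects duplicates and unknown tokens", {
  expect_error(
    gene_catalog(gene = c("FGF7", "FGF7"), family = "FGF", role = "LIGAND",
                 probe_sets = list("230918_at", "x_at")),
    "FGF7")
  expect_error(
    gene_catalog(gene = "A", family = "NOT_A_FAMILY", role = "LIGAND",
                 probe_sets = list("p_at")),
    "family")
  expect_error(
    gene_catalog(gene = "A", family = "FGF", role = "DRIVER",
                 probe_sets = list("p_at")),
    "role")
  # a receptor_of target present in the catalog must be a ligand
  expect_error(
    gene_catalog(gene = c("R1", "R2"), family = "OTHER",
                 role = "RECEPTOR", probe_sets = list("a_at", "b_at"),
                 receptor_of = c("R2", NA)),
    "LIGAND")
})

test_that("an empty catalog file and empty selections are handled", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("gene,family,role,probe_sets", f)
  empty <- load_catalog(f)
  expect_equal(nrow(empty), 0)
  expect_equal(unname(count_interrogable(empty, "FGF", "LIGAND")), c(0, 0))
})

test_that("interrogability tracks probe-set availability row by row", {
  cat1 <- load_catalog(gf_catalog_path())
  expect_equal(cat1$interrogable,
               unname(vapply(cat1$probe_sets, function(x) length(x) > 0,
                             logical(1))))
  expect_true(cat1$interrogable[cat1$gene == "FGF7"])
  expect_identical(cat1$probe_sets[[which(cat1$gene == "FGF7")]],
                   "230918_at")
})

test_that("dataset loading reconciles call axes by identifier", {
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "signal.tsv")
  cp <- file.path(dir, "call.tsv")
  mp <- file.path(dir, "samples.tsv")
  writeLines(c("probe_id\ts1\ts2\ts3",
               "p1\t1.5\t2\t3",
               "p2\t4\t5\t6.25"), sp)
  # call columns deliberately permuted relative to the signal file
  writeLines(c("probe_id\ts3\ts1\ts2",
               "p2\tA\tP\tM",
               "p1\tP\tP\tA"), cp)
  writeLines(c("sample_id\tpopulation",
               "s1\tMMC", "s2\tMMC", "s3\tBMSC"), mp)
  ds <- load_dataset(sp, cp, mp)
  expect_equal(dim(ds$signal), c(2, 3))
  expect_equal(ds$call["p1", ], c(s1 = "P", s2 = "A", s3 = "P"))
  expect_equal(ds$call["p2", ], c(s1 = "P", s2 = "M", s3 = "A"))
  expect_equal(ds$signal["p2", "s3"], 6.25)

  # invalid call token errors with its coordinates
  writeLines(c("probe_id\ts1\ts2\ts3",
               "p1\tP\tX\tP",
               "p2\tP\tP\tP"), cp)
  expect_error(load_dataset(sp, cp, mp), "p1,s2")

  # axis mismatch errors name the offending identifiers
  writeLines(c("probe_id\ts1\ts2\ts4",
               "p1\tP\tP\tP",
               "p2\tP\tP\tP"), cp)
  expect_error(load_dataset(sp, cp, mp), "s4")
})

test_that("datasets and catalogs round-trip through their file formats", {
  set.seed(42)
  pops <- setNames(c("MMC", "MMC", "BMSC", "BMSC", "OC"),
                   sprintf("s%d", 1:5))
  signal <- matrix(2^rnorm(15, 6, 1), 3, 5)
  call <- matrix(sample(c("P", "M", "A"), 15, replace = TRUE), 3, 5)
  ds <- make_ds(signal, pops, call)
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("s.tsv", "c.tsv", "m.tsv"))
  write_dataset(ds, paths[1], paths[2], paths[3])
  ds2 <- load_dataset(paths[1], paths[2], paths[3])
  expect_identical(ds2$signal, ds$signal)
  expect_identical(ds2$call, ds$call)
  expect_identical(ds2$samples, ds$samples)

  cat1 <- load_catalog(gf_catalog_path())
  cp <- file.path(dir, "cat.csv")
  write_catalog(cat1, cp)
  cat2 <- load_catalog(cp)
  expect_identical(cat2$gene, cat1$gene)
  expect_identical(cat2$probe_sets, cat1$probe_sets)
  expect_identical(cat2$interrogable, cat1$interrogable)
})

test_that("a sample may carry only one known population label", {
  sig <- matrix(1:4, 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  call <- matrix("P", 2, 2)
  expect_error(make_ds(sig, c(s1 = "MMC", s2 = "TUMOR")), "TUMOR")
  expect_error(
    expression_dataset(sig, matrix("P", 2, 2, dimnames = dimnames(sig)),
                       data.frame(sample_id = c("s1", "s1", "s2"),
                                  population = "MMC")),
    "s1")
})
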