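test_that("arrays are scaled to the target average intensity and floored", {
  pops <- c(s1 = "MMC", s2 = "MMC", s3 = "BMSC")
  signal <- cbind(s1 = c(2, 4, 6), s2 = c(100, 100, 100),
                  s3 = c(0.3, 0.3, 599.4))
  rownames(signal) <- c("p1", "p2", "p3")
  ds <- make_ds(signal, pops)
  scaled <- scale_dataset(ds, analysis_config())
  # factor 100/4 for s1
  expect_equal(unname(scaled$signal[, "s1"]), c(50, 100, 150))
  # a sample already at the target mean is unchanged
  expect_equal(unname(scaled$signal[, "s2"]), c(100, 100, 100))
  # values under 1 after scaling are set to 1 (0.3 * 100/200 = 0.15 -> 1)
  expect_equal(unname(scaled$signal[, "s3"]), c(1, 1, 299.7))
  # calls untouched
  expect_identical(scaled$call, ds$call)
})

test_that("scaling restores the target mean and respects the floor on random data", {
  set.seed(7)
  for (rep in 1:5) {
    signal <- matrix(2^rnorm(200, 6, 2), 20, 10,
                     dimnames = list(sprintf("p%d", 1:20),
                                     sprintf("s%d", 1:10)))
    pops <- setNames(rep("MMC", 10), colnames(signal))
    ds <- make_ds(signal, pops)
    nofloor <- scale_dataset(ds, analysis_config(signal_floor = 0))
    expect_equal(unname(colMeans(nofloor$signal)), rep(100, 10),
                 tolerance = 1e-9)
    floored <- scale_dataset(ds, analysis_config())
    expect_true(all(floored$signal >= 1))
    # idempotence: rescaling unfloored output changes nothing
    again <- scale_dataset(nofloor, analysis_config(signal_floor = 0))
    expect_equal(again$signal, nofloor$signal, tolerance = 1e-9)
  }
})

test_that("a sample with zero mean signal cannot be scaled", {
  signal <- cbind(s1 = c(0, 0), s2 = c(1, 2))
  rownames(signal) <- c("p1", "p2")
  ds <- make_ds(signal, c(s1 = "MMC", s2 = "MMC"))
  expect_error(scale_dataset(ds), "s1")
})

test_that("presence counts only P calls; marginal is not-present", {
  expect_equal(presence_fraction(c("P", "P", "A")), 2 / 3)
  expect_equal(presence_fraction(c("M", "M", "M")), 0)
  expect_equal(presence_fraction(rep("P", 5)), 1)
  expect_error(presence_fraction(character(0)), "empty")
})

test_that("the 95%-absent informativeness boundary behaves exactly as stated", {
  pops <- setNames(rep("MMC", 20), sprintf("s%02d", 1:20))
  signal <- matrix(10, 3, 20, dimnames = list(c("absent19", "absent18",
                                                "allP"), names(pops)))
  call <- matrix("P", 3, 20, dimnames = dimnames(signal))
  call["absent19", 1:19] <- "A"   # 19/20 = 0.95 not-present -> excluded
  call["absent18", 1:18] <- "A"   # 18/20 = 0.90 -> retained
  ds <- make_ds(signal, pops, call)
  kept <- informative_probesets(ds, analysis_config())
  expect_setequal(kept, c("absent18", "allP"))
})

test_that("raising the informativeness threshold never drops a retained probe", {
  set.seed(13)
  for (rep in 1:10) {
    pops <- setNames(rep("MMC", 12), sprintf("s%d", 1:12))
    call <- matrix(sample(c("P", "A"), 8 * 12, replace = TRUE,
                          prob = c(0.3, 0.7)), 8, 12)
    signal <- matrix(10, 8, 12)
    ds <- make_ds(signal, pops, call)
    kept_lo <- informative_probesets(ds, analysis_config(
      noninformative_absent_frac = 0.6))
    kept_hi <- informative_probesets(ds, analysis_config(
      noninformative_absent_frac = 0.9))
    expect_true(all(kept_lo %in% kept_hi))
  }
})

test_that("probe-set selection prefers presence, then variance, then identifier", {
  pops <- setNames(rep("MMC", 5), sprintf("s%d", 1:5))
  signal <- rbind(hi_pres = c(10, 10, 10, 10, 10),
                  lo_pres = c(90, 10, 10, 10, 10),
                  var_small = c(10, 11, 12, 13, 14),
                  var_big = c(10, 20, 30, 40, 50),
                  tie_a = c(5, 5, 5, 5, 5),
                  tie_b = c(5, 5, 5, 5, 5))
  colnames(signal) <- names(pops)
  call <- matrix("P", 6, 5, dimnames = dimnames(signal))
  call["hi_pres", 1] <- "A"    # 80% presence
  call["lo_pres", 1:2] <- "A"  # 60% presence
  ds <- make_ds(signal, pops, call)

  pick <- function(probes) {
    select_probeset(list(gene = "G", probe_sets = probes), ds)$probe
  }
  expect_equal(pick(c("hi_pres", "lo_pres")), "hi_pres")
  # both at 100% presence: the higher-variance probe wins
  expect_equal(pick(c("var_small", "var_big")), "var_big")
  # full tie: lexicographic identifier
  expect_equal(pick(c("tie_b", "tie_a")), "tie_a")
  expect_equal(pick("lo_pres"), "lo_pres")
  expect_error(pick("not_here"), "G")
})

test_that("probe-set selection agrees with a brute-force scorer on random instances", {
  set.seed(99)
  for (rep in 1:30) {
    n_probe <- sample(2:5, 1)
    n_samp <- sample(4:8, 1)
    pops <- setNames(rep("MMC", n_samp), sprintf("s%d", seq_len(n_samp)))
    signal <- matrix(round(2^rnorm(n_probe * n_samp, 5, 1), 3),
                     n_probe, n_samp,
                     dimnames = list(sample(sprintf("pr%02d",
                                                    seq_len(n_probe))),
                                     names(pops)))
    call <- matrix(sample(c("P", "A"), n_probe * n_samp, replace = TRUE),
                   n_probe, n_samp, dimnames = dimnames(signal))
    ds <- make_ds(signal, pops, call)
    chosen <- select_probeset(list(gene = "G",
                                   probe_sets = rownames(signal)), ds)$probe
    # exhaustive scorer: best presence, then variance, then identifier
    best <- NULL
    for (p in sort(rownames(signal))) {
      sc <- c(mean(call[p, ] == "P"), var(signal[p, ]))
      if (is.null(best) || sc[1] > best$sc[1] ||
          (sc[1] == best$sc[1] && sc[2] > best$sc[2])) {
        best <- list(p = p, sc = sc)
      }
    }
    expect_equal(chosen, best$p)
  }
})
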