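test_that("label mass shifts reproduce the five nominal SILAC deltas", {
  expect_equal(round(label_mass_shift(1, 0), 2), 6.02)
  expect_equal(round(label_mass_shift(0, 1), 2), 10.01)
  expect_equal(round(label_mass_shift(2, 0), 2), 12.04)
  expect_equal(round(label_mass_shift(1, 1), 2), 16.03)
  expect_equal(round(label_mass_shift(0, 2), 2), 20.02)
  # unrounded value from the isotope-mass arithmetic
  expect_equal(label_mass_shift(0, 2), 2 * (6 * 1.003355 + 4 * 0.997035))
  expect_error(label_mass_shift(0, 0), "no SILAC pair")
  expect_error(label_mass_shift(-1, 1), ">= 0")
})

test_that("label mass shift is additive in residue counts", {
  for (a in 0:3) for (b in 0:3) for (cc in 0:3) for (d in 0:3) {
    if ((a + cc) == 0 && (b + d) == 0) next
    lhs <- label_mass_shift(a + cc, b + d)
    rhs <- (if (a + b > 0) label_mass_shift(a, b) else 0) +
      (if (cc + d > 0) label_mass_shift(cc, d) else 0)
    expect_equal(lhs, rhs)
  }
})

test_that("SILAC pair matching finds nominal-shift pairs and nothing else", {
  pk <- tibble::tibble(mz = c(1000.00, 1006.02), intensity = c(10, 20))
  m <- match_silac_pairs(pk, tolerance = 0.05)
  expect_equal(nrow(m), 1)
  expect_equal(m$shift_class, "K1")
  expect_equal(m$light_intensity, 10)

  pk2 <- tibble::tibble(mz = c(1000.00, 1003.00), intensity = c(1, 1))
  expect_equal(nrow(match_silac_pairs(pk2, 0.05)), 0)

  # 1010.01 stays unmatched: 1000.00 is consumed by the K1 pair and
  # 1010.01 - 1006.02 = 3.99 matches no nominal shift
  pk3 <- tibble::tibble(mz = c(1000.00, 1006.02, 1010.01),
                        intensity = c(1, 1, 1))
  m3 <- match_silac_pairs(pk3, 0.05)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$light_mz, 1000.00)
  expect_equal(m3$heavy_mz, 1006.02)

  expect_error(match_silac_pairs(pk, tolerance = -0.1), "> 0")
})

test_that("pair matching is permutation-stable and never reuses a peak", {
  withr::local_seed(7)
  shifts <- c(6.02, 10.01, 12.04, 16.03, 20.02)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    base <- sort(runif(n, 800, 1200))
    # seed some true pairs among noise
    mz <- c(base, base[1] + sample(shifts, 1) + runif(1, -0.03, 0.03))
    pk <- tibble::tibble(mz = mz, intensity = runif(length(mz), 1, 100))
    m <- match_silac_pairs(pk, 0.05)
    perm <- pk[sample(nrow(pk)), ]
    expect_equal(match_silac_pairs(perm, 0.05), m)
    used <- c(m$light_mz, m$heavy_mz)
    expect_equal(anyDuplicated(used), 0)
    if (nrow(m)) {
      dev <- vapply(m$delta, function(d) min(abs(d - shifts)), 1)
      expect_true(all(dev <= 0.05))
    }
  }
})

test_that("pair ratio respects orientation and one-channel capping", {
  expect_equal(pair_ratio(200, 100, "forward"), list(ratio = 2, capped = FALSE))
  expect_equal(pair_ratio(100, 200, "reverse"), list(ratio = 2, capped = FALSE))
  expect_equal(pair_ratio(500, 0, "forward", cap = 100),
               list(ratio = 100, capped = TRUE))
  # reverse with a dead heavy (live) channel is also one-channel
  expect_equal(pair_ratio(0, 500, "reverse", cap = 100),
               list(ratio = 100, capped = TRUE))
  expect_error(pair_ratio(0, 0, "forward"), "zero")

  # label-swap symmetry: forward(h, l) == reverse(l, h)
  withr::local_seed(1)
  for (rep in 1:20) {
    h <- runif(1, 1, 1000); l <- runif(1, 1, 1000)
    expect_equal(pair_ratio(h, l, "forward"), pair_ratio(l, h, "reverse"))
  }
})

test_that("gel sections are half-open [lo, hi) with out-of-range handling", {
  b <- c(5, 10, 15, 20)
  expect_equal(assign_gel_section(7.5, b),
               list(section = 1L, mwexp_lo = 5, mwexp_hi = 10))
  expect_equal(assign_gel_section(10, b)$section, 2L)  # boundary goes up
  expect_equal(assign_gel_section(10, b)$mwexp_lo, 10)
  expect_equal(assign_gel_section(3, b)$section, 1L)   # below range: lowest band
  expect_error(assign_gel_section(20, b), "above the top boundary")

  # intact actin lands well above the 5-10 kDa band
  s <- assign_gel_section(41.793)
  expect_gt(s$mwexp_lo, 10)
})

test_that("classification applies the MW rule before abundance thresholds", {
  cfg <- nf_config()
  ctsc <- quant_entry("P53634", ratio = 3.5849, mwcal = 51.854,
                      mwexp_lo = 15, mwexp_hi = 20)
  expect_equal(classify_protein(ctsc, cfg)$label, "FRAGMENTED")

  # ratio barely above 1 still fragments when the MW rule fires
  or5h2 <- quant_entry("Q8NGV7", ratio = 1.01, mwcal = 35.974,
                       mwexp_lo = 5, mwexp_hi = 10)
  expect_equal(classify_protein(or5h2, cfg)$label, "FRAGMENTED")

  expect_equal(classify_protein(quant_entry(ratio = 3), cfg)$label,
               "UPREGULATED")
  expect_equal(classify_protein(quant_entry(ratio = 0.3), cfg)$label,
               "DOWNREGULATED")
  expect_equal(classify_protein(quant_entry(ratio = 1.2), cfg)$label,
               "UNCHANGED")
  # intact but one-channel: capped counts as enrichment only under the MW rule
  expect_equal(classify_protein(quant_entry(ratio = 100, capped = TRUE),
                                cfg)$label, "UPREGULATED")
})

test_that("every entry gets exactly one label and MW precedence is stable", {
  withr::local_seed(11)
  for (rep in 1:50) {
    frag <- runif(1) < 0.5
    mwcal <- runif(1, 20, 100)
    e <- quant_entry(ratio = exp(rnorm(1, 0, 1.2)),
                     mwcal = mwcal,
                     mwexp_lo = if (frag) 5 else mwcal - 3,
                     mwexp_hi = if (frag) 10 else mwcal + 3)
    lab <- classify_protein(e)$label
    expect_true(lab %in% c("FRAGMENTED", "UPREGULATED", "DOWNREGULATED",
                           "UNCHANGED"))
    if (lab == "FRAGMENTED") {
      # crossing the up-threshold never demotes a fragment call
      e2 <- e; e2$ratio <- max(e$ratio * 10, 2.5)
      expect_equal(classify_protein(e2)$label, "FRAGMENTED")
    }
  }
})

test_that("classify_quant matches rowwise classification and rejects duplicates", {
  f <- read_quant_table(table1_path("forward"), "forward")
  cq <- classify_quant(f)
  rowwise <- vapply(seq_len(nrow(f)),
                    function(i) classify_protein(f[i, ])$label, "")
  expect_equal(cq$label, rowwise)
  expect_error(classify_quant(rbind(f, f[1, ])), "duplicate accession")
})

test_that("replicate concordance intersects fragment calls by accession", {
  cf <- classify_quant(read_quant_table(table1_path("forward"), "forward"))
  cr <- classify_quant(read_quant_table(table1_path("reverse"), "reverse"))
  shared <- replicate_concordance(cf, cr)
  expect_equal(shared, sort(c("P53634", "P63261", "Q8NGV7", "Q8IZ41",
                              "Q86UE4", "P07602")))
  # disjoint and identical call sets
  expect_equal(replicate_concordance(cf[1:3, ], cf[4:6, ]), character(0))
  expect_equal(replicate_concordance(cf, cf),
               sort(cf$accession[cf$label == "FRAGMENTED"]))
})
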