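protein_of <- function(L, accession = "P1") {
  withr::with_seed(L, tibble::tibble(
    accession = accession, gene = "G",
    sequence = paste(sample(c("A", "C", "D", "E", "G", "K", "L", "R"),
                            L, replace = TRUE), collapse = "")))
}

test_that("target regions expand by the flank, clip, and merge", {
  p <- protein_of(100)
  ev <- tibble::tibble(accession = "P1", start = 41L, end = 52L)
  r <- extract_target_regions(p, ev, flank = 20)
  expect_equal(c(r$start, r$end), c(21L, 72L))

  p30 <- protein_of(30)
  ev2 <- tibble::tibble(accession = "P1", start = 3L, end = 10L)
  r2 <- extract_target_regions(p30, ev2, flank = 20)
  expect_equal(c(r2$start, r2$end), c(1L, 30L))

  p200 <- protein_of(200)
  ev3 <- tibble::tibble(accession = "P1", start = c(41L, 60L),
                        end = c(52L, 70L))
  r3 <- extract_target_regions(p200, ev3, flank = 20)
  expect_equal(nrow(r3), 1)
  expect_equal(c(r3$start, r3$end), c(21L, 90L))

  ev_bad <- tibble::tibble(accession = "P1", start = 150L, end = 260L)
  expect_error(extract_target_regions(p200, ev_bad, 20), "bounds")
})

test_that("region merging agrees with a residue-set union oracle", {
  withr::local_seed(5)
  for (rep in 1:30) {
    L <- sample(60:400, 1)
    k <- sample(1:5, 1)
    s <- sample(seq_len(L - 10), k)
    e <- pmin(s + sample(5:30, k, replace = TRUE), L)
    keep <- e - s + 1 >= 6
    if (!any(keep)) next
    ev <- tibble::tibble(accession = "P1", start = as.integer(s[keep]),
                         end = as.integer(e[keep]))
    flank <- sample(0:25, 1)
    got <- extract_target_regions(protein_of(L), ev, flank)
    want <- region_union_oracle(ev$start, ev$end, flank, L)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("tiling steps by length minus overlap with a right-anchored tail", {
  p <- protein_of(200)
  reg <- function(s, e) tibble::tibble(accession = "P1", start = s, end = e)

  t1 <- tile_region(reg(1L, 20L), p)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$sequence, substr(p$sequence, 1, 20))

  t36 <- tile_region(reg(1L, 36L), p)
  expect_equal(t36$start, c(1L, 9L, 17L))
  expect_equal(diff(t36$start), c(8, 8))  # 12-residue overlaps

  t30 <- tile_region(reg(1L, 30L), p)
  expect_equal(t30$start, c(1L, 9L, 11L))
  expect_equal(t30$end[3], 30L)
  # consecutive overlaps 12 then 18
  expect_equal(t30$end[-3] - t30$start[-1] + 1L, c(12L, 18L))

  short <- tile_region(reg(1L, 15L), p)
  expect_true(short$short)
  expect_equal(c(short$start, short$end), c(1L, 15L))

  expect_error(tile_region(reg(1L, 40L), p, length = 20, overlap = 20),
               "overlap")
})

test_that("tile counts follow the closed form for all region lengths 20-200", {
  p <- protein_of(250)
  for (R in 20:200) {
    tiles <- tile_region(tibble::tibble(accession = "P1", start = 1L,
                                        end = as.integer(R)), p)
    expect_equal(nrow(tiles), tile_count_oracle(R),
                 info = paste("region length", R))
    # tiles cover the region exactly and stay inside it
    expect_equal(min(tiles$start), 1L)
    expect_equal(max(tiles$end), R)
    covered <- sort(unique(unlist(mapply(seq, tiles$start, tiles$end,
                                         SIMPLIFY = FALSE))))
    expect_equal(covered, 1:R)
    # every tile is full length and every consecutive overlap >= 12
    expect_true(all(tiles$end - tiles$start + 1L == 20L))
    if (nrow(tiles) > 1 && R >= 2 * 20 - 12) {
      ov <- tiles$end[-nrow(tiles)] - tiles$start[-1] + 1L
      expect_true(all(ov >= 12))
    }
  }
})

test_that("tiling is translation-invariant", {
  p <- protein_of(300)
  base <- tile_region(tibble::tibble(accession = "P1", start = 1L, end = 53L), p)
  shifted <- tile_region(tibble::tibble(accession = "P1", start = 101L,
                                        end = 153L), p)
  expect_equal(shifted$start, base$start + 100L)
  expect_equal(shifted$end, base$end + 100L)
})

test_that("library design is deterministic, sorted, and validates evidence", {
  p <- protein_of(100, "P1")
  p2 <- p; p2$accession <- "P0"  # identical sequence, different accession
  proteins <- rbind(p, p2)
  ev <- tibble::tibble(accession = c("P1", "P0"), start = c(25L, 25L),
                       end = c(36L, 36L))
  lib <- design_peptide_library(proteins, evidence = ev,
                                accessions = c("P1", "P0"))
  # evidence (25,36) + flank 20 -> region (5,56) of length 52: (52-20)/8 exact
  expect_equal(nrow(lib), 2 * tile_count_oracle(52))
  expect_equal(lib$accession, sort(lib$accession))
  a <- lib[lib$accession == "P0", ]; b <- lib[lib$accession == "P1", ]
  expect_equal(a$sequence, b$sequence)
  expect_equal(a$start, b$start)
  expect_equal(b$tile_id, paste0("P1_", b$start))

  # a 52-residue region yields 5 tiles
  ev52 <- tibble::tibble(accession = "P1", start = 21L, end = 32L)
  lib52 <- design_peptide_library(rbind(p), evidence = ev52,
                                  accessions = "P1",
                                  config = nf_config(flank_residues = 20))
  expect_equal(nrow(lib52), 5)

  calls <- tibble::tibble(accession = "P1", label = "UNCHANGED")
  expect_equal(nrow(design_peptide_library(proteins, calls, ev)), 0)
  expect_error(design_peptide_library(proteins, evidence = ev[1, ],
                                      accessions = c("P1", "P0")),
               "no evidence")
})
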