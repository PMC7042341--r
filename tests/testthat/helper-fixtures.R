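# fixture builders and independent brute-force oracles shared across tests

quant_entry <- function(accession = "X1", ratio = 3, capped = FALSE,
                        mwcal = 40, mwexp_lo = 35, mwexp_hi = 45,
                        orientation = "forward", gene = "GX",
                        n_unique_peptides = 1L) {
  tibble::tibble(accession = accession, gene = gene,
                 n_unique_peptides = n_unique_peptides, ratio = ratio,
                 capped = capped, mwcal = mwcal, mwexp_lo = mwexp_lo,
                 mwexp_hi = mwexp_hi, orientation = orientation)
}

random_quant_table <- function(n, orientation = "forward") {
  tibble::tibble(
    accession = sprintf("RQ%03d", seq_len(n)),
    gene = sprintf("G%03d", seq_len(n)),
    n_unique_peptides = sample(1:6, n, replace = TRUE),
    ratio = round(exp(rnorm(n, 0, 1)), 4),
    capped = FALSE,
    mwcal = round(runif(n, 10, 200), 3),
    mwexp_lo = 15, mwexp_hi = 20,
    orientation = orientation)
}

table1_path <- function(block) {
  system.file("extdata", paste0("table1_", block, ".tsv"),
              package = "neofrag")
}

write_fasta_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# residue-set union oracle for region extraction: expand each evidence
# peptide by the flank, clip, and take the union of residue indices
region_union_oracle <- function(starts, ends, flank, L) {
  res <- sort(unique(unlist(mapply(function(s, e) {
    seq(max(s - flank, 1), min(e + flank, L))
  }, starts, ends, SIMPLIFY = FALSE))))
  # contiguous runs of the residue set
  brk <- c(0, which(diff(res) > 1), length(res))
  data.frame(start = res[brk[-length(brk)] + 1], end = res[brk[-1]])
}

# closed-form tile count for a region of R residues
tile_count_oracle <- function(R, len = 20, step = 8) {
  if (R < len) return(1L)
  rem <- R - len
  if (rem %% step == 0) rem %/% step + 1L else rem %/% step + 2L
}

# brute-force cover-counting oracle for deconvolution ambiguity: count
# candidate subsets whose pool union equals the positive set
count_covering_subsets <- function(cand_pairs, positives) {
  k <- length(cand_pairs)
  n_cover <- 0L
  for (mask in 0:(2^k - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    u <- as.integer(sort(unique(unlist(cand_pairs[sel]))))
    if (identical(u, as.integer(sort(unique(positives))))) {
      n_cover <- n_cover + 1L
    }
  }
  n_cover
}
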