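#' Read a protein FASTA file
#'
#' Headers are parsed as `>accession [gene]`; anything after the second token
#' is ignored. Sequences are uppercased and validated against the 20-letter
#' amino-acid alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `gene` (may be `""`),
#'   `sequence`, in file order.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0) {
    return(tibble::tibble(accession = character(), gene = character(),
                          sequence = character()))
  }
  # read as raw strings: residue validation against the 20-letter alphabet
  # is done here rather than by the AA-alphabet reader, which silently drops
  # codes it does not know
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  heads <- names(set)
  toks <- strsplit(trimws(heads), "\\s+")
  accession <- vapply(toks, function(x) x[1] %||% "", "")
  gene <- vapply(toks, function(x) if (length(x) >= 2) x[2] else "", "")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
  if (any(bad)) {
    abort(paste0("illegal residue in record(s): ",
                 paste(accession[bad], collapse = ", ")))
  }
  if (any(accession == "") || anyDuplicated(accession)) {
    abort("FASTA headers must carry unique, non-empty accessions")
  }
  if (any(nchar(seqs) == 0)) abort("empty sequence in FASTA")
  tibble::tibble(accession = accession, gene = gene, sequence = unname(seqs))
}

#' Write protein (or peptide tile) sequences as FASTA
#'
#' @param x Tibble with `accession` (or `tile_id`) and `sequence` columns;
#'   an optional `gene` column is appended to the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(x, path) {
  id <- if ("accession" %in% names(x)) x$accession else x$tile_id
  hdr <- if ("gene" %in% names(x) && any(nzchar(x$gene))) {
    trimws(paste(id, x$gene))
  } else id
  set <- Biostrings::AAStringSet(x$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Strip thousands separators ("51,854" -> 51854) and parse as numeric;
# row-indexed error on failure.
parse_numeric_col <- function(x, col) {
  v <- suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
  bad <- which(is.na(v) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    abort(paste0("non-numeric value in column '", col, "' at row ",
                 bad[1], ": '", x[bad[1]], "'"))
  }
  v
}

quant_cols <- c("accession", "gene", "peptides", "ratio", "mwcal_da",
                "mwexp_lo_kda", "mwexp_hi_kda")

#' Read a SILAC quantitation table
#'
#' Expects a TSV with header columns `accession`, `gene`, `peptides`,
#' `ratio`, `mwcal_da`, `mwexp_lo_kda`, `mwexp_hi_kda`. Thousands separators
#' in numeric fields ("51,854") are accepted. The theoretical molecular
#' weight is converted from Da to kDa on read; ratios equal to or above
#' `ratio_cap` are flagged as one-channel (capped) detections.
#'
#' @param path TSV path.
#' @param orientation `"forward"` (apoptotic cells in the heavy channel) or
#'   `"reverse"` (label swap); stamped on every entry.
#' @param ratio_cap Cap value marking one-channel detections (default 100).
#' @return Tibble of quantitation entries: `accession`, `gene`,
#'   `n_unique_peptides`, `ratio` (apoptotic/live), `capped`, `mwcal` (kDa),
#'   `mwexp_lo`, `mwexp_hi` (kDa), `orientation`.
#' @export
read_quant_table <- function(path, orientation = c("forward", "reverse"),
                             ratio_cap = 100) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(quant_cols, names(raw))
  if (length(missing)) {
    abort(paste0("quant table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(accession = character(), gene = character(),
                          n_unique_peptides = integer(), ratio = double(),
                          capped = logical(), mwcal = double(),
                          mwexp_lo = double(), mwexp_hi = double(),
                          orientation = character()))
  }
  out <- tibble::tibble(
    accession = raw$accession,
    gene = raw$gene %||% "",
    n_unique_peptides = as.integer(parse_numeric_col(raw$peptides, "peptides")),
    ratio = parse_numeric_col(raw$ratio, "ratio"),
    mwcal = parse_numeric_col(raw$mwcal_da, "mwcal_da") / 1000,
    mwexp_lo = parse_numeric_col(raw$mwexp_lo_kda, "mwexp_lo_kda"),
    mwexp_hi = parse_numeric_col(raw$mwexp_hi_kda, "mwexp_hi_kda"),
    orientation = orientation)
  out$capped <- out$ratio >= ratio_cap
  if (any(out$ratio <= 0)) abort("ratios must be > 0")
  if (any(out$mwexp_lo >= out$mwexp_hi)) abort("need mwexp_lo < mwexp_hi")
  if (any(out$n_unique_peptides < 1)) abort("peptide counts must be >= 1")
  out[, c("accession", "gene", "n_unique_peptides", "ratio", "capped",
          "mwcal", "mwexp_lo", "mwexp_hi", "orientation")]
}

#' Write a SILAC quantitation table
#'
#' Inverse of [read_quant_table()]: writes the on-disk schema (MWcal back in
#' Da), rows sorted by accession for deterministic output.
#'
#' @param x Quantitation tibble as returned by [read_quant_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  out <- tibble::tibble(
    accession = x$accession, gene = x$gene,
    peptides = x$n_unique_peptides, ratio = x$ratio,
    mwcal_da = x$mwcal * 1000,
    mwexp_lo_kda = x$mwexp_lo, mwexp_hi_kda = x$mwexp_hi)
  out <- dplyr::arrange(out, .data$accession)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a centroided peak list
#'
#' @param path TSV with columns `mz` (Da, singly charged assumed) and
#'   `intensity`.
#' @return Tibble with numeric `mz`, `intensity`.
#' @export
read_peak_list <- function(path) {
  x <- readr::read_tsv(path, col_types = "dd", progress = FALSE)
  if (!all(c("mz", "intensity") %in% names(x))) {
    abort("peak list needs columns mz, intensity")
  }
  if (any(x$mz <= 0)) abort("mz must be > 0")
  if (any(x$intensity < 0)) abort("intensity must be >= 0")
  x
}

#' Write / read a peptide tile table
#'
#' Tiles are written sorted by (accession, start) with columns `tile_id`,
#' `accession`, `start`, `end`, `sequence`, `short` — 1-based inclusive
#' coordinates.
#'
#' @param x Tile tibble from [design_peptide_library()] or [tile_region()].
#' @param path TSV path.
#' @return `write_tiles()`: `path` invisibly; `read_tiles()`: the tile tibble.
#' @export
write_tiles <- function(x, path) {
  out <- dplyr::arrange(x, .data$accession, .data$start)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_tiles
#' @export
read_tiles <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    tile_id = "c", accession = "c", start = "i", end = "i",
    sequence = "c", short = "l"), progress = FALSE)
}

#' Write / read a pool design as JSON
#'
#' The JSON layout is `{n_pools, pools: {<pool>: [tile_ids]},
#' pairs: {<tile_id>: [i, j]}}`.
#'
#' @param design A pool design from [design_pools()].
#' @param path JSON path.
#' @return `write_pool_design()`: `path` invisibly; `read_pool_design()`: a
#'   pool design object.
#' @export
write_pool_design <- function(design, path) {
  pools <- lapply(seq_len(design$n_pools), function(p) {
    design$assignment$tile_id[design$assignment$pool1 == p |
                              design$assignment$pool2 == p]
  })
  names(pools) <- as.character(seq_len(design$n_pools))
  pairs <- setNames(
    lapply(seq_len(nrow(design$assignment)),
           function(i) c(design$assignment$pool1[i], design$assignment$pool2[i])),
    design$assignment$tile_id)
  jsonlite::write_json(list(n_pools = design$n_pools, pools = pools,
                            pairs = pairs),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pool_design
#' @export
read_pool_design <- function(path) {
  x <- jsonlite::read_json(path)
  assignment <- tibble::tibble(
    tile_id = names(x$pairs),
    pool1 = vapply(x$pairs, function(p) as.integer(p[[1]]), 1L,
                   USE.NAMES = FALSE),
    pool2 = vapply(x$pairs, function(p) as.integer(p[[2]]), 1L,
                   USE.NAMES = FALSE))
  new_pool_design(as.integer(x$n_pools), assignment)
}

#' Read a per-pool T-cell response table
#'
#' @param path TSV with columns `patient_id`, `timepoint` (T0/T1/T2/HD/NAIVE),
#'   `subset` (CD4/CD8), `cytokine` (IFNG/TNFA/DUAL), `pool`, `pct_stim`,
#'   `pct_ns`, and optionally `pct_pd1`.
#' @return Tibble with those columns; percentages validated to `[0, 100]`.
#' @export
read_response_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = "c", timepoint = "c", subset = "c", cytokine = "c",
    pool = "i", .default = "d"), progress = FALSE)
  need <- c("patient_id", "timepoint", "subset", "cytokine", "pool",
            "pct_stim", "pct_ns")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0("response table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  pct <- c(x$pct_stim, x$pct_ns)
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    abort("percentages must lie in [0, 100]")
  }
  x
}

#' Read a survival record table
#'
#' @param path TSV with columns `patient_id`, `months` (> 0), `event`
#'   (0/1 or logical), and either `group` (HIGH/LOW) or `value` (a response
#'   level to be median-split later).
#' @return Tibble of survival records.
#' @export
read_survival_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("patient_id", "months", "event")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0("survival table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    patient_id = x$patient_id,
    months = parse_numeric_col(x$months, "months"),
    event = parse_numeric_col(x$event, "event") > 0)
  if ("group" %in% names(x)) out$group <- x$group
  if ("value" %in% names(x)) out$value <- parse_numeric_col(x$value, "value")
  if (any(out$months <= 0)) abort("months must be > 0")
  out
}

#' Write a classification report as JSON
#'
#' One object per accession with the label, ratio and molecular-weight fields
#' and the rule that fired.
#'
#' @param calls Classification tibble from [classify_quant()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_classification_report <- function(calls, path) {
  calls <- dplyr::arrange(calls, .data$accession)
  jsonlite::write_json(calls, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
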