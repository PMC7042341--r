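#' Select target regions around MS-identified peptides
#'
#' Each evidence peptide is expanded by `flank` residues on both sides,
#' clipped to the protein bounds; overlapping or adjacent expanded intervals
#' are merged so no residue is synthesised twice.
#'
#' @param protein One-row tibble with `accession` and `sequence`.
#' @param evidence Tibble of MS-identified peptides with `accession`,
#'   `start`, `end` (1-based inclusive, within the protein, length >= 6).
#' @param flank Residues added on each side (default 20).
#' @return Tibble of disjoint regions: `accession`, `start`, `end`.
#' @export
extract_target_regions <- function(protein, evidence, flank = 20) {
  stopifnot(nrow(protein) == 1)
  L <- nchar(protein$sequence)
  ev <- evidence[evidence$accession == protein$accession, , drop = FALSE]
  if (nrow(ev) < nrow(evidence)) abort("evidence not all on the given protein")
  if (any(ev$start < 1 | ev$end > L | ev$start > ev$end)) {
    abort("evidence peptide outside protein bounds")
  }
  if (any(ev$end - ev$start + 1 < 6)) {
    abort("evidence peptides must be at least 6 residues")
  }
  lo <- pmax(ev$start - flank, 1L)
  hi <- pmin(ev$end + flank, L)
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]
  # merge overlapping or adjacent intervals
  ms <- me <- integer(0)
  for (k in seq_along(lo)) {
    if (length(ms) && lo[k] <= me[length(me)] + 1L) {
      me[length(me)] <- max(me[length(me)], hi[k])
    } else {
      ms <- c(ms, lo[k]); me <- c(me, hi[k])
    }
  }
  tibble::tibble(accession = protein$accession,
                 start = as.integer(ms), end = as.integer(me))
}

#' Tile a target region into overlapping peptides
#'
#' Tiles of `length` residues start at `region$start` and step by
#' `length - overlap`. If the last stepped tile falls short of the region
#' end, one extra right-anchored tile ending exactly at the region end is
#' appended, so every tile stays full length. Regions shorter than `length`
#' yield a single whole-region tile flagged `short = TRUE`.
#'
#' @param region One-row tibble with `accession`, `start`, `end`.
#' @param protein One-row tibble with the parent `sequence`.
#' @param length Tile length in residues (default 20).
#' @param overlap Overlap between consecutive stepped tiles (default 12);
#'   must be < `length`.
#' @return Tile tibble: `tile_id` (`accession_start`), `accession`, `start`,
#'   `end`, `sequence`, `short`.
#' @export
tile_region <- function(region, protein, length = 20, overlap = 12) {
  stopifnot(nrow(region) == 1, nrow(protein) == 1)
  if (overlap >= length || overlap < 0) abort("need 0 <= overlap < length")
  seq_str <- protein$sequence
  R <- region$end - region$start + 1L
  if (R < length) {
    starts <- region$start
    ends <- region$end
    short <- TRUE
  } else {
    step <- length - overlap
    starts <- seq(region$start, region$end - length + 1L, by = step)
    last_anchor <- region$end - length + 1L
    if (starts[base::length(starts)] < last_anchor) {
      starts <- c(starts, last_anchor)
    }
    ends <- starts + length - 1L
    short <- FALSE
  }
  tibble::tibble(
    tile_id = paste0(region$accession, "_", starts),
    accession = region$accession,
    start = as.integer(starts), end = as.integer(ends),
    sequence = substring(seq_str, starts, ends),
    short = short)
}

#' Design the overlapping-peptide library for fragment calls
#'
#' Builds target regions and tiles for every accession called FRAGMENTED
#' (or for an explicit accession list), producing a deterministic library
#' sorted by (accession, start).
#'
#' @param proteins Protein tibble from [read_protein_fasta()].
#' @param calls Classified quantitation table from [classify_quant()], or
#'   `NULL` if `accessions` is given.
#' @param evidence Evidence-peptide tibble (`accession`, `start`, `end`).
#' @param config An [nf_config()] list supplying flank, tile length, overlap.
#' @param accessions Optional explicit accession selection overriding the
#'   FRAGMENTED calls.
#' @return Tile tibble as in [tile_region()].
#' @export
design_peptide_library <- function(proteins, calls = NULL, evidence,
                                   config = nf_config(), accessions = NULL) {
  if (is.null(accessions)) {
    if (is.null(calls)) abort("provide either calls or accessions")
    accessions <- unique(calls$accession[calls$label == "FRAGMENTED"])
  }
  accessions <- sort(unique(accessions))
  empty <- tibble::tibble(tile_id = character(), accession = character(),
                          start = integer(), end = integer(),
                          sequence = character(), short = logical())
  if (!base::length(accessions)) return(empty)
  missing_prot <- setdiff(accessions, proteins$accession)
  if (base::length(missing_prot)) {
    abort(paste0("no sequence for accession(s): ",
                 paste(missing_prot, collapse = ", ")))
  }
  tiles <- purrr::map(accessions, function(acc) {
    prot <- proteins[proteins$accession == acc, , drop = FALSE]
    ev <- evidence[evidence$accession == acc, , drop = FALSE]
    if (!nrow(ev)) abort(paste0("no evidence peptides for ", acc))
    regions <- extract_target_regions(prot, ev, flank = config$flank_residues)
    purrr::map(seq_len(nrow(regions)), function(i) {
      tile_region(regions[i, ], prot,
                  length = config$tile_length, overlap = config$tile_overlap)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  nf_log("design_peptide_library: %d proteins -> %d tiles (length %d, overlap %d, flank %d)",
         base::length(accessions), nrow(tiles), config$tile_length,
         config$tile_overlap, config$flank_residues)
  dplyr::arrange(tiles, .data$accession, .data$start)
}
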