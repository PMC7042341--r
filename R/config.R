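#' Default gel-section boundaries
#'
#' The gel lane is cut into 16 sections spanning 5-250 kDa. Only the section
#' count and the overall range are fixed by the protocol; the individual cut
#' positions are not published, so the default places 17 log-spaced
#' breakpoints between 5 and 250 kDa, reflecting the roughly logarithmic
#' migration of molecular weight in SDS-PAGE. Override via
#' [nf_config()]`$gel_section_boundaries` if the true cut positions are known.
#'
#' @param n_sections Number of gel sections (default 16).
#' @param range_kda Length-2 numeric, total mass range covered in kDa.
#' @return Numeric vector of `n_sections + 1` strictly increasing breakpoints.
#' @export
#' @examples
#' gel_boundaries()
gel_boundaries <- function(n_sections = 16, range_kda = c(5, 250)) {
  stopifnot(n_sections >= 1, length(range_kda) == 2, range_kda[1] > 0,
            range_kda[2] > range_kda[1])
  exp(seq(log(range_kda[1]), log(range_kda[2]), length.out = n_sections + 1))
}

#' Read a pipeline configuration file
#'
#' Configurations are stored as a single structured text (YAML) file whose
#' keys mirror the arguments of [nf_config()]; keys given in `overrides`
#' (e.g. from a caller's command line) take precedence, and unset keys fall
#' back to the documented defaults, so runs are fully reproducible from the
#' file plus the overrides.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return An [nf_config()] list.
#' @export
read_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals <- utils::modifyList(vals, overrides)
  unknown <- setdiff(names(vals), names(formals(nf_config)))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(nf_config, vals)
}

# stage logging: row counts, filter counts and active thresholds, enabled by
# options(neofrag.verbose = TRUE)
nf_log <- function(...) {
  if (isTRUE(getOption("neofrag.verbose", FALSE))) {
    rlang::inform(paste0("[neofrag] ", sprintf(...)))
  }
  invisible(NULL)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#'
#' @param ratio_up_threshold Fold-change above which a protein is called
#'   upregulated (default 2: ">2-fold increase").
#' @param ratio_down_threshold Fold-change below which a protein is called
#'   downregulated (default 0.5, the symmetric 2-fold window).
#' @param ratio_cap Ratio value used for one-channel detections where the
#'   live-channel partner is undetected (default 100, the value the
#'   quantitation software prints for such rows).
#' @param gel_section_boundaries Ordered kDa breakpoints, see
#'   [gel_boundaries()].
#' @param flank_residues Residues added on each side of an MS-identified
#'   peptide when selecting the target region (default 20).
#' @param tile_length Designed peptide length in residues (default 20).
#' @param tile_overlap Overlap between consecutive tiles (default 12).
#' @param n_pools Number of pools in the two-of-N matrix (default 12).
#' @param pair_match_tolerance Mass tolerance in Da when matching SILAC peak
#'   pairs (default 0.05).
#' @param responder_floor Net response (percentage points) at or above which
#'   a patient x pool measurement counts as a responder (default 0.01).
#' @param rng_seed Integer seed recorded with the run.
#' @return A named list of class `nf_config`.
#' @export
#' @examples
#' cfg <- nf_config()
#' cfg$tile_length
nf_config <- function(ratio_up_threshold = 2,
                      ratio_down_threshold = 0.5,
                      ratio_cap = 100,
                      gel_section_boundaries = gel_boundaries(),
                      flank_residues = 20,
                      tile_length = 20,
                      tile_overlap = 12,
                      n_pools = 12,
                      pair_match_tolerance = 0.05,
                      responder_floor = 0.01,
                      rng_seed = 1L) {
  if (!(ratio_down_threshold > 0 && ratio_down_threshold < 1 &&
        ratio_up_threshold > 1)) {
    abort("need 0 < ratio_down_threshold < 1 < ratio_up_threshold")
  }
  if (tile_overlap >= tile_length) abort("tile_overlap must be < tile_length")
  if (any(diff(gel_section_boundaries) <= 0)) {
    abort("gel_section_boundaries must be strictly increasing")
  }
  if (n_pools < 3) abort("n_pools must be >= 3")
  if (pair_match_tolerance <= 0) abort("pair_match_tolerance must be > 0")
  structure(
    list(ratio_up_threshold = ratio_up_threshold,
         ratio_down_threshold = ratio_down_threshold,
         ratio_cap = ratio_cap,
         gel_section_boundaries = gel_section_boundaries,
         flank_residues = flank_residues,
         tile_length = tile_length,
         tile_overlap = tile_overlap,
         n_pools = n_pools,
         pair_match_tolerance = pair_match_tolerance,
         responder_floor = responder_floor,
         rng_seed = as.integer(rng_seed)),
    class = "nf_config")
}
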