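# Isotopic mass differences (Da) underlying the heavy labels:
# 13C6-Lys adds six 13C-12C shifts; 13C6-15N4-Arg adds six 13C-12C plus
# four 15N-14N shifts.
DELTA_13C <- 1.003355
DELTA_15N <- 0.997035

# nominal shift classes printed by the acquisition software, in Da
silac_shift_classes <- function() {
  c(K1 = 6 * DELTA_13C,
    R1 = 6 * DELTA_13C + 4 * DELTA_15N,
    K2 = 12 * DELTA_13C,
    K1R1 = 12 * DELTA_13C + 4 * DELTA_15N,
    R2 = 2 * (6 * DELTA_13C + 4 * DELTA_15N))
}

#' Heavy-minus-light mass shift of a labeled tryptic peptide
#'
#' With 13C6-lysine and 13C6-15N4-arginine labels the shift is additive in
#' the residue counts: `n_lys * 6 * (13C-12C) + n_arg * (6 * (13C-12C) +
#' 4 * (15N-14N))`. The five shift classes observed for tryptic peptides
#' with at most one missed cleavage round to 6.02, 10.01, 12.04, 16.03 and
#' 20.02 Da.
#'
#' @param n_lys,n_arg Non-negative counts of labeled lysines / arginines in
#'   the peptide; they cannot both be zero (an unlabeled peptide has no
#'   SILAC pair).
#' @return Mass shift in Da.
#' @export
#' @examples
#' round(label_mass_shift(1, 0), 2)  # 6.02
#' round(label_mass_shift(0, 1), 2)  # 10.01
label_mass_shift <- function(n_lys, n_arg) {
  stopifnot(length(n_lys) == length(n_arg))
  if (any(n_lys < 0 | n_arg < 0)) abort("residue counts must be >= 0")
  if (any(n_lys == 0 & n_arg == 0)) {
    abort("peptide with no labeled Lys or Arg has no SILAC pair")
  }
  n_lys * 6 * DELTA_13C + n_arg * (6 * DELTA_13C + 4 * DELTA_15N)
}

#' Match heavy/light SILAC peak pairs in a centroided peak list
#'
#' Peaks are treated as singly-charged centroids. Every ordered pair of
#' peaks whose mass difference lies within `tolerance` of one of the five
#' nominal shifts (6.02, 10.01, 12.04, 16.03, 20.02 Da) is a candidate;
#' candidates are accepted greedily by smallest absolute deviation from the
#' nominal shift, ties broken by lower light m/z, and each peak is used in
#' at most one pair.
#'
#' @param peaks Tibble with `mz`, `intensity` (see [read_peak_list()]).
#' @param tolerance Mass tolerance in Da (> 0).
#' @return Tibble of pairs: `light_mz`, `heavy_mz`, `shift_class`,
#'   `light_intensity`, `heavy_intensity`, `delta` (observed difference).
#' @export
match_silac_pairs <- function(peaks, tolerance = 0.05) {
  if (tolerance <= 0) abort("tolerance must be > 0")
  empty <- tibble::tibble(light_mz = double(), heavy_mz = double(),
                          shift_class = character(),
                          light_intensity = double(),
                          heavy_intensity = double(), delta = double())
  n <- nrow(peaks)
  if (n < 2) return(empty)
  ord <- order(peaks$mz, peaks$intensity)
  mz <- peaks$mz[ord]; int <- peaks$intensity[ord]
  shifts <- silac_shift_classes()
  cand <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d <- mz[j] - mz[i]
      if (d > max(shifts) + tolerance) break
      dev <- abs(d - shifts)
      k <- unname(which.min(dev))
      if (dev[k] <= tolerance) {
        cand[[length(cand) + 1]] <-
          c(i = i, j = j, dev = unname(dev[k]), class = k)
      }
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, "dev"], mz[cand[, "i"]]), , drop = FALSE]
  used <- rep(FALSE, n)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (!used[i] && !used[j]) {
      keep[r] <- TRUE
      used[c(i, j)] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- tibble::tibble(
    light_mz = mz[cand[, "i"]],
    heavy_mz = mz[cand[, "j"]],
    shift_class = names(shifts)[cand[, "class"]],
    light_intensity = int[cand[, "i"]],
    heavy_intensity = int[cand[, "j"]],
    delta = mz[cand[, "j"]] - mz[cand[, "i"]])
  dplyr::arrange(out, .data$light_mz)
}

#' Apoptotic/live ratio of a SILAC pair
#'
#' In the forward experiment apoptotic cells carry the heavy label, so the
#' ratio is heavy/light; the reverse (label-swap) experiment inverts this.
#' A missing (zero-intensity) live-channel partner yields the cap with
#' `capped = TRUE`, matching how one-channel detections are printed by the
#' quantitation software; computed ratios above the cap are truncated.
#'
#' @param heavy,light Channel intensities (>= 0, not both zero).
#' @param orientation `"forward"` or `"reverse"`.
#' @param cap One-channel / truncation cap (default 100).
#' @return List with `ratio` (apoptotic/live) and `capped` (logical).
#' @export
pair_ratio <- function(heavy, light, orientation = c("forward", "reverse"),
                       cap = 100) {
  orientation <- match.arg(orientation)
  if (heavy < 0 || light < 0) abort("intensities must be >= 0")
  if (heavy == 0 && light == 0) abort("both channel intensities are zero")
  apo <- if (orientation == "forward") heavy else light
  live <- if (orientation == "forward") light else heavy
  if (live == 0) return(list(ratio = cap, capped = TRUE))
  r <- apo / live
  if (r > cap) list(ratio = cap, capped = TRUE) else list(ratio = r, capped = FALSE)
}

#' Assign a mass to its gel section
#'
#' Sections are half-open `[lo, hi)` kDa intervals indexed from 1 at the
#' lowest band. Masses below the first boundary fall into the lowest band;
#' masses at or above the last boundary are out of range.
#'
#' @param mass_kda Mass in kDa.
#' @param boundaries Strictly increasing breakpoints (length = sections + 1),
#'   see [gel_boundaries()].
#' @return List with `section` (index), `mwexp_lo`, `mwexp_hi` (kDa).
#' @export
assign_gel_section <- function(mass_kda, boundaries = gel_boundaries()) {
  if (any(diff(boundaries) <= 0)) abort("boundaries must be strictly increasing")
  n <- length(boundaries) - 1
  if (mass_kda >= boundaries[n + 1]) {
    abort(paste0("mass ", mass_kda, " kDa is above the top boundary (",
                 boundaries[n + 1], " kDa)"))
  }
  s <- if (mass_kda < boundaries[1]) 1L else {
    max(which(boundaries <= mass_kda))
  }
  list(section = as.integer(s),
       mwexp_lo = boundaries[s], mwexp_hi = boundaries[s + 1])
}

#' Classify one quantitation entry
#'
#' A protein is FRAGMENTED when the apparent (gel-derived) molecular weight
#' range lies strictly below the theoretical weight of the intact protein
#' (`mwexp_hi < mwcal`) *and* the entry is enriched in the apoptotic channel
#' (ratio > 1, or a capped one-channel detection). This molecular-weight
#' rule takes precedence over the abundance thresholds. Otherwise the call
#' is UPREGULATED for ratio above `ratio_up_threshold`, DOWNREGULATED below
#' `ratio_down_threshold`, else UNCHANGED.
#'
#' @param entry One-row quantitation tibble (see [read_quant_table()]).
#' @param config An [nf_config()] list.
#' @return List with `accession`, `label`, `rule`, `orientation`.
#' @export
classify_protein <- function(entry, config = nf_config()) {
  stopifnot(nrow(entry) == 1)
  enriched <- entry$ratio > 1 || isTRUE(entry$capped)
  if (entry$mwexp_hi < entry$mwcal && enriched) {
    label <- "FRAGMENTED"
    rule <- "mwexp_below_mwcal"
  } else if (entry$ratio > config$ratio_up_threshold) {
    label <- "UPREGULATED"; rule <- "ratio_above_up_threshold"
  } else if (entry$ratio < config$ratio_down_threshold) {
    label <- "DOWNREGULATED"; rule <- "ratio_below_down_threshold"
  } else {
    label <- "UNCHANGED"; rule <- "ratio_within_window"
  }
  list(accession = entry$accession, label = label, rule = rule,
       orientation = entry$orientation)
}

#' Classify a whole quantitation table
#'
#' Vectorised [classify_protein()] over a quantitation table; one label per
#' (accession, orientation).
#'
#' @inheritParams classify_protein
#' @param quant Quantitation tibble.
#' @return The input with `label` and `rule` columns appended.
#' @export
classify_quant <- function(quant, config = nf_config()) {
  if (anyDuplicated(quant[, c("accession", "orientation")])) {
    abort("duplicate accession within one orientation")
  }
  enriched <- quant$ratio > 1 | quant$capped
  frag <- quant$mwexp_hi < quant$mwcal & enriched
  label <- dplyr::case_when(
    frag ~ "FRAGMENTED",
    quant$ratio > config$ratio_up_threshold ~ "UPREGULATED",
    quant$ratio < config$ratio_down_threshold ~ "DOWNREGULATED",
    TRUE ~ "UNCHANGED")
  rule <- dplyr::case_when(
    frag ~ "mwexp_below_mwcal",
    quant$ratio > config$ratio_up_threshold ~ "ratio_above_up_threshold",
    quant$ratio < config$ratio_down_threshold ~ "ratio_below_down_threshold",
    TRUE ~ "ratio_within_window")
  nf_log("classify_quant: %d entries, thresholds up>%.2f down<%.2f; %d fragmented, %d up, %d down, %d unchanged",
         nrow(quant), config$ratio_up_threshold, config$ratio_down_threshold,
         sum(label == "FRAGMENTED"), sum(label == "UPREGULATED"),
         sum(label == "DOWNREGULATED"), sum(label == "UNCHANGED"))
  dplyr::mutate(quant, label = label, rule = rule)
}

#' Fragment calls concordant between label-swap replicates
#'
#' @param forward_calls,reverse_calls Classified tables from
#'   [classify_quant()] for the forward and reverse experiments.
#' @return Sorted character vector of accessions labeled FRAGMENTED in both
#'   orientations (matching is by accession, not gene name).
#' @export
replicate_concordance <- function(forward_calls, reverse_calls) {
  for (x in list(forward_calls, reverse_calls)) {
    if (anyDuplicated(x$accession)) {
      abort("duplicate accession within one orientation")
    }
  }
  f <- forward_calls$accession[forward_calls$label == "FRAGMENTED"]
  r <- reverse_calls$accession[reverse_calls$label == "FRAGMENTED"]
  sort(intersect(f, r))
}
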