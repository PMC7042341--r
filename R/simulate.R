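# average residue masses (Da), standard amino-acid composition table
AVG_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

#' Average molecular mass of a peptide or protein
#'
#' Sum of standard average residue masses plus one water.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return Mass in Da (vectorised).
#' @export
#' @examples
#' peptide_average_mass("GGG")  # 189.17 Da
peptide_average_mass <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- strsplit(s, "")[[1]]
    bad <- setdiff(aa, names(AVG_RESIDUE_MASS))
    if (length(bad)) abort(paste0("unknown residue(s): ",
                                  paste(bad, collapse = ", ")))
    sum(AVG_RESIDUE_MASS[aa]) + WATER_MASS
  }, 1, USE.NAMES = FALSE)
}

#' Simulation configuration
#'
#' Parameters of the synthetic proteome and patient cohort the generator
#' emulates: a tumour-cell proteome in which a fraction of proteins yields
#' low-molecular-weight caspase-type fragments enriched in the apoptotic
#' channel with lognormal ratio noise and a label-swap replicate, plus a
#' cohort sampled before chemotherapy (T0), after chemotherapy (T1) and
#' after subsequent anti-PD-1 therapy (T2), with pool-level cytokine
#' responses, PD-1 kinetics and survival coupled to the CD8 response.
#'
#' @param rng_seed Integer master seed; per-stage streams are derived from
#'   it so stages can be regenerated in isolation.
#' @param n_proteins Proteome size (default 200).
#' @param protein_length_range Residue-length range, uniform (default
#'   100-900).
#' @param fraction_fragmented,fraction_up,fraction_down Class fractions
#'   (defaults 0.08, 0.3, 0.5; the remainder is unchanged).
#' @param ratio_noise_sigma Lognormal sigma of multiplicative ratio noise,
#'   applied independently to forward and reverse experiments (default
#'   0.25).
#' @param singleton_probability Probability that a fragmented protein's
#'   live-channel partner is undetected, giving a capped one-channel ratio
#'   (default 0.3).
#' @param cohort Named list: `n_patients` (14; 12 continue to T2, mirroring
#'   the treated cohort), `stage_means` (specific-response effect in
#'   percentage points per timepoint; T0 0.02, T1 0.15, T2 0.40),
#'   `pd1_means` (percent PD-1 within specific cells; 20, 45, 18),
#'   `response_noise_sigma` (lognormal sigma on the effect, 0.25),
#'   `ns_mean`/`ns_sigma` (unstimulated background, 0.02/0.005 percentage
#'   points), `pd1_sigma` (5), `hazard_baseline` (1/30 per month),
#'   `hazard_ratio` (3, protective for above-median CD8 IFN-gamma at T2),
#'   `censoring_rate` (0.2).
#' @return A named list of class `nf_sim_config`.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_proteins = 200,
                       protein_length_range = c(100, 900),
                       fraction_fragmented = 0.08,
                       fraction_up = 0.3,
                       fraction_down = 0.5,
                       ratio_noise_sigma = 0.25,
                       singleton_probability = 0.3,
                       cohort = list()) {
  fr <- c(fraction_fragmented, fraction_up, fraction_down)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
    abort("class fractions must lie in [0,1] and sum to at most 1")
  }
  if (ratio_noise_sigma < 0) abort("ratio_noise_sigma must be >= 0")
  co <- utils::modifyList(
    list(n_patients = 14L,
         n_patients_t2 = 12L,
         stage_means = c(T0 = 0.02, T1 = 0.15, T2 = 0.40),
         pd1_means = c(T0 = 20, T1 = 45, T2 = 18),
         response_noise_sigma = 0.25,
         ns_mean = 0.02, ns_sigma = 0.005,
         pd1_sigma = 5,
         hazard_baseline = 1 / 30,
         hazard_ratio = 3,
         censoring_rate = 0.2),
    cohort)
  structure(
    list(rng_seed = as.integer(rng_seed),
         n_proteins = as.integer(n_proteins),
         protein_length_range = protein_length_range,
         fraction_fragmented = fraction_fragmented,
         fraction_up = fraction_up,
         fraction_down = fraction_down,
         ratio_noise_sigma = ratio_noise_sigma,
         singleton_probability = singleton_probability,
         cohort = co),
    class = "nf_sim_config")
}

# derive a reproducible sub-seed for a named stage from the master seed
stage_seed <- function(seed, stage) {
  offsets <- c(proteome = 11, fragmentation = 23, silac = 37,
               cohort = 53, survival = 71)
  as.integer((as.numeric(seed) * 101 + offsets[[stage]]) %% 2147483647)
}

#' Generate a synthetic proteome
#'
#' Residue composition is uniform over the 20 letters; lengths are uniform
#' over the configured range. Fully determined by the master seed.
#'
#' @param config An [sim_config()] list.
#' @return Protein tibble (`accession`, `gene`, `sequence`) with synthetic
#'   accessions `SYN0001`, ...
#' @export
simulate_proteome <- function(config = sim_config()) {
  n <- config$n_proteins
  if (n == 0) {
    return(tibble::tibble(accession = character(), gene = character(),
                          sequence = character()))
  }
  rng <- config$protein_length_range
  withr::with_seed(stage_seed(config$rng_seed, "proteome"), {
    lens <- if (rng[1] == rng[2]) rep(rng[1], n) else {
      sample(seq(rng[1], rng[2]), n, replace = TRUE)
    }
    seqs <- vapply(lens, function(L) {
      paste(sample(names(AVG_RESIDUE_MASS), L, replace = TRUE),
            collapse = "")
    }, "")
  })
  tibble::tibble(
    accession = sprintf("SYN%04d", seq_len(n)),
    gene = sprintf("G%04d", seq_len(n)),
    sequence = seqs)
}

# choose a caspase-type cleavage site for one protein: cut C-terminal to a
# randomly chosen aspartate (uniform site when the protein has no D); the
# fragment is the shorter side and must fall at least one gel section below
# the intact protein; resample a limited number of times, then take the
# smallest-fragment site.
choose_fragment <- function(sequence, boundaries, max_tries = 50) {
  L <- nchar(sequence)
  intact_kda <- peptide_average_mass(sequence) / 1000
  intact_sec <- assign_gel_section(intact_kda, boundaries)$section
  d_pos <- which(strsplit(sequence, "")[[1]] == "D")
  d_pos <- d_pos[d_pos < L]  # a C-terminal D leaves nothing to cleave off
  sites <- if (length(d_pos)) d_pos else seq_len(L - 1)
  frag_at <- function(cut) {
    if (cut <= L - cut) c(1L, cut) else c(cut + 1L, L)
  }
  pick <- NULL
  for (i in seq_len(max_tries)) {
    cut <- if (length(sites) == 1) sites else sample(sites, 1)
    iv <- frag_at(cut)
    frag <- substring(sequence, iv[1], iv[2])
    kda <- peptide_average_mass(frag) / 1000
    sec <- assign_gel_section(min(kda, intact_kda), boundaries)$section
    if (sec <= intact_sec - 1L) {
      pick <- list(start = iv[1], end = iv[2], mass_kda = kda,
                   section = sec)
      break
    }
  }
  if (is.null(pick)) {
    # fall back to the site giving the lightest fragment
    cuts <- vapply(sites, function(cut) {
      iv <- frag_at(cut)
      peptide_average_mass(substring(sequence, iv[1], iv[2]))
    }, 1)
    cut <- sites[which.min(cuts)]
    iv <- frag_at(cut)
    kda <- min(cuts) / 1000
    pick <- list(start = iv[1], end = iv[2], mass_kda = kda,
                 section = assign_gel_section(kda, boundaries)$section)
  }
  c(pick, list(intact_kda = intact_kda, intact_section = intact_sec))
}

#' Simulate caspase-type fragmentation truth
#'
#' Assigns each protein a ground-truth class (FRAGMENTED / UPREGULATED /
#' DOWNREGULATED / UNCHANGED, with exact counts from the configured
#' fractions), picks a cleavage site after an aspartate for fragmented
#' proteins (uniform fallback when the protein has no D), computes fragment
#' masses from standard average residue masses, and derives one
#' MS-identified evidence peptide inside each fragment.
#'
#' @param proteins Protein tibble from [simulate_proteome()].
#' @param config An [sim_config()] list.
#' @param boundaries Gel-section breakpoints shared with the classifier.
#' @return List with `truth` (accession, class, true_ratio, capped,
#'   intact_kda, intact_section, frag_start/end, frag_mass_kda,
#'   frag_section) and `evidence` (accession, start, end) for fragmented
#'   proteins.
#' @export
simulate_fragmentation <- function(proteins, config = sim_config(),
                                   boundaries = gel_boundaries()) {
  n <- nrow(proteins)
  n_frag <- round(config$fraction_fragmented * n)
  n_up <- round(config$fraction_up * n)
  n_down <- round(config$fraction_down * n)
  classes <- c(rep("FRAGMENTED", n_frag), rep("UPREGULATED", n_up),
               rep("DOWNREGULATED", n_down),
               rep("UNCHANGED", n - n_frag - n_up - n_down))
  withr::with_seed(stage_seed(config$rng_seed, "fragmentation"), {
    classes <- sample(classes)
    truth <- tibble::tibble(
      accession = proteins$accession, class = classes,
      true_ratio = NA_real_, capped = FALSE,
      intact_kda = peptide_average_mass(proteins$sequence) / 1000,
      intact_section = NA_integer_,
      frag_start = NA_integer_, frag_end = NA_integer_,
      frag_mass_kda = NA_real_, frag_section = NA_integer_)
    truth$intact_section <- vapply(truth$intact_kda, function(m) {
      assign_gel_section(m, boundaries)$section
    }, 1L)
    # true apoptotic/live ratios per class, on a log-uniform scale
    luni <- function(k, lo, hi) exp(runif(k, log(lo), log(hi)))
    for (cl in unique(truth$class)) {
      idx <- which(truth$class == cl)
      truth$true_ratio[idx] <- switch(
        cl,
        UPREGULATED = luni(length(idx), 2.5, 30),
        DOWNREGULATED = 1 / luni(length(idx), 2.5, 30),
        UNCHANGED = exp(rnorm(length(idx), 0, 0.05)),
        FRAGMENTED = luni(length(idx), 2, 30))
    }
    fi <- which(truth$class == "FRAGMENTED")
    truth$capped[fi] <- runif(length(fi)) < config$singleton_probability
    ev <- vector("list", length(fi))
    for (k in seq_along(fi)) {
      i <- fi[k]
      fr <- choose_fragment(proteins$sequence[i], boundaries)
      truth$frag_start[i] <- fr$start
      truth$frag_end[i] <- fr$end
      truth$frag_mass_kda[i] <- fr$mass_kda
      truth$frag_section[i] <- fr$section
      # one MS-identified tryptic-scale peptide inside the fragment;
      # fragments below the 6-residue instrument minimum go unidentified
      flen <- fr$end - fr$start + 1L
      if (flen >= 6L) {
        plen <- min(12L, flen)
        pstart <- if (fr$end - plen + 1L > fr$start) {
          sample(seq(fr$start, fr$end - plen + 1L), 1)
        } else fr$start
        ev[[k]] <- tibble::tibble(accession = proteins$accession[i],
                                  start = pstart, end = pstart + plen - 1L)
      }
    }
  })
  list(truth = truth, evidence = purrr::list_rbind(ev))
}

#' Simulate forward and reverse SILAC quantitation tables
#'
#' True apoptotic/live ratios are multiplied by independent lognormal noise
#' for the forward and the label-swapped reverse experiment; capped
#' (one-channel) detections stay at the cap. The apparent molecular-weight
#' range is the gel section of the fragment for fragmented proteins and of
#' the intact protein otherwise, using the same boundaries as the
#' classifier, so truth and observation are consistent by construction.
#'
#' @param proteins Protein tibble.
#' @param truth Truth table from [simulate_fragmentation()].
#' @param config An [sim_config()] list.
#' @param boundaries Gel-section breakpoints.
#' @return List of two quantitation tibbles, `forward` and `reverse`, in the
#'   schema of [read_quant_table()].
#' @export
simulate_silac_tables <- function(proteins, truth, config = sim_config(),
                                  boundaries = gel_boundaries()) {
  sec <- function(s) {
    b <- vapply(s, function(x) {
      g <- assign_gel_section(x, boundaries); c(g$mwexp_lo, g$mwexp_hi)
    }, c(0, 0))
    list(lo = b[1, ], hi = b[2, ])
  }
  obs_kda <- ifelse(truth$class == "FRAGMENTED",
                    truth$frag_mass_kda, truth$intact_kda)
  rng <- sec(obs_kda)
  one <- function(orientation, noise) {
    ratio <- truth$true_ratio * exp(noise)
    ratio[truth$capped] <- 100
    tibble::tibble(
      accession = truth$accession,
      gene = proteins$gene,
      n_unique_peptides = pmax(1L, rpois(nrow(truth), 2)),
      ratio = ratio,
      capped = truth$capped,
      mwcal = truth$intact_kda,
      mwexp_lo = rng$lo, mwexp_hi = rng$hi,
      orientation = orientation)
  }
  withr::with_seed(stage_seed(config$rng_seed, "silac"), {
    nf <- rnorm(nrow(truth), 0, config$ratio_noise_sigma)
    nr <- rnorm(nrow(truth), 0, config$ratio_noise_sigma)
    fwd <- one("forward", nf)
    rev <- one("reverse", nr)
  })
  list(forward = fwd, reverse = rev)
}

# draw k truth-positive tiles whose combined pool readout deconvolves back
# to exactly those tiles: pool matrices are planned so the expected positives
# stay resolvable, so the generator emulates that design property
pick_identifiable_positives <- function(design, k, max_tries = 500) {
  ids <- design$assignment$tile_id
  while (k >= 1) {
    for (i in seq_len(max_tries)) {
      cand <- sample(ids, k)
      a <- design$assignment[design$assignment$tile_id %in% cand, ]
      res <- deconvolve_pools(design, unique(c(a$pool1, a$pool2)))
      if (!res$ambiguous && setequal(res$candidate_tiles, cand)) {
        return(sort(cand))
      }
    }
    k <- k - 1  # fall back to a smaller, resolvable positive set
  }
  character(0)
}

# survival coupled to a response value by median split: above-median
# patients have their hazard divided by hazard_ratio; independent
# exponential censoring calibrated to censoring_rate in the baseline group
sim_survival_from_values <- function(values, cohort_cfg) {
  h0 <- cohort_cfg$hazard_baseline
  hr <- cohort_cfg$hazard_ratio
  grp <- median_split(values)
  hz <- ifelse(grp == "HIGH", h0 / hr, h0)
  t_event <- rexp(length(values), hz)
  cr <- cohort_cfg$censoring_rate
  if (cr > 0) {
    c_rate <- h0 * cr / (1 - cr)
    t_cens <- rexp(length(values), c_rate)
  } else {
    t_cens <- rep(Inf, length(values))
  }
  tibble::tibble(
    patient_id = names(values),
    months = pmin(t_event, t_cens),
    event = t_event <= t_cens,
    group = unname(grp),
    value = unname(values))
}

#' Simulate a patient cohort with pooled T-cell responses and survival
#'
#' For every patient x timepoint x subset x cytokine x pool cell the
#' unstimulated background is drawn near `ns_mean`; pools containing at
#' least one truth-positive tile additionally receive the stage effect
#' (T0 < T1 < T2) under multiplicative lognormal noise. PD-1 percentages
#' within specific cells follow the configured rise-then-fall means.
#' Survival months are exponential, with the hazard divided by
#' `hazard_ratio` for patients whose CD8 IFN-gamma net response at T2 is
#' above the cohort median, and independently censored. Only the patients
#' followed to T2 contribute survival records.
#'
#' @param design An `nf_pool_design` from [design_pools()].
#' @param positive_tiles Character vector of truth-positive (immunogenic)
#'   tile ids.
#' @param config An [sim_config()] list.
#' @return List with `responses` (schema of [read_response_table()], plus
#'   `pct_pd1`), `survival` (schema of [read_survival_table()]) and
#'   `positive_pools` (the pools containing positive tiles).
#' @export
simulate_cohort <- function(design, positive_tiles, config = sim_config()) {
  co <- config$cohort
  a <- design$assignment
  pos <- a[a$tile_id %in% positive_tiles, , drop = FALSE]
  positive_pools <- sort(unique(c(pos$pool1, pos$pool2)))
  tps <- names(co$stage_means)
  patients <- sprintf("PT%02d", seq_len(co$n_patients))
  at_t2 <- patients[seq_len(min(co$n_patients_t2, co$n_patients))]
  grid <- tidyr::expand_grid(
    patient_id = patients, timepoint = tps,
    subset = c("CD4", "CD8"), cytokine = c("IFNG", "TNFA", "DUAL"),
    pool = seq_len(design$n_pools))
  grid <- grid[grid$timepoint != "T2" | grid$patient_id %in% at_t2, ]
  withr::with_seed(stage_seed(config$rng_seed, "cohort"), {
    ns <- pmax(rnorm(nrow(grid), co$ns_mean, co$ns_sigma), 0)
    eff <- co$stage_means[grid$timepoint] *
      (grid$pool %in% positive_pools) *
      exp(rnorm(nrow(grid), 0, co$response_noise_sigma))
    stim <- pmin(pmax(ns + eff, 0), 100)
    pd1 <- pmin(pmax(
      co$pd1_means[grid$timepoint] + rnorm(nrow(grid), 0, co$pd1_sigma),
      0), 100)
    responses <- dplyr::mutate(grid, pct_stim = stim, pct_ns = ns,
                               pct_pd1 = unname(pd1))
    # survival coupled to CD8 IFN-gamma net response at T2
    t2 <- responses[responses$timepoint == "T2" &
                    responses$subset == "CD8" &
                    responses$cytokine == "IFNG", ]
    t2$net <- net_response(t2$pct_stim, t2$pct_ns)
    lvl <- tapply(t2$net, t2$patient_id, mean)
    survival <- sim_survival_from_values(
      setNames(as.numeric(lvl), names(lvl)), co)
  })
  list(responses = responses, survival = survival,
       positive_pools = positive_pools)
}

#' Simulate survival records coupled to a response level
#'
#' Draws per-patient response levels (lognormal around the configured T2
#' stage mean) and survival times whose hazard is divided by `hazard_ratio`
#' for patients above the cohort median, with independent exponential
#' censoring calibrated to `censoring_rate` in the baseline group. Used to
#' study the operating characteristics of the median-split log-rank
#' comparison at cohort sizes beyond the study's own.
#'
#' @param n_patients Cohort size (>= 2).
#' @param config An [sim_config()] list; its `cohort` entry supplies the
#'   hazard parameters.
#' @param seed Optional seed overriding `config$rng_seed`.
#' @return Survival tibble: `patient_id`, `months`, `event`, `group`,
#'   `value`.
#' @export
simulate_survival_records <- function(n_patients, config = sim_config(),
                                      seed = NULL) {
  co <- config$cohort
  seed <- seed %||% stage_seed(config$rng_seed, "survival")
  withr::with_seed(seed, {
    values <- exp(rnorm(n_patients,
                        log(max(co$stage_means[["T2"]], 1e-3)),
                        max(co$response_noise_sigma, 1e-6)))
    names(values) <- sprintf("PT%03d", seq_len(n_patients))
    sim_survival_from_values(values, co)
  })
}

#' Run the full synthetic experiment
#'
#' Fans the master seed out to the per-stage generators and returns every
#' input the pipeline consumes together with the generating truth: a
#' proteome, fragmentation truth and evidence peptides, forward/reverse
#' SILAC tables, the peptide library and pool design built from the truth,
#' and a patient cohort whose positive tiles are the designed peptides of
#' truly fragmented proteins.
#'
#' @param config An [sim_config()] list.
#' @param pipeline_config An [nf_config()] list used for library and pool
#'   design.
#' @param n_selected_proteins Number of fragmented proteins carried into the
#'   peptide library (default 8, the number selected for immunologic
#'   validation in the study design this emulates).
#' @param n_positive_tiles Number of truth-positive (immunogenic) tiles
#'   drawn from the designed library (default 2, so noise-free pool
#'   readouts stay unambiguously deconvolvable per patient).
#' @return Named list with `proteins`, `truth`, `evidence`, `silac`
#'   (forward/reverse), `tiles`, `design`, `cohort`, `positive_tiles`.
#' @export
simulate_experiment <- function(config = sim_config(),
                                pipeline_config = nf_config(),
                                n_selected_proteins = 8,
                                n_positive_tiles = 2) {
  proteins <- simulate_proteome(config)
  fr <- simulate_fragmentation(proteins, config,
                               pipeline_config$gel_section_boundaries)
  silac <- simulate_silac_tables(proteins, fr$truth, config,
                                 pipeline_config$gel_section_boundaries)
  frag_acc <- fr$truth$accession[fr$truth$class == "FRAGMENTED"]
  frag_acc <- intersect(sort(frag_acc), fr$evidence$accession)
  frag_acc <- head(frag_acc, n_selected_proteins)
  tiles <- design_peptide_library(proteins, evidence = fr$evidence,
                                  config = pipeline_config,
                                  accessions = frag_acc)
  design <- design_pools(tiles$tile_id, pipeline_config$n_pools)
  positive_tiles <- withr::with_seed(
    stage_seed(config$rng_seed, "survival"),
    pick_identifiable_positives(design, min(n_positive_tiles, nrow(tiles))))
  cohort <- simulate_cohort(design, positive_tiles, config)
  list(proteins = proteins, truth = fr$truth, evidence = fr$evidence,
       silac = silac, tiles = tiles, design = design, cohort = cohort,
       positive_tiles = positive_tiles)
}
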