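new_pool_design <- function(n_pools, assignment) {
  structure(list(n_pools = as.integer(n_pools), assignment = assignment),
            class = "nf_pool_design")
}

#' @export
print.nf_pool_design <- function(x, ...) {
  loads <- pool_loads(x)
  cat("Two-of-N pool design:", nrow(x$assignment), "tiles in",
      x$n_pools, "pools\n")
  cat("pool sizes:", paste(loads, collapse = " "), "\n")
  invisible(x)
}

pool_loads <- function(design) {
  tabulate(c(design$assignment$pool1, design$assignment$pool2),
           nbins = design$n_pools)
}

# exact maximum matching on a small graph, branch-and-bound;
# edges: 2-column matrix of vertex indices
max_matching <- function(edges, n_vertices) {
  best_m <- integer(0)
  recur <- function(avail, m) {
    if (length(m) > length(best_m)) best_m <<- m
    if (nrow(avail) == 0L) return(invisible())
    if (length(m) + 2L * nrow(avail) <= length(best_m)) return(invisible())
    v <- min(avail)
    idx <- which(avail[, 1] == v | avail[, 2] == v)
    for (i in idx) {
      a <- avail[i, 1]; b <- avail[i, 2]
      keep <- avail[avail[, 1] != a & avail[, 2] != a &
                    avail[, 1] != b & avail[, 2] != b, , drop = FALSE]
      recur(keep, c(m, a, b))
    }
    recur(avail[avail[, 1] != v & avail[, 2] != v, , drop = FALSE], m)
  }
  recur(edges, integer(0))
  if (!length(best_m)) return(matrix(integer(0), 0, 2))
  m <- matrix(best_m, ncol = 2, byrow = TRUE)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Build a balanced two-of-N pool matrix
#'
#' Assigns every tile to a distinct unordered pair of pools so that a
#' positive pool pair identifies a single peptide, keeping pool sizes within
#' one of each other. At each step the constructor takes the pools with the
#' smallest current load and assigns tiles along an exact maximum matching of
#' the still-unused pairs among them (lexicographic tie-breaks); when no
#' within-level pair remains, a least-loaded pool is paired with the
#' least-loaded available partner. The matching lookahead is what guarantees
#' the balance invariant for every prefix length — a purely local greedy
#' choice can strand the last two least-loaded pools on an already-used pair.
#'
#' The `seed` only permutes which tile receives which pair; the pair sequence
#' itself is deterministic, so designs are reproducible.
#'
#' @param tile_ids Character vector of unique tile identifiers.
#' @param n_pools Number of pools (>= 3); capacity is `choose(n_pools, 2)`.
#' @param seed Optional integer; permutes tile order before assignment.
#' @return An `nf_pool_design`: `n_pools` plus an `assignment` tibble with
#'   `tile_id`, `pool1`, `pool2` (`pool1 < pool2`).
#' @export
#' @examples
#' d <- design_pools(paste0("t", 1:37), 12)
#' table(neofrag:::pool_loads(d))
design_pools <- function(tile_ids, n_pools, seed = NULL) {
  if (anyDuplicated(tile_ids)) abort("tile_ids must be unique")
  if (n_pools < 3) abort("n_pools must be >= 3")
  n <- length(tile_ids)
  cap <- choose(n_pools, 2)
  if (n > cap) {
    abort(paste0("too many tiles: ", n, " exceeds the ", cap,
                 " unique pool pairs available with ", n_pools, " pools"))
  }
  if (!is.null(seed)) {
    tile_ids <- withr::with_seed(seed, sample(tile_ids))
  }
  all_pairs <- t(combn(n_pools, 2))
  used <- rep(FALSE, nrow(all_pairs))
  pair_key <- function(i, j) (i - 1L) * n_pools + j
  key_to_row <- setNames(seq_len(nrow(all_pairs)),
                         pair_key(all_pairs[, 1], all_pairs[, 2]))
  load <- rep(0L, n_pools)
  out <- matrix(NA_integer_, n, 2)
  t <- 1L
  while (t <= n) {
    m <- min(load)
    S <- which(load == m)
    in_s <- all_pairs[, 1] %in% S & all_pairs[, 2] %in% S & !used
    if (any(in_s)) {
      mm <- max_matching(all_pairs[in_s, , drop = FALSE], n_pools)
      for (r in seq_len(nrow(mm))) {
        if (t > n) break
        i <- mm[r, 1]; j <- mm[r, 2]
        used[key_to_row[[as.character(pair_key(i, j))]]] <- TRUE
        load[c(i, j)] <- load[c(i, j)] + 1L
        out[t, ] <- c(i, j)
        t <- t + 1L
      }
    } else {
      # least-loaded pool must pair upward with the least-loaded partner
      cand <- which(!used & xor(all_pairs[, 1] %in% S, all_pairs[, 2] %in% S))
      l1 <- load[all_pairs[cand, 1]]
      l2 <- load[all_pairs[cand, 2]]
      k <- cand[order(pmax(l1, l2), all_pairs[cand, 1],
                      all_pairs[cand, 2])[1]]
      used[k] <- TRUE
      load[all_pairs[k, ]] <- load[all_pairs[k, ]] + 1L
      out[t, ] <- all_pairs[k, ]
      t <- t + 1L
    }
  }
  assignment <- tibble::tibble(tile_id = tile_ids,
                               pool1 = out[, 1], pool2 = out[, 2])
  assignment <- dplyr::arrange(assignment, .data$tile_id)
  nf_log("design_pools: %d tiles over %d pools (capacity %d)", n, n_pools, cap)
  new_pool_design(n_pools, assignment)
}

#' Deconvolve pool-level positives to peptide candidates
#'
#' Candidates are all tiles whose two pools are both positive. The result is
#' flagged ambiguous unless the candidate set is the unique minimal
#' explanation of the positive pools: every positive pool must be covered by
#' at least one candidate, and no candidate may be redundant (each must
#' contribute a pool no other candidate covers) — otherwise more than one
#' candidate subset explains the readout.
#'
#' @param design An `nf_pool_design` from [design_pools()].
#' @param positive_pools Integer set of positive pool indices.
#' @return List with `positive_pools`, `candidate_tiles` (sorted character)
#'   and `ambiguous` (logical).
#' @export
deconvolve_pools <- function(design, positive_pools) {
  positive_pools <- unique(as.integer(positive_pools))
  if (length(positive_pools) &&
      any(positive_pools < 1 | positive_pools > design$n_pools)) {
    abort("positive pool index out of range")
  }
  a <- design$assignment
  hit <- a$pool1 %in% positive_pools & a$pool2 %in% positive_pools
  cand <- a[hit, , drop = FALSE]
  if (!nrow(cand)) {
    return(list(positive_pools = sort(positive_pools),
                candidate_tiles = character(0),
                ambiguous = length(positive_pools) > 0))
  }
  covered <- unique(c(cand$pool1, cand$pool2))
  uncovered <- setdiff(positive_pools, covered)
  redundant <- vapply(seq_len(nrow(cand)), function(i) {
    others <- unique(c(cand$pool1[-i], cand$pool2[-i]))
    all(positive_pools %in% others)
  }, TRUE)
  ambiguous <- length(uncovered) > 0 || any(redundant)
  list(positive_pools = sort(positive_pools),
       candidate_tiles = sort(cand$tile_id),
       ambiguous = ambiguous)
}

#' Validate a pool design
#'
#' Report-only check of the design invariants: each tile sits in exactly two
#' distinct pools, no two tiles share a pool pair, all indices are in range,
#' and pool sizes differ by at most one.
#'
#' @param design An `nf_pool_design`.
#' @return List with `pass` (logical) and `failures` (character vector of
#'   violated invariants, empty on pass).
#' @export
validate_pool_design <- function(design) {
  a <- design$assignment
  failures <- character(0)
  if (any(a$pool1 == a$pool2)) {
    failures <- c(failures, "2-of-N violated: tile assigned twice to one pool")
  }
  if (any(a$pool1 < 1 | a$pool2 < 1 |
          a$pool1 > design$n_pools | a$pool2 > design$n_pools)) {
    failures <- c(failures, "pool index out of range")
  }
  key <- paste(pmin(a$pool1, a$pool2), pmax(a$pool1, a$pool2))
  if (anyDuplicated(key)) {
    failures <- c(failures, "unique-pair violated: duplicated pool pair")
  }
  if (anyDuplicated(a$tile_id)) {
    failures <- c(failures,
                  "2-of-N violated: tile assigned to more than two pools")
  }
  loads <- pool_loads(design)
  if (diff(range(loads)) > 1) {
    failures <- c(failures, "balance violated: pool sizes differ by more than 1")
  }
  list(pass = length(failures) == 0, failures = failures)
}
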