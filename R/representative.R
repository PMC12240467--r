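#' Enumerating gMCSs with k-representative subsets
#'
#' The driver maintains a small ordered list of modes T' (a representative
#' subset of the target region T) and a catalog of confirmed gMCSs. Work
#' proceeds in phases of increasing cardinality k: candidates are the minimal
#' hitting sets of size exactly k over the families of T' (capped at k), each
#' candidate is either confirmed as a gMCS of T by an oracle cut-set check or
#' refuted by a witness mode of T that survives the knockout, and refuting
#' witnesses are appended to T' (deduplicated by support). After the phase at
#' cardinality k, T' is k-representative: its gMCSs of length <= k are
#' exactly those of T, so no confirmed set is ever re-tested.
#'
#' @name representative
NULL

mode_key <- function(support) set_key(sort(support))

#' Initialize the enumeration state
#'
#' Seeds T' with a first witness of the target (the empty knockout) and sets
#' the starting cardinality to the smallest member of that mode's family: any
#' cut set of T must contain a member of the first mode's family, so no gMCS
#' shorter than that minimum exists and the phases below it are provably
#' empty. If the first mode's family is empty the target cannot be blocked
#' genetically at all and the enumeration is already finished.
#'
#' @param oracle a `witness_oracle`.
#' @param k_max cardinality cap (`>= 1`).
#' @return an enumeration state (list), for use with [next_candidates()] and
#'   [confirm_candidates()]; most callers want [compute_gmcs()] instead.
#' @export
rep_initialize <- function(oracle, k_max) {
  stopifnot(inherits(oracle, "witness_oracle"), k_max >= 1)
  w <- oracle$find_witness(character(0))
  if (is.null(w)) {
    stop("rep_initialize: wild-type target is infeasible", call. = FALSE)
  }
  state <- list(oracle = oracle, k_max = as.integer(k_max),
                modes = list(w), mode_keys = mode_key(w$support),
                confirmed = list(), confirmed_by_k = list(),
                lp_calls = 1L, finished = FALSE, k_current = NA_integer_,
                stats = list())
  fam <- oracle$mode_family(w$support, k = NULL)
  if (length(fam) == 0L) {
    state$finished <- TRUE
    state$k_current <- k_max + 1L
    return(state)
  }
  state$k_current <- min(lengths(fam$members))
  if (state$k_current > k_max) state$finished <- TRUE
  state
}

contains_confirmed <- function(state, G) {
  for (C in state$confirmed) {
    if (all(C %in% G)) return(TRUE)
  }
  FALSE
}

#' Candidate gMCSs for the next phase
#'
#' Minimal hitting sets over the current T' families capped at `k_next`,
#' restricted to size exactly `k_next`, with any set containing an
#' already-confirmed gMCS removed.
#'
#' @param state an enumeration state.
#' @param k_next the phase cardinality.
#' @return a `gene_set_family`.
#' @export
next_candidates <- function(state, k_next) {
  fams <- lapply(state$modes,
                 function(m) state$oracle$mode_family(m$support, k = k_next))
  mhs <- minimal_hitting_sets(fams, k = k_next)
  keep <- mhs$members[lengths(mhs$members) == k_next]
  keep <- keep[!vapply(keep, function(G) contains_confirmed(state, G), NA)]
  gene_set_family(keep, cap = k_next)
}

#' Confirm or refute one phase of candidates
#'
#' Candidates are processed in canonical order. A candidate failing to hit
#' the family of a mode added earlier in the same phase is refuted without a
#' solver call (the surviving mode is already in T'). Otherwise the oracle
#' decides: confirmation enters the catalog at cardinality `k`; refutation
#' yields a witness mode of T, appended to T' unless its support is already
#' present. T' therefore gains at most one mode per refuted candidate.
#'
#' @param state an enumeration state.
#' @param candidates a `gene_set_family`, every member of size `k`.
#' @param k the phase cardinality.
#' @return the updated state, with a phase record appended to `$stats`.
#' @export
confirm_candidates <- function(state, candidates, k) {
  confirmed_here <- list()
  witnesses_added <- 0L
  fams_k <- lapply(state$modes,
                   function(m) state$oracle$mode_family(m$support, k = k))
  for (G in candidates$members) {
    if (contains_confirmed(state, G)) next
    hit_all <- all(vapply(fams_k, function(f) is_cutset_for_mode(G, f), NA))
    if (!hit_all) next  # an existing mode already refutes G
    state$lp_calls <- state$lp_calls + 1L
    if (state$oracle$is_gcs(G)) {
      confirmed_here[[length(confirmed_here) + 1L]] <- G
      state$confirmed[[length(state$confirmed) + 1L]] <- G
    } else {
      state$lp_calls <- state$lp_calls + 1L
      w <- state$oracle$find_witness(G)
      if (is.null(w)) {
        stop("confirm_candidates: oracle contradiction (no witness for a non-cut set)",
             call. = FALSE)
      }
      key <- mode_key(w$support)
      if (!(key %in% state$mode_keys)) {
        state$modes[[length(state$modes) + 1L]] <- w
        state$mode_keys <- c(state$mode_keys, key)
        fams_k[[length(fams_k) + 1L]] <- state$oracle$mode_family(w$support, k = k)
        witnesses_added <- witnesses_added + 1L
      }
    }
  }
  state$confirmed_by_k[[as.character(k)]] <- gene_set_family(confirmed_here)
  state$stats[[length(state$stats) + 1L]] <- data.frame(
    k = k, candidates = length(candidates),
    confirmed = length(confirmed_here), witnesses_added = witnesses_added,
    modes_total = length(state$modes), lp_calls = state$lp_calls)
  state
}

#' Enumerate all gMCSs of a target up to cardinality k_max
#'
#' Runs the full phase loop: initialize, then for each k up to `k_max`
#' generate candidates and confirm/refute them. Deterministic given a
#' deterministic oracle; candidate order is canonical, so witness sets are
#' stable.
#'
#' @param oracle a `witness_oracle` (see [lp_oracle()], [enumerated_oracle()]).
#' @param k_max cardinality cap (`>= 1`).
#' @param verbose print one progress line per phase (k, candidate count,
#'   confirmed count, |T'|, oracle call count).
#' @return a `gmcs_catalog`; attribute `"phases"` holds the per-phase stats
#'   data frame and attribute `"modes"` the final representative subset.
#' @examples
#' toy <- toy_fixture()
#' orc <- enumerated_oracle(toy$supports, toy$reaction_families, toy$genes)
#' compute_gmcs(orc, k_max = 3)
#' @export
compute_gmcs <- function(oracle, k_max = 4, verbose = FALSE) {
  state <- rep_initialize(oracle, k_max)
  if (!state$finished) {
    for (k in seq.int(state$k_current, k_max)) {
      cands <- next_candidates(state, k)
      state <- confirm_candidates(state, cands, k)
      if (verbose) {
        s <- state$stats[[length(state$stats)]]
        message(sprintf("phase k=%d: %d candidate(s), %d confirmed, |T'|=%d, %d oracle call(s)",
                        s$k, s$candidates, s$confirmed, s$modes_total, s$lp_calls))
      }
      state$k_current <- k + 1L
    }
  }
  by_card <- list()
  for (k in seq_len(k_max)) {
    kk <- as.character(k)
    by_card[[kk]] <- if (!is.null(state$confirmed_by_k[[kk]])) {
      state$confirmed_by_k[[kk]]
    } else {
      gene_set_family(list())
    }
  }
  cat <- gmcs_catalog(by_card, target = oracle$name, k_max = as.integer(k_max))
  stats <- if (length(state$stats) > 0) do.call(rbind, state$stats) else
    data.frame(k = integer(0), candidates = integer(0), confirmed = integer(0),
               witnesses_added = integer(0), modes_total = integer(0),
               lp_calls = integer(0))
  attr(cat, "phases") <- stats
  attr(cat, "modes") <- state$modes
  cat
}

#' Classify every entry of a coupling catalog
#'
#' Applies [classify_intervention()] to each confirmed gMCS.
#'
#' @param catalog a `gmcs_catalog` computed on a coupling target.
#' @param model the underlying `metabolic_model`.
#' @param p biomass fraction used by the target.
#' @param biomass_max wild-type maximal biomass.
#' @return the catalog with its `classification` filled in.
#' @export
classify_catalog <- function(catalog, model, p = 0.01, biomass_max = NULL) {
  if (is.null(biomass_max)) biomass_max <- max_biomass(model)
  sets <- catalog_sets(catalog)
  cls <- vapply(sets, function(G) {
    classify_intervention(model, G, p = p, biomass_max = biomass_max)
  }, "")
  catalog$classification <- setNames(cls, vapply(sets, set_key, ""))
  catalog
}
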