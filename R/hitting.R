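#' Generalized minimal hitting sets over mode families
#'
#' A gene set G cuts a flux mode v exactly when G contains some member of the
#' mode's gene-support family gMCS(v). The cut sets of a collection of modes
#' are therefore its generalized hitting sets, and the minimal ones are found
#' incrementally: starting from the family containing only the empty set,
#' each mode's family is folded in with [berge_step()].
#'
#' @name hitting
NULL

#' Gene-support family of a flux mode
#'
#' The family of minimal gene cut sets of a mode is the reduction of the
#' union of the per-reaction families over the mode's support. An empty
#' result means the mode cannot be blocked genetically (all support reactions
#' lack genetic support).
#'
#' @param support character vector of reaction identifiers (nonempty).
#' @param reaction_families named list mapping reaction id ->
#'   `gene_set_family`; every support reaction must have an entry.
#' @param k optional cardinality cap.
#' @return a `gene_set_family`.
#' @export
mode_gmcs <- function(support, reaction_families, k = NULL) {
  support <- as.character(support)
  missing <- setdiff(support, names(reaction_families))
  if (length(missing) > 0L) {
    stop(sprintf("mode_gmcs: unknown reaction(s) in support: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  members <- unlist(lapply(reaction_families[support], function(f) f$members),
                    recursive = FALSE)
  gene_set_family(if (is.null(members)) list() else members, cap = k)
}

#' One step of the modified Berge algorithm
#'
#' Folds one mode's family into the current working family of minimal
#' hitting sets. Sets already hitting the new family survive; each failing
#' set G spawns candidates G union G' over the new family's members G'.
#' Candidates are pruned by the cardinality cap first (cheapest), duplicates
#' collapsed by canonical encoding, and the result reduced, so the working
#' family stays reduced after every mode.
#'
#' @param current a reduced `gene_set_family`; initialization is the family
#'   containing the empty set (`gene_set_family(list(character(0)))`).
#' @param mode_family the incoming mode's `gene_set_family`.
#' @param k cardinality cap, or `NULL` for uncapped.
#' @return the updated reduced `gene_set_family`; every member has size
#'   `<= k` and hits the new mode. An empty `mode_family` (unblockable mode)
#'   empties the result.
#' @export
berge_step <- function(current, mode_family, k = NULL) {
  stopifnot(inherits(current, "gene_set_family"),
            inherits(mode_family, "gene_set_family"))
  out <- list()
  for (G in current$members) {
    if (is_cutset_for_mode(G, mode_family)) {
      if (is.null(k) || length(G) <= k) out[[length(out) + 1L]] <- G
      next
    }
    for (Gp in mode_family$members) {
      cand <- sort(unique(c(G, Gp)))
      if (is.null(k) || length(cand) <= k) out[[length(out) + 1L]] <- cand
    }
  }
  gene_set_family(out, cap = k)
}

#' All minimal hitting sets of a list of families, up to cardinality k
#'
#' Returns the reduced family of every inclusion-minimal gene set of size
#' `<= k` that contains at least one member of each input family. The result
#' is independent of the order of the input families. A family with no
#' member of size `<= k` simply cannot be hit within the cap, so the result
#' may be empty.
#'
#' @param families list of `gene_set_family` objects (each reduced).
#' @param k cardinality cap (`>= 1`), or `NULL` for uncapped.
#' @return a `gene_set_family`.
#' @examples
#' f1 <- gene_set_family(list("a", "b"))
#' f2 <- gene_set_family(list("b", "c"))
#' minimal_hitting_sets(list(f1, f2), k = 2)  # {{b},{a,c}}
#' @export
minimal_hitting_sets <- function(families, k = NULL) {
  stopifnot(is.null(k) || k >= 1)
  acc <- gene_set_family(list(character(0)))
  for (fam in families) {
    acc <- berge_step(acc, fam, k = k)
    if (length(acc) == 0L) break
  }
  acc
}
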