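#' Gene-set families
#'
#' A `gene_set_family` is a reduced collection of finite gene sets: no member
#' contains another member as a subset. Families represent the genetic cut-set
#' structure of a reaction (`reaction_gmcs()`), of a flux mode
#' (`mode_gmcs()`), and of whole catalogs. Members are stored in a canonical
#' order (each member sorted, members ordered lexicographically) so that all
#' downstream output is deterministic.
#'
#' @param members list of character vectors (gene identifiers); may contain
#'   duplicates and supersets, which are removed.
#' @param cap optional integer cardinality cap `k`; members larger than `k`
#'   are dropped *after* reduction, so a capped family is exactly the
#'   size-`<= k` slice of the uncapped one.
#' @return an object of class `gene_set_family`.
#' @examples
#' gene_set_family(list(c("g0", "g1"), "g0"))  # reduces to {{g0}}
#' @export
gene_set_family <- function(members = list(), cap = NULL) {
  members <- lapply(members, function(g) sort(unique(as.character(g))))
  members <- reduce_members(members)
  if (!is.null(cap)) {
    stopifnot(length(cap) == 1L, cap >= 1L)
    members <- members[lengths(members) <= cap]
  }
  structure(list(members = members, cap = cap), class = "gene_set_family")
}

# canonical key for a sorted gene vector; \x1f never occurs in identifiers
set_key <- function(g) paste(g, collapse = "\x1f")

# inclusion-minimal, deduplicated, canonically ordered member list
reduce_members <- function(members) {
  if (length(members) == 0L) return(list())
  keys <- vapply(members, set_key, "")
  members <- members[!duplicated(keys)]
  ord <- order(lengths(members))
  members <- members[ord]
  keep <- logical(length(members))
  kept <- list()
  for (i in seq_along(members)) {
    g <- members[[i]]
    minimal <- TRUE
    for (h in kept) {
      if (all(h %in% g)) { minimal <- FALSE; break }
    }
    if (minimal) {
      keep[i] <- TRUE
      kept[[length(kept) + 1L]] <- g
    }
  }
  members <- members[keep]
  members[order(vapply(members, set_key, ""))]
}

#' Reduce a collection of gene sets to its inclusion-minimal members
#'
#' Removes duplicates and any set that contains another set of the collection.
#' Idempotent and invariant under permutation of the input.
#'
#' @param members a list of character vectors, or a `gene_set_family`.
#' @return a `gene_set_family` holding exactly the minimal sets.
#' @export
reduce_family <- function(members) {
  if (inherits(members, "gene_set_family")) members <- members$members
  gene_set_family(members)
}

#' @export
length.gene_set_family <- function(x) length(x$members)

#' @exportS3Method base::print
print.gene_set_family <- function(x, ...) {
  cat(sprintf("<gene_set_family: %d set(s)%s>\n", length(x$members),
              if (is.null(x$cap)) "" else sprintf(", cap k=%d", x$cap)))
  for (g in x$members) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

#' @export
as.list.gene_set_family <- function(x, ...) x$members

family_keys <- function(fam) vapply(fam$members, set_key, "")

#' Test two families for equality as sets of gene sets
#' @param a,b `gene_set_family` objects.
#' @return logical.
#' @export
family_equal <- function(a, b) {
  setequal(family_keys(a), family_keys(b))
}

#' Does a gene set contain some member of a family?
#'
#' The generalized hitting test: `TRUE` iff some family member is a subset of
#' `G`. A gene set cuts a mode exactly when it hits the mode's family, so this
#' predicate is the workhorse of cut-set checking on enumerated modes.
#'
#' @param G character vector of gene identifiers.
#' @param family a `gene_set_family`.
#' @return logical. An empty family is never hit.
#' @export
is_cutset_for_mode <- function(G, family) {
  stopifnot(inherits(family, "gene_set_family"))
  for (m in family$members) {
    if (all(m %in% G)) return(TRUE)
  }
  FALSE
}

#' Serialize / read a family as TSV (one set per line, genes comma-separated)
#'
#' Debugging helper; the canonical member order makes output stable.
#' @param family a `gene_set_family`.
#' @param path file path.
#' @return `read_family_tsv` returns a `gene_set_family`.
#' @export
write_family_tsv <- function(family, path) {
  lines <- vapply(family$members, function(g) paste(g, collapse = ","), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_family_tsv
#' @export
read_family_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  gene_set_family(strsplit(lines, ",", fixed = TRUE))
}
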