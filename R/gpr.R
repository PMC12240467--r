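#' Gene-protein rule (GPR) expressions
#'
#' GPRs are monotone boolean expressions over gene identifiers attached to a
#' reaction: they state which gene combinations must be active for the
#' reaction to carry flux. `parse_gpr()` accepts the rule strings found in
#' COBRA JSON (`gene_reaction_rule`) and in SBML-fbc gene-product
#' associations: identifiers combined with `and`/`or` (case-insensitive; `&`
#' and `|` are synonyms) and parentheses, `and` binding tighter than `or`.
#' Gene identifiers are opaque strings: no case folding or other
#' normalization is applied, so distinct loci are never silently merged.
#'
#' @param text a GPR rule string; the empty string (or `NA`) yields the empty
#'   rule, meaning the reaction has no genetic support.
#' @return an object of class `gpr_expr` with node kinds `gene`, `and`, `or`
#'   or `empty`.
#' @examples
#' parse_gpr("g0 and (g5 or g6 or g7)")
#' @export
parse_gpr <- function(text) {
  if (length(text) != 1L || is.na(text)) text <- ""
  toks <- gpr_tokenize(text)
  if (nrow(toks) == 0L) return(gpr_empty())
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st)
  if (st$pos <= nrow(st$toks)) {
    stop(sprintf("GPR parse error: unexpected '%s' at position %d",
                 st$toks$text[st$pos], st$toks$at[st$pos]), call. = FALSE)
  }
  expr
}

gpr_tokenize <- function(text) {
  text <- as.character(text)
  n <- nchar(text)
  toks <- list(); ats <- integer(); kinds <- character()
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", "&", "|")) {
      kind <- switch(ch, "(" = "lpar", ")" = "rpar", "&" = "and", "|" = "or")
      toks[[length(toks) + 1L]] <- ch; ats <- c(ats, i); kinds <- c(kinds, kind)
      i <- i + 1L
      next
    }
    # identifier: run of characters excluding whitespace, parens, & and |
    m <- regmatches(substr(text, i, n),
                    regexpr("^[^()&|[:space:]]+", substr(text, i, n)))
    word <- m[[1]]
    lw <- tolower(word)
    kind <- if (lw == "and") "and" else if (lw == "or") "or" else "gene"
    toks[[length(toks) + 1L]] <- word; ats <- c(ats, i); kinds <- c(kinds, kind)
    i <- i + nchar(word)
  }
  data.frame(text = unlist(c(toks, list(character(0)))),
             at = ats, kind = kinds, stringsAsFactors = FALSE)
}

gpr_peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$kind[st$pos] else "eof"

gpr_parse_or <- function(st) {
  children <- list(gpr_parse_and(st))
  while (gpr_peek(st) == "or") {
    st$pos <- st$pos + 1L
    children[[length(children) + 1L]] <- gpr_parse_and(st)
  }
  gpr_node("or", children)
}

gpr_parse_and <- function(st) {
  children <- list(gpr_parse_atom(st))
  while (gpr_peek(st) == "and") {
    st$pos <- st$pos + 1L
    children[[length(children) + 1L]] <- gpr_parse_atom(st)
  }
  gpr_node("and", children)
}

gpr_parse_atom <- function(st) {
  k <- gpr_peek(st)
  if (k == "gene") {
    g <- st$toks$text[st$pos]
    st$pos <- st$pos + 1L
    return(gpr_gene(g))
  }
  if (k == "lpar") {
    at <- st$toks$at[st$pos]
    st$pos <- st$pos + 1L
    expr <- gpr_parse_or(st)
    if (gpr_peek(st) != "rpar") {
      stop(sprintf("GPR parse error: unbalanced '(' opened at position %d", at),
           call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(expr)
  }
  where <- if (st$pos <= nrow(st$toks)) {
    sprintf("'%s' at position %d", st$toks$text[st$pos], st$toks$at[st$pos])
  } else "end of rule"
  stop(sprintf("GPR parse error: expected gene or '(' but found %s", where),
       call. = FALSE)
}

gpr_empty <- function() structure(list(kind = "empty"), class = "gpr_expr")
gpr_gene <- function(g) structure(list(kind = "gene", gene = g), class = "gpr_expr")

# n-ary node; flattens nested same-kind children and collapses single children
gpr_node <- function(kind, children) {
  flat <- list()
  for (ch in children) {
    if (ch$kind == kind) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  if (length(flat) == 1L) return(flat[[1]])
  structure(list(kind = kind, children = flat), class = "gpr_expr")
}

#' @exportS3Method base::print
print.gpr_expr <- function(x, ...) {
  cat("<gpr_expr> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::format
format.gpr_expr <- function(x, ...) {
  switch(x$kind,
    empty = "",
    gene = x$gene,
    and = paste(vapply(x$children, function(ch) {
      s <- format(ch)
      if (ch$kind == "or") paste0("(", s, ")") else s
    }, ""), collapse = " and "),
    or = paste(vapply(x$children, format, ""), collapse = " or ")
  )
}

#' Genes mentioned by a rule
#' @param expr a `gpr_expr`.
#' @return character vector (sorted, unique); empty for the empty rule.
#' @export
gpr_genes <- function(expr) {
  if (expr$kind == "empty") return(character(0))
  if (expr$kind == "gene") return(expr$gene)
  sort(unique(unlist(lapply(expr$children, gpr_genes))))
}

#' Evaluate a rule under a gene knockout
#'
#' Genes in `knocked` are set to FALSE, every other gene to TRUE. The empty
#' rule evaluates to TRUE: a reaction without genetic support is unaffected
#' by any knockout.
#'
#' @param expr a `gpr_expr`.
#' @param knocked character vector of knocked-out gene identifiers.
#' @return logical.
#' @export
evaluate_gpr <- function(expr, knocked) {
  switch(expr$kind,
    empty = TRUE,
    gene = !(expr$gene %in% knocked),
    and = all(vapply(expr$children, evaluate_gpr, NA, knocked = knocked)),
    or = any(vapply(expr$children, evaluate_gpr, NA, knocked = knocked))
  )
}

# absorb supersets among DNF terms (terms: list of sorted character vectors)
absorb_terms <- function(terms) reduce_members(terms)

#' Convert a rule to disjunctive normal form
#'
#' Returns the DNF summands as a list of gene sets. Absorbed (superset) terms
#' are removed as the product is formed, so the result is boolean-equivalent
#' to the input and irredundant. Rules that are neither pure DNF nor pure CNF
#' are normalized by recursive distribution; a guard aborts with a "rule too
#' complex" error if the intermediate term count exceeds `max_terms` (never
#' silent truncation).
#'
#' @param expr a `gpr_expr`; must not be the empty rule.
#' @param max_terms intermediate term-count limit (default `1e6`).
#' @return list of character vectors, each one conjunctive summand.
#' @export
to_dnf <- function(expr, max_terms = 1e6) {
  if (expr$kind == "empty") {
    stop("to_dnf: the empty rule has no DNF representation", call. = FALSE)
  }
  rec <- function(e) {
    switch(e$kind,
      gene = list(e$gene),
      or = {
        terms <- unlist(lapply(e$children, rec), recursive = FALSE)
        if (length(terms) > max_terms) stop("rule too complex", call. = FALSE)
        absorb_terms(terms)
      },
      and = {
        acc <- list(character(0))
        for (ch in e$children) {
          t2 <- rec(ch)
          if (length(acc) * length(t2) > max_terms) {
            stop("rule too complex", call. = FALSE)
          }
          acc <- unlist(lapply(acc, function(a) {
            lapply(t2, function(b) sort(unique(c(a, b))))
          }), recursive = FALSE)
          acc <- absorb_terms(acc)
        }
        acc
      }
    )
  }
  rec(expr)
}

#' CNF factors of a DNF rule via minimal hitting sets
#'
#' Each DNF summand is a gene set; the minimal hitting sets of those sets are
#' exactly the factors of the boolean-equivalent conjunctive normal form, and
#' therefore the reaction's candidate genetic minimal cut sets. Computed with
#' the incremental Berge construction.
#'
#' @param terms nonempty list of nonempty gene sets (DNF summands).
#' @return a `gene_set_family` of the minimal CNF factors.
#' @export
dnf_to_cnf_factors <- function(terms) {
  if (length(terms) == 0L) {
    stop("dnf_to_cnf_factors: empty term list", call. = FALSE)
  }
  terms <- lapply(terms, function(g) sort(unique(as.character(g))))
  if (any(lengths(terms) == 0L)) {
    stop("dnf_to_cnf_factors: terms must be nonempty gene sets", call. = FALSE)
  }
  # hitting a plain set = containing one of its elements, i.e. hitting the
  # family of its singletons
  fams <- lapply(terms, function(t) gene_set_family(as.list(t)))
  minimal_hitting_sets(fams, k = NULL)
}

# if the rule is CNF-shaped (literal / or-of-literals / and of those),
# return its factor sets, else NULL
cnf_factors_if_cnf <- function(expr) {
  or_lits <- function(e) {
    if (e$kind == "gene") return(e$gene)
    if (e$kind == "or" &&
        all(vapply(e$children, function(c) c$kind == "gene", NA))) {
      return(vapply(e$children, function(c) c$gene, ""))
    }
    NULL
  }
  if (expr$kind %in% c("gene", "or")) {
    f <- or_lits(expr)
    return(if (is.null(f)) NULL else list(f))
  }
  if (expr$kind == "and") {
    out <- lapply(expr$children, or_lits)
    if (any(vapply(out, is.null, NA))) return(NULL)
    return(out)
  }
  NULL
}

#' Genetic minimal cut sets of a single reaction
#'
#' For a CNF-shaped rule the gMCSs are the inclusion-minimal factors; any
#' other rule is first converted to DNF and then factored by minimal hitting
#' sets. The empty rule yields the empty family: such a reaction cannot be
#' blocked genetically. If `k` is given, members larger than `k` are dropped
#' *after* reduction, so the capped family is the exact size-`<= k` slice of
#' the uncapped one.
#'
#' @param expr a `gpr_expr`.
#' @param k optional cardinality cap (`>= 1`).
#' @return a `gene_set_family`.
#' @examples
#' reaction_gmcs(parse_gpr("g0 and (g5 or g6 or g7)"))  # {{g0},{g5,g6,g7}}
#' @export
reaction_gmcs <- function(expr, k = NULL) {
  if (expr$kind == "empty") return(gene_set_family(list(), cap = k))
  fac <- cnf_factors_if_cnf(expr)
  fam <- if (!is.null(fac)) {
    gene_set_family(fac)
  } else {
    dnf_to_cnf_factors(to_dnf(expr))
  }
  gene_set_family(fam$members, cap = k)
}
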