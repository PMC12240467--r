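# Independent brute-force oracles and small model builders used across tests.
# Oracles enumerate exhaustively and never share code paths with the package
# implementation they check.

# all gene subsets of size <= k, as a list of sorted character vectors
all_subsets <- function(genes, k) {
  out <- list(character(0))
  for (size in seq_len(min(k, length(genes)))) {
    cmb <- utils::combn(genes, size, simplify = FALSE)
    out <- c(out, lapply(cmb, sort))
  }
  out
}

# brute-force generalized minimal hitting sets: test every subset of size <= k
# for the hitting property, keep the inclusion-minimal ones
brute_mhs <- function(families, k, genes) {
  hits <- function(G) {
    all(vapply(families, function(f) {
      any(vapply(f$members, function(m) all(m %in% G), FALSE))
    }, NA))
  }
  hitting <- Filter(hits, all_subsets(genes, k))
  gene_set_family(hitting)
}

# brute-force gMCS catalog from an is_gcs predicate
brute_gmcs <- function(is_gcs_fn, genes, k_max) {
  cuts <- Filter(is_gcs_fn, all_subsets(genes, k_max)[-1])
  gene_set_family(cuts)
}

# random monotone GPR rule string over the given genes (seeded by caller)
random_rule <- function(genes, depth = 3) {
  rec <- function(d) {
    if (d == 0 || stats::runif(1) < 0.35) {
      return(sample(genes, 1))
    }
    op <- sample(c(" and ", " or "), 1)
    nk <- sample(2:3, 1)
    kids <- vapply(seq_len(nk), function(i) rec(d - 1), "")
    paste0("(", paste(kids, collapse = op), ")")
  }
  rec(depth)
}

# evaluate a CNF given as a gene_set_family of clauses under a truth assignment
cnf_eval <- function(family, true_genes) {
  all(vapply(family$members, function(cl) any(cl %in% true_genes), NA))
}

# random reduced family over the given genes
random_family <- function(genes, n_sets = 4, max_size = 3) {
  members <- lapply(seq_len(n_sets), function(i) {
    sample(genes, sample.int(max_size, 1))
  })
  gene_set_family(members)
}

diamond_model <- function() {
  read_model(system.file("extdata", "diamond.json", package = "gmcskit"))
}

# the known elementary-mode supports of the diamond network's growth region
diamond_efm_supports <- function() {
  list(c("R_up", "R_a1", "R_b", "R_bio"),
       c("R_up", "R_a2", "R_b", "R_bio"))
}

# small growth-coupling model: two routes A -> B, one co-producing P which
# must be exported at steady state; biomass consumes B
coupling_toy_model <- function() {
  mets <- c("A", "B", "P")
  rxns <- c("R_up", "R_plain", "R_co", "R_bio", "R_ex_p")
  S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
  S["A", "R_up"] <- 1
  S["A", "R_plain"] <- -1; S["B", "R_plain"] <- 1
  S["A", "R_co"] <- -1; S["B", "R_co"] <- 1; S["P", "R_co"] <- 1
  S["B", "R_bio"] <- -1
  S["P", "R_ex_p"] <- -1
  metabolic_model(
    id = "coupling_toy", metabolites = mets, reactions = rxns, S = S,
    lb = c(0, 0, 0, 0, 0), ub = c(10, 1000, 1000, 1000, 1000),
    gpr_strings = c(R_plain = "ga", R_co = "gc", R_bio = "gb"),
    biomass_reaction = "R_bio")
}

# independent LP oracle: scipy.optimize.linprog (HiGHS) via the system python
scipy_lp <- function(obj, Aeq, beq, lb, ub, Aineq = NULL, bineq = NULL) {
  payload <- list(obj = obj, Aeq = Aeq, beq = beq, lb = lb, ub = ub)
  if (!is.null(Aineq)) { payload$Aineq <- Aineq; payload$bineq <- bineq }
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, digits = NA, matrix = "rowmajor")
  script <- paste(
    "import json, sys, numpy as np, scipy.optimize as so",
    sprintf("d = json.load(open(%s))", deparse(fin)),
    "kw = {}",
    "if 'Aineq' in d: kw = dict(A_ub=-np.array(d['Aineq']), b_ub=-np.array(d['bineq']))",
    "r = so.linprog(c=-np.array(d['obj']), A_eq=np.array(d['Aeq']), b_eq=np.array(d['beq']),",
    "  bounds=list(zip(d['lb'], d['ub'])), method='highs', **kw)",
    "status = {0: 'optimal', 2: 'infeasible', 3: 'unbounded'}.get(r.status, 'other')",
    "obj = -r.fun if r.status == 0 else None",
    sprintf("json.dump({'status': status, 'objval': obj}, open(%s, 'w'))", deparse(fout)),
    sep = "\n")
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) stop("scipy oracle failed: ", paste(res, collapse = "\n"))
  jsonlite::fromJSON(fout)
}
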