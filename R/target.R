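#' Target flux regions and LP-based cut-set checks
#'
#' A target region is T = { v in E : A v >= b }, where E is the feasible cone
#' (steady state plus bounds). A gene set G is a genetic cut set (gCS) for T
#' exactly when the LP
#'   max 0  s.t.  S v = 0, l <= v <= u (blocked reactions fixed to 0), A v >= b
#' is infeasible. The objective is identically zero: any linear objective is
#' permitted for the feasibility characterization, and a zero objective
#' avoids unboundedness and is cheapest.
#'
#' @name target
NULL

#' Maximal biomass flux of a model
#'
#' Optimum of `max v_biomass` over the feasible cone. Errors (naming the
#' condition) if the model is infeasible or the optimum unbounded.
#'
#' @param model a `metabolic_model` with a biomass reaction set.
#' @return numeric flux value.
#' @export
max_biomass <- function(model) {
  if (is.na(model$biomass_reaction)) {
    stop("max_biomass: model has no biomass reaction", call. = FALSE)
  }
  n <- length(model$reactions)
  obj <- numeric(n)
  obj[match(model$biomass_reaction, model$reactions)] <- 1
  res <- lp_solve(obj, Aeq = as.matrix(model$S), beq = rep(0, nrow(model$S)),
                  lb = model$lb, ub = model$ub)
  if (res$status != "optimal") {
    stop(sprintf("max_biomass: model LP is %s", res$status), call. = FALSE)
  }
  res$objval
}

#' Build a target region
#'
#' `build_lethality_target()` constrains the biomass flux to at least
#' `p * biomass_max` (all nontrivially growing modes): its gMCSs are
#' essential genes (length 1) and synthetic-lethal sets (longer).
#' `build_coupling_target()` additionally forces the product reaction's flux
#' to zero (encoded as the two rows `v_r >= 0` and `-v_r >= 0`, keeping every
#' target uniformly of the form `A v >= b`): its gMCSs are interventions that
#' eliminate growth-without-production. The maximal biomass is computed once
#' on the wild-type model and cached; the threshold `p * biomass_max` is
#' never recomputed after knockouts. Construction fails loudly if the
#' wild-type target LP is infeasible.
#'
#' @param model a `metabolic_model`.
#' @param p biomass fraction in (0, 1], default 0.01.
#' @param name label for the target.
#' @param biomass_max optional precomputed maximal biomass flux.
#' @return an object of class `target_spec` with fields `model`, `A`, `b`,
#'   `name`, `p`, `biomass_max`.
#' @export
build_lethality_target <- function(model, p = 0.01, name = "lethality",
                                   biomass_max = NULL) {
  stopifnot(p > 0, p <= 1)
  if (is.null(biomass_max)) biomass_max <- max_biomass(model)
  if (biomass_max <= 0) {
    stop("build_lethality_target: maximal biomass is 0 (no growth to block)",
         call. = FALSE)
  }
  n <- length(model$reactions)
  A <- matrix(0, 1, n)
  A[1, match(model$biomass_reaction, model$reactions)] <- 1
  b <- p * biomass_max
  new_target_spec(model, A, b, name, p, biomass_max)
}

#' @param product_reaction id of the bioproduct exchange reaction whose
#'   growth-coupling is sought.
#' @rdname build_lethality_target
#' @export
build_coupling_target <- function(model, product_reaction, p = 0.01,
                                  name = NULL, biomass_max = NULL) {
  stopifnot(p > 0, p <= 1)
  if (!(product_reaction %in% model$reactions)) {
    stop(sprintf("build_coupling_target: product reaction '%s' not in model",
                 product_reaction), call. = FALSE)
  }
  if (is.null(biomass_max)) biomass_max <- max_biomass(model)
  if (biomass_max <= 0) {
    stop("build_coupling_target: maximal biomass is 0", call. = FALSE)
  }
  n <- length(model$reactions)
  A <- matrix(0, 3, n)
  A[1, match(model$biomass_reaction, model$reactions)] <- 1
  ridx <- match(product_reaction, model$reactions)
  A[2, ridx] <- 1
  A[3, ridx] <- -1
  b <- c(p * biomass_max, 0, 0)
  if (is.null(name)) name <- paste0("couple:", product_reaction)
  new_target_spec(model, A, b, name, p, biomass_max)
}

new_target_spec <- function(model, A, b, name, p, biomass_max) {
  spec <- structure(list(model = model, A = A, b = b, name = name,
                         p = p, biomass_max = biomass_max),
                    class = "target_spec")
  res <- target_lp(spec, character(0))
  if (res$status != "optimal") {
    stop(sprintf("target '%s': wild-type target LP is %s (empty target region)",
                 name, res$status), call. = FALSE)
  }
  spec
}

#' @exportS3Method base::print
print.target_spec <- function(x, ...) {
  cat(sprintf("<target_spec '%s': %d extra row(s), p=%g, biomass_max=%g>\n",
              x$name, nrow(x$A), x$p, x$biomass_max))
  invisible(x)
}

#' Reactions disabled by a gene knockout
#'
#' Exactly the reactions whose GPR evaluates to FALSE with the genes of `G`
#' knocked out; reactions without genetic support are never blocked.
#'
#' @param model a `metabolic_model`.
#' @param G character vector of gene ids (must all be model genes).
#' @return character vector of reaction ids.
#' @export
blocked_reactions <- function(model, G) {
  G <- as.character(G)
  unknown <- setdiff(G, model$genes)
  if (length(unknown) > 0) {
    stop(sprintf("blocked_reactions: unknown gene(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  ok <- vapply(model$gpr, evaluate_gpr, NA, knocked = G)
  model$reactions[!ok]
}

# the Proposition-1 feasibility LP under knockout G, zero objective
target_lp <- function(spec, G, obj = NULL) {
  model <- spec$model
  lb <- model$lb; ub <- model$ub
  blocked <- blocked_reactions(model, G)
  lb[blocked] <- 0; ub[blocked] <- 0
  n <- length(model$reactions)
  if (is.null(obj)) obj <- numeric(n)
  lp_solve(obj, Aeq = as.matrix(model$S), beq = rep(0, nrow(model$S)),
           Aineq = spec$A, bineq = spec$b, lb = lb, ub = ub)
}

#' Is a gene set a genetic cut set for a target?
#'
#' TRUE iff the knockout feasibility LP over the target region is
#' infeasible. Any solver status other than optimal/infeasible raises an
#' error carrying the status — never a silent boolean.
#'
#' @param target a `target_spec`.
#' @param G character vector of gene ids.
#' @return logical.
#' @export
is_gcs <- function(target, G) {
  res <- target_lp(target, G)
  if (res$status == "infeasible") return(TRUE)
  if (res$status == "optimal") return(FALSE)
  stop(sprintf("is_gcs: solver returned status '%s'", res$status), call. = FALSE)
}

#' Witness mode of a surviving knockout
#'
#' If `G` is not a cut set for the target, returns a feasible flux vector of
#' the knockout LP as a mode: its support is extracted at tolerance
#' `tol_supp` (fluxes are floating point, so the nonzero-support definition
#' needs a numeric threshold — comfortably above LP feasibility tolerance,
#' below meaningful flux scale). Returns `NULL` iff `G` is a cut set.
#'
#' @param target a `target_spec`.
#' @param G character vector of gene ids.
#' @param tol_supp support tolerance (default 1e-6).
#' @return `NULL`, or a list with `support` (character) and `flux` (named
#'   numeric), of class `flux_mode`.
#' @export
find_witness <- function(target, G, tol_supp = 1e-6) {
  res <- target_lp(target, G)
  if (res$status == "infeasible") return(NULL)
  if (res$status != "optimal") {
    stop(sprintf("find_witness: solver returned status '%s'", res$status),
         call. = FALSE)
  }
  flux <- setNames(res$x, target$model$reactions)
  support <- names(flux)[abs(flux) > tol_supp]
  structure(list(support = support, flux = flux), class = "flux_mode")
}

#' Classify a coupling-target intervention
#'
#' A confirmed gMCS of a coupling target either blocks growth outright or
#' enforces production whenever growth exceeds the threshold. The class is
#' decided by maximizing biomass under the knockout over the feasible cone:
#' `"biomass-blocking"` if the optimum falls below `p * biomass_max`, else
#' `"coupling-enforcing"` (the class of engineering interest).
#'
#' @param model a `metabolic_model`.
#' @param G gene set (character).
#' @param p biomass fraction.
#' @param biomass_max wild-type maximal biomass (computed if missing).
#' @return `"biomass-blocking"` or `"coupling-enforcing"`.
#' @export
classify_intervention <- function(model, G, p = 0.01, biomass_max = NULL) {
  if (is.null(biomass_max)) biomass_max <- max_biomass(model)
  lb <- model$lb; ub <- model$ub
  blocked <- blocked_reactions(model, G)
  lb[blocked] <- 0; ub[blocked] <- 0
  n <- length(model$reactions)
  obj <- numeric(n)
  obj[match(model$biomass_reaction, model$reactions)] <- 1
  res <- lp_solve(obj, Aeq = as.matrix(model$S), beq = rep(0, nrow(model$S)),
                  lb = lb, ub = ub)
  growth <- if (res$status == "infeasible") 0 else if (res$status == "optimal") {
    res$objval
  } else {
    stop(sprintf("classify_intervention: solver status '%s'", res$status),
         call. = FALSE)
  }
  if (growth < p * biomass_max) "biomass-blocking" else "coupling-enforcing"
}

#' Witness oracles
#'
#' The enumeration driver talks to a target only through a witness oracle:
#' `is_gcs(G)` decides the cut-set property and `find_witness(G)` produces a
#' surviving mode when the answer is no (and `NULL` when it is yes).
#' `lp_oracle()` backs the contract with the feasibility LP of a
#' `target_spec`; `enumerated_oracle()` backs it with an explicit list of
#' mode supports (as in the worked example, where the target region is given
#' by three supports). The `order` argument of the enumerated oracle permutes
#' the scan order used by `find_witness`, which exercises the driver's
#' witness-order robustness.
#'
#' @param target a `target_spec`.
#' @param tol_supp support tolerance for LP witnesses.
#' @return an object of class `witness_oracle`: a list with functions
#'   `is_gcs(G)`, `find_witness(G)` (returning a `flux_mode` or `NULL`),
#'   `mode_family(support, k)`, plus `genes` and `name`.
#' @export
lp_oracle <- function(target, tol_supp = 1e-6) {
  families_cache <- new.env(parent = emptyenv())
  get_families <- function(k) {
    key <- if (is.null(k)) "uncapped" else as.character(k)
    if (is.null(families_cache[[key]])) {
      families_cache[[key]] <- model_reaction_families(target$model, k = k)
    }
    families_cache[[key]]
  }
  structure(list(
    is_gcs = function(G) is_gcs(target, G),
    find_witness = function(G) find_witness(target, G, tol_supp = tol_supp),
    mode_family = function(support, k = NULL) {
      mode_gmcs(support, get_families(k), k = k)
    },
    genes = target$model$genes,
    name = target$name
  ), class = "witness_oracle")
}

#' @param supports list of character vectors: the target's mode supports.
#' @param reaction_families named list of `gene_set_family` covering every
#'   reaction appearing in the supports.
#' @param genes character vector of gene ids.
#' @param name target label.
#' @param order permutation of `seq_along(supports)` controlling the witness
#'   scan order.
#' @rdname lp_oracle
#' @export
enumerated_oracle <- function(supports, reaction_families, genes,
                              name = "enumerated", order = seq_along(supports)) {
  stopifnot(length(order) == length(supports),
            setequal(order, seq_along(supports)))
  full <- lapply(supports, mode_gmcs, reaction_families = reaction_families)
  structure(list(
    is_gcs = function(G) {
      all(vapply(full, function(f) is_cutset_for_mode(G, f), NA))
    },
    find_witness = function(G) {
      for (i in order) {
        if (!is_cutset_for_mode(G, full[[i]])) {
          return(structure(list(support = supports[[i]], flux = NULL),
                           class = "flux_mode"))
        }
      }
      NULL
    },
    mode_family = function(support, k = NULL) {
      mode_gmcs(support, reaction_families, k = k)
    },
    genes = genes,
    name = name
  ), class = "witness_oracle")
}
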