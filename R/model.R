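#' Constraint-based metabolic model container
#'
#' Holds the data of a genome-scale model needed for cut-set analysis: the
#' stoichiometric matrix over *internal* metabolites only (boundary species
#' are dropped), per-reaction flux bounds, parsed gene-protein rules, and the
#' biomass (objective) reaction. Flux units are whatever the source model
#' declares (typically mmol/gDW/h) and are treated as opaque. Irreversibility
#' is encoded purely through `lb >= 0`.
#'
#' @param id model identifier.
#' @param metabolites character vector of internal metabolite ids (rows of S).
#' @param reactions character vector of reaction ids (columns of S).
#' @param S stoichiometric matrix, m x n (coerced to sparse).
#' @param lb,ub numeric bounds per reaction; must satisfy `lb <= ub`.
#' @param gpr_strings named character vector (reaction -> rule string); absent
#'   or empty entries mean no genetic support.
#' @param genes character vector of gene ids; defaults to the union of genes
#'   mentioned by the rules.
#' @param biomass_reaction id of the biomass/objective reaction (or `NA`).
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, S, lb, ub,
                            gpr_strings = character(0), genes = NULL,
                            biomass_reaction = NA_character_) {
  reactions <- as.character(reactions)
  metabolites <- as.character(metabolites)
  n <- length(reactions)
  S <- Matrix::Matrix(S, sparse = TRUE)
  stopifnot(nrow(S) == length(metabolites), ncol(S) == n,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub)) stop("metabolic_model: lb > ub for some reaction", call. = FALSE)
  full <- setNames(rep("", n), reactions)
  if (length(gpr_strings) > 0) {
    unknown <- setdiff(names(gpr_strings), reactions)
    if (length(unknown) > 0) {
      stop(sprintf("metabolic_model: GPR for unknown reaction(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    gpr_strings[is.na(gpr_strings)] <- ""
    full[names(gpr_strings)] <- gpr_strings
  }
  gpr <- lapply(full, parse_gpr)
  mentioned <- sort(unique(unlist(lapply(gpr, gpr_genes))))
  if (is.null(genes)) genes <- mentioned
  genes <- as.character(genes)
  if (!all(mentioned %in% genes)) {
    stop("metabolic_model: GPRs mention genes absent from the gene list",
         call. = FALSE)
  }
  if (!is.na(biomass_reaction) && !(biomass_reaction %in% reactions)) {
    stop(sprintf("metabolic_model: biomass reaction '%s' not in model",
                 biomass_reaction), call. = FALSE)
  }
  structure(list(
    id = id, metabolites = metabolites, reactions = reactions, S = S,
    lb = setNames(as.numeric(lb), reactions),
    ub = setNames(as.numeric(ub), reactions),
    gpr = gpr, gpr_strings = full, genes = genes,
    biomass_reaction = biomass_reaction
  ), class = "metabolic_model")
}

#' @exportS3Method base::print
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d metabolites, %d reactions, %d genes>\n",
              x$id, length(x$metabolites), length(x$reactions), length(x$genes)))
  if (!is.na(x$biomass_reaction)) cat("  biomass:", x$biomass_reaction, "\n")
  invisible(x)
}

#' Per-reaction gene cut-set families of a model
#'
#' Applies [reaction_gmcs()] to every reaction's rule.
#' @param model a `metabolic_model`.
#' @param k optional cardinality cap.
#' @return named list of `gene_set_family`.
#' @export
model_reaction_families <- function(model, k = NULL) {
  lapply(model$gpr, reaction_gmcs, k = k)
}

#' Read a metabolic model from SBML (fbc) or COBRA JSON
#'
#' `format = "auto"` decides by extension (`.xml`/`.sbml` vs `.json`). SBML
#' species flagged `boundaryCondition="true"` (or, when
#' `boundary_suffix` is given, whose id/compartment matches that suffix) are
#' excluded from the stoichiometric rows. The declared fbc objective is taken
#' as the biomass reaction; `biomass` overrides it.
#'
#' @param path model file.
#' @param format `"sbml"`, `"cobra-json"`, or `"auto"`.
#' @param biomass optional reaction id overriding the declared objective.
#' @param boundary_suffix optional regex; SBML species whose compartment
#'   matches are treated as boundary (e.g. `"^e$"` for an extracellular
#'   compartment convention).
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "sbml", "cobra-json"),
                       biomass = NULL, boundary_suffix = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("read_model: no such file: %s", path),
                               call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml"
              else if (ext == "json") "cobra-json"
              else stop(sprintf("read_model: cannot infer format of '%s'", path),
                        call. = FALSE)
  }
  model <- switch(format,
    "cobra-json" = read_cobra_json(path),
    "sbml" = read_sbml_fbc(path, boundary_suffix = boundary_suffix)
  )
  if (!is.null(biomass)) {
    if (!(biomass %in% model$reactions)) {
      stop(sprintf("read_model: biomass override '%s' not in model", biomass),
           call. = FALSE)
    }
    model$biomass_reaction <- biomass
  }
  model
}

read_cobra_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  met_ids <- vapply(j$metabolites, function(m) m$id, "")
  rxn_ids <- vapply(j$reactions, function(r) r$id, "")
  n <- length(rxn_ids); m <- length(met_ids)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lb <- numeric(n); ub <- numeric(n); gprs <- character(n)
  obj <- numeric(n)
  midx <- setNames(seq_len(m), met_ids)
  for (ri in seq_len(n)) {
    r <- j$reactions[[ri]]
    st <- r$metabolites
    if (length(st) > 0) {
      rows <- midx[names(st)]
      if (anyNA(rows)) {
        stop(sprintf("read_model: reaction '%s' references unknown metabolite",
                     r$id), call. = FALSE)
      }
      ii <- c(ii, unname(rows)); jj <- c(jj, rep(ri, length(st)))
      xx <- c(xx, vapply(st, as.numeric, 0))
    }
    lb[ri] <- if (is.null(r$lower_bound)) -1000 else as.numeric(r$lower_bound)
    ub[ri] <- if (is.null(r$upper_bound)) 1000 else as.numeric(r$upper_bound)
    gprs[ri] <- if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule
    obj[ri] <- if (is.null(r$objective_coefficient)) 0
               else as.numeric(r$objective_coefficient)
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n))
  genes <- if (length(j$genes) > 0) vapply(j$genes, function(g) g$id, "") else NULL
  biomass <- if (any(obj != 0)) rxn_ids[which(obj != 0)[1]] else NA_character_
  metabolic_model(id = if (is.null(j$id)) basename(path) else j$id,
                  metabolites = met_ids, reactions = rxn_ids, S = S,
                  lb = lb, ub = ub,
                  gpr_strings = setNames(gprs, rxn_ids),
                  genes = genes, biomass_reaction = biomass)
}

# parse an fbc:geneProductAssociation subtree into a GPR string
sbml_gpa_to_string <- function(node, gp_labels) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lab <- gp_labels[[ref]]
    return(if (is.null(lab)) ref else lab)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, sbml_gpa_to_string, "", gp_labels = gp_labels)
  op <- switch(nm, "and" = " and ", "or" = " or ",
               stop(sprintf("read_model: unsupported association node <%s>", nm),
                    call. = FALSE))
  paste0("(", paste(parts, collapse = op), ")")
}

read_sbml_fbc <- function(path, boundary_suffix = NULL) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) {
    stop("read_model: not an SBML level-3 file", call. = FALSE)
  }
  # global flux-bound parameters
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))
  # gene products: label used in rules (falls back to id)
  gps <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_ids <- xml2::xml_attr(gps, "fbc:id", ns = ns)
  gp_lab <- xml2::xml_attr(gps, "fbc:label", ns = ns)
  gp_lab[is.na(gp_lab)] <- gp_ids[is.na(gp_lab)]
  gp_labels <- as.list(setNames(gp_lab, gp_ids))

  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_ids <- xml2::xml_attr(species, "id")
  sp_bc <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  if (!is.null(boundary_suffix)) {
    comp <- xml2::xml_attr(species, "compartment")
    sp_bc <- sp_bc | grepl(boundary_suffix, comp)
  }
  internal <- sp_ids[!sp_bc]
  midx <- setNames(seq_along(internal), internal)

  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxn_ids <- xml2::xml_attr(rxns, "id")
  n <- length(rxn_ids)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lb <- numeric(n); ub <- numeric(n); gprs <- character(n)
  for (ri in seq_len(n)) {
    rx <- rxns[[ri]]
    lbp <- xml2::xml_attr(rx, "fbc:lowerFluxBound", ns = ns)
    ubp <- xml2::xml_attr(rx, "fbc:upperFluxBound", ns = ns)
    rev <- xml2::xml_attr(rx, "reversible") %in% "true"
    lb[ri] <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]]
              else if (rev) -1000 else 0
    ub[ri] <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
    add_side <- function(xpath, sign) {
      refs <- xml2::xml_find_all(rx, xpath, ns)
      for (sr in refs) {
        sp <- xml2::xml_attr(sr, "species")
        if (!(sp %in% internal)) next  # boundary species: no row
        st <- xml2::xml_attr(sr, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        ii <<- c(ii, midx[[sp]]); jj <<- c(jj, ri); xx <<- c(xx, sign * st)
      }
    }
    add_side("./s:listOfReactants/s:speciesReference", -1)
    add_side("./s:listOfProducts/s:speciesReference", +1)
    gpa <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation", ns)
    gprs[ri] <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_children(gpa)
      if (length(kids) == 0) "" else sbml_gpa_to_string(kids[[1]], gp_labels)
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(internal), n))
  # declared objective
  objflux <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  biomass <- if (inherits(objflux, "xml_missing")) NA_character_
             else xml2::xml_attr(objflux, "fbc:reaction", ns = ns)
  genes <- sort(unique(unname(gp_lab)))
  nonempty <- nzchar(gprs)
  if (length(gps) == 0 && any(nonempty)) {
    warning("read_model: SBML has GPR associations but no fbc gene products; ",
            "parsing raw reference strings", call. = FALSE)
    genes <- NULL
  }
  metabolic_model(id = xml2::xml_attr(model_node, "id"),
                  metabolites = internal, reactions = rxn_ids, S = S,
                  lb = lb, ub = ub, gpr_strings = setNames(gprs, rxn_ids),
                  genes = if (length(genes) > 0) genes else NULL,
                  biomass_reaction = biomass)
}

#' Close or rebound exchange reactions (medium definition)
#'
#' With a plain character vector, the listed reactions are closed (bounds set
#' to `[0, 0]`). With a data frame of columns `reaction`, `lb`, `ub` (the
#' two-column-plus-id medium TSV), bounds are assigned directly.
#'
#' @param model a `metabolic_model`.
#' @param closed_exchanges character vector of reaction ids to close, or a
#'   data frame `reaction`/`lb`/`ub`.
#' @return the modified model.
#' @export
apply_medium <- function(model, closed_exchanges) {
  if (is.data.frame(closed_exchanges)) {
    stopifnot(all(c("reaction", "lb", "ub") %in% names(closed_exchanges)))
    ids <- as.character(closed_exchanges$reaction)
    unknown <- setdiff(ids, model$reactions)
    if (length(unknown) > 0) {
      stop(sprintf("apply_medium: unknown reaction(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    model$lb[ids] <- as.numeric(closed_exchanges$lb)
    model$ub[ids] <- as.numeric(closed_exchanges$ub)
    return(model)
  }
  ids <- as.character(closed_exchanges)
  unknown <- setdiff(ids, model$reactions)
  if (length(unknown) > 0) {
    stop(sprintf("apply_medium: unknown reaction(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  model$lb[ids] <- 0
  model$ub[ids] <- 0
  model
}

#' Read a medium file (TSV: reaction id, lower bound, upper bound)
#' @param path file path.
#' @return data frame with columns `reaction`, `lb`, `ub`.
#' @export
read_medium <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("reaction", "lb", "ub"),
                          stringsAsFactors = FALSE)
  df
}

#' The ten-reaction worked-example fixture
#'
#' The textbook toy used throughout the package's tests: ten reactions
#' r0..r9 with rules r0:g0, r1:g1, r2:g1, r3:g2, r4:g3, r5:g4, r6:g4,
#' r7:`g0 and (g5 or g6 or g7)`, r8:g8, r9:`(g1 and g2) or (g3 and g4)`, and
#' a target region given explicitly by three mode supports
#' {r0,r1,r4,r7}, {r0,r2,r5,r7}, {r0,r3,r6,r7}. The source text describes the
#' network as "5 metabolites, 8 reactions, and 9 genes" yet tabulates ten
#' rules; the fixture carries all ten. Its accompanying figure (the
#' stoichiometry) is not available, so the target region is represented by
#' the explicit supports rather than by a stoichiometric matrix — the
#' hitting-set and driver layers accept explicit supports.
#'
#' @return list with `reaction_families` (named list of `gene_set_family`
#'   computed from the rules), `supports` (list of 3 character vectors),
#'   `gpr_strings`, and `genes`.
#' @export
toy_fixture <- function() {
  gpr_strings <- c(
    r0 = "g0", r1 = "g1", r2 = "g1", r3 = "g2", r4 = "g3",
    r5 = "g4", r6 = "g4", r7 = "g0 and (g5 or g6 or g7)",
    r8 = "g8", r9 = "(g1 and g2) or (g3 and g4)"
  )
  fams <- lapply(gpr_strings, function(s) reaction_gmcs(parse_gpr(s)))
  supports <- list(c("r0", "r1", "r4", "r7"),
                   c("r0", "r2", "r5", "r7"),
                   c("r0", "r3", "r6", "r7"))
  list(reaction_families = fams, supports = supports,
       gpr_strings = gpr_strings,
       genes = paste0("g", 0:8))
}
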