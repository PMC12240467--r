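#' Catalogs of genetic minimal cut sets
#'
#' A `gmcs_catalog` holds all confirmed gMCSs of a target up to a length cap,
#' indexed by cardinality, globally reduced (no member contains another), and
#' canonically ordered. Each entry carries a classification: `"lethal"` for
#' lethality targets, `"biomass-blocking"` or `"coupling-enforcing"` for
#' coupling targets.
#'
#' @param by_cardinality named list (`"1"`, `"2"`, ...) of `gene_set_family`.
#' @param target target label.
#' @param k_max cardinality cap of the enumeration.
#' @param classification named character vector keyed by canonical set key;
#'   defaults to `"lethal"` for every entry.
#' @return an object of class `gmcs_catalog`.
#' @export
gmcs_catalog <- function(by_cardinality, target, k_max,
                         classification = NULL) {
  all_members <- unlist(lapply(by_cardinality, function(f) f$members),
                        recursive = FALSE)
  if (is.null(all_members)) all_members <- list()
  red <- reduce_members(all_members)
  if (length(red) != length(all_members)) {
    stop("gmcs_catalog: catalog is not globally reduced", call. = FALSE)
  }
  if (is.null(classification)) {
    classification <- setNames(rep("lethal", length(all_members)),
                               vapply(all_members, set_key, ""))
  }
  structure(list(by_cardinality = by_cardinality, target = target,
                 k_max = k_max, classification = classification),
            class = "gmcs_catalog")
}

#' @exportS3Method base::print
print.gmcs_catalog <- function(x, ...) {
  total <- sum(vapply(x$by_cardinality, length, 0L))
  cat(sprintf("<gmcs_catalog '%s': %d gMCS(s), k_max=%d>\n",
              x$target, total, x$k_max))
  for (k in names(x$by_cardinality)) {
    fam <- x$by_cardinality[[k]]
    if (length(fam) == 0L) next
    cat(sprintf("  length %s: %d\n", k, length(fam)))
    for (g in fam$members) cat("    {", paste(g, collapse = ", "), "}\n")
  }
  invisible(x)
}

#' All catalog members as a flat list
#' @param catalog a `gmcs_catalog`.
#' @return list of character vectors, in cardinality then canonical order.
#' @export
catalog_sets <- function(catalog) {
  out <- unlist(lapply(catalog$by_cardinality, function(f) f$members),
                recursive = FALSE)
  if (is.null(out)) list() else unname(out)
}

#' Per-cardinality counts of a catalog
#' @param catalog a `gmcs_catalog`.
#' @return data frame with columns `k` and `n_gmcs`.
#' @export
catalog_summary <- function(catalog) {
  data.frame(k = as.integer(names(catalog$by_cardinality)),
             n_gmcs = vapply(catalog$by_cardinality, length, 0L),
             row.names = NULL)
}

catalog_records <- function(catalog) {
  sets <- catalog_sets(catalog)
  if (length(sets) == 0L) {
    return(data.frame(cardinality = integer(0), genes = character(0),
                      target = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  keys <- vapply(sets, set_key, "")
  data.frame(
    cardinality = lengths(sets),
    genes = vapply(sets, function(g) paste(g, collapse = ","), ""),
    target = catalog$target,
    class = unname(catalog$classification[keys]),
    stringsAsFactors = FALSE
  )
}

#' Write / read a catalog (TSV or JSON)
#'
#' TSV: one record per gMCS with columns `cardinality`, `genes`
#' (comma-separated, sorted), `target`, `class`; deterministic row order.
#' JSON round-trips losslessly through `read_catalog()`.
#'
#' @param catalog a `gmcs_catalog`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return the path, invisibly; `read_catalog` returns a `gmcs_catalog`.
#' @export
write_catalog <- function(catalog, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rec <- catalog_records(catalog)
  if (format == "tsv") {
    utils::write.table(rec, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    payload <- list(
      target = catalog$target,
      k_max = catalog$k_max,
      gmcs = lapply(seq_len(nrow(rec)), function(i) {
        list(cardinality = rec$cardinality[i],
             genes = strsplit(rec$genes[i], ",", fixed = TRUE)[[1]],
             class = rec$class[i])
      })
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  if (format == "tsv") {
    rec <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = c("integer", "character",
                                            "character", "character"))
    sets <- strsplit(rec$genes, ",", fixed = TRUE)
    target <- if (nrow(rec) > 0) rec$target[1] else "unknown"
    k_max <- if (nrow(rec) > 0) max(rec$cardinality) else 1L
    classes <- rec$class
  } else {
    j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    sets <- lapply(j$gmcs, function(r) unlist(r$genes))
    target <- j$target
    k_max <- j$k_max
    classes <- vapply(j$gmcs, function(r) r$class, "")
  }
  by_card <- list()
  for (k in seq_len(max(k_max, 1L))) {
    by_card[[as.character(k)]] <- gene_set_family(sets[lengths(sets) == k])
  }
  cls <- setNames(classes, vapply(lapply(sets, sort), set_key, ""))
  gmcs_catalog(by_card, target = target, k_max = as.integer(k_max),
               classification = cls)
}
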