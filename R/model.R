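# Stoichiometric metabolic model container and native JSON / SBML readers.

#' Construct a stoichiometric metabolic model
#'
#' The container used by all constraint-based operations: a sparse
#' stoichiometric matrix (metabolites x reactions), per-reaction flux bounds
#' (mmol/gDW/h, nominal), boolean gene-protein-reaction rules, a biomass
#' objective reaction and exchange flags. Invariants are checked on
#' construction; readers reject invariant-violating inputs rather than
#' repairing them.
#'
#' @param metabolite_ids character vector of metabolite identifiers.
#' @param reaction_ids character vector of reaction identifiers.
#' @param S stoichiometry, coercible to a sparse matrix with
#'   \code{length(metabolite_ids)} rows and \code{length(reaction_ids)} columns.
#' @param lb,ub numeric per-reaction flux bounds; \code{lb <= ub} everywhere.
#' @param gpr character per-reaction GPR expressions (\code{""} for none).
#' @param objective id of the objective (biomass) reaction.
#' @param exchange logical per-reaction exchange flag.
#' @return An object of class \code{stoich_model}.
#' @seealso [read_model()], [fba()], [delete_genes()]
#' @export
stoich_model <- function(metabolite_ids, reaction_ids, S, lb, ub,
                         gpr = rep("", length(reaction_ids)),
                         objective, exchange = rep(FALSE, length(reaction_ids))) {
  m <- length(metabolite_ids); n <- length(reaction_ids)
  S <- Matrix::Matrix(S, sparse = TRUE)
  if (nrow(S) != m || ncol(S) != n)
    stop("stoichiometry must be ", m, " metabolites x ", n, " reactions")
  if (anyDuplicated(metabolite_ids)) stop("duplicate metabolite ids")
  if (anyDuplicated(reaction_ids)) stop("duplicate reaction ids")
  if (length(lb) != n || length(ub) != n || length(gpr) != n || length(exchange) != n)
    stop("lb, ub, gpr and exchange must have one entry per reaction")
  if (!all(is.finite(lb)) || !all(is.finite(ub) | ub == Inf))
    stop("flux bounds must be finite (upper bounds may be +Inf)")
  bad <- which(lb > ub)
  if (length(bad))
    stop("lower_bound > upper_bound for reaction '", reaction_ids[bad[1]], "'")
  if (length(objective) != 1L || !objective %in% reaction_ids)
    stop("objective reaction '", objective, "' is not in the model")
  gpr[is.na(gpr)] <- ""
  ast <- lapply(gpr, parse_gpr)  # errors name the offending rule
  genes <- sort(unique(unlist(lapply(ast, gpr_ast_genes))))
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  structure(list(
    metabolite_ids = as.character(metabolite_ids),
    reaction_ids = as.character(reaction_ids),
    S = S,
    lb = as.numeric(lb), ub = as.numeric(ub),
    gpr = as.character(gpr), gpr_ast = ast,
    objective = objective,
    exchange = as.logical(exchange),
    genes = genes
  ), class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("stoich_model:", length(x$metabolite_ids), "metabolites,",
      length(x$reaction_ids), "reactions,", length(x$genes), "genes\n")
  cat("objective:", x$objective,
      " exchanges:", sum(x$exchange), "\n")
  invisible(x)
}

#' Model gene set
#' @param model a \code{stoich_model}.
#' @return character vector of all gene identifiers appearing in GPR rules.
#' @export
model_genes <- function(model) model$genes

#' Read a metabolic model
#'
#' Reads the native JSON interchange format (authoritative) or an SBML Level 3
#' file with the \code{fbc} package (read-only ingestion). The native schema is
#' \code{{"metabolites": [...], "reactions": [{"id", "stoich": {met: coef},
#' "lb", "ub", "gpr", "exchange"}], "objective": "rxn_id"}}.
#'
#' @param path file path.
#' @param format \code{"json"} or \code{"sbml"}.
#' @return a \code{stoich_model}.
#' @export
read_model <- function(path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  for (field in c("metabolites", "reactions", "objective"))
    if (is.null(doc[[field]])) stop("model JSON is missing the '", field, "' field")
  mets <- as.character(doc$metabolites)
  rxns <- doc$reactions
  ids <- vapply(rxns, function(r) {
    if (is.null(r$id)) stop("model JSON: reaction without an 'id'")
    as.character(r$id)
  }, character(1))
  n <- length(ids)
  S <- Matrix::Matrix(0, length(mets), n, sparse = TRUE)
  for (j in seq_len(n)) {
    st <- rxns[[j]]$stoich
    if (length(st)) {
      unknown <- setdiff(names(st), mets)
      if (length(unknown))
        stop("reaction '", ids[j], "' references unknown metabolite '",
             unknown[1], "'")
      S[match(names(st), mets), j] <- as.numeric(unlist(st))
    }
  }
  num_field <- function(field, default = NULL) vapply(rxns, function(r) {
    v <- r[[field]]
    if (is.null(v)) {
      if (is.null(default)) stop("reaction '", r$id, "' is missing '", field, "'")
      v <- default
    }
    as.numeric(v)
  }, numeric(1))
  lb <- num_field("lb"); ub <- num_field("ub")
  gpr <- vapply(rxns, function(r) {
    v <- r$gpr; if (is.null(v) || is.na(v)) "" else as.character(v)
  }, character(1))
  exch <- vapply(rxns, function(r) isTRUE(as.logical(r$exchange)), logical(1))
  stoich_model(mets, ids, S, lb, ub, gpr, as.character(doc$objective), exch)
}

#' Write a metabolic model to native JSON
#' @param model a \code{stoich_model}.
#' @param path output file path.
#' @export
write_model <- function(model, path) {
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    col <- model$S[, j]
    nz <- which(col != 0)
    st <- as.list(as.numeric(col[nz]))
    names(st) <- model$metabolite_ids[nz]
    list(id = model$reaction_ids[j], stoich = st,
         lb = model$lb[j], ub = model$ub[j],
         gpr = model$gpr[j], exchange = model$exchange[j])
  })
  doc <- list(metabolites = model$metabolite_ids, reactions = rxns,
              objective = model$objective)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# SBML L3 + fbc ingestion: species/reactions/speciesReferences map onto the
# native container; geneProductAssociation subtrees map onto GPR strings.
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(model_node, ns))) stop("not an SBML L3 document: ", path)

  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(species, "id")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  mets <- sp_id[!sp_boundary]

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  gp <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))

  gpa_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lab <- gp_label[[ref]]
      return(if (is.null(lab) || is.na(lab)) ref else lab)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_string, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  ids <- xml2::xml_attr(rxn_nodes, "id")
  n <- length(ids)
  S <- Matrix::Matrix(0, length(mets), n, sparse = TRUE)
  lb <- numeric(n); ub <- numeric(n); gpr <- character(n); exch <- logical(n)
  for (j in seq_len(n)) {
    node <- rxn_nodes[[j]]
    add_side <- function(xpath, sign) {
      refs <- xml2::xml_find_all(node, xpath, ns)
      for (r in refs) {
        sp <- xml2::xml_attr(r, "species")
        coef <- xml2::xml_attr(r, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        i <- match(sp, mets)
        if (!is.na(i)) S[i, j] <<- S[i, j] + sign * coef
      }
    }
    add_side(".//s:listOfReactants/s:speciesReference", -1)
    add_side(".//s:listOfProducts/s:speciesReference", +1)
    lbref <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns = ns)
    ubref <- xml2::xml_attr(node, "fbc:upperFluxBound", ns = ns)
    rev <- xml2::xml_attr(node, "reversible") %in% "true"
    lb[j] <- if (!is.na(lbref)) pval[[lbref]] else if (rev) -1000 else 0
    ub[j] <- if (!is.na(ubref)) pval[[ubref]] else 1000
    gpa <- xml2::xml_find_first(node, ".//fbc:geneProductAssociation", ns)
    gpr[j] <- if (!is.na(xml2::xml_name(gpa, ns))) {
      gpa_to_string(xml2::xml_children(gpa)[[1]])
    } else ""
    # exchange: reactions touching only boundary species on one side, or by
    # convention a single-metabolite column
    exch[j] <- sum(S[, j] != 0) <= 1
  }

  obj <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (is.na(xml2::xml_name(obj, ns)))
    stop("SBML file declares no flux objective (fbc:listOfObjectives)")
  objective <- xml2::xml_attr(obj, "fbc:reaction", ns = ns)

  stoich_model(mets, ids, S, lb, ub, gpr, objective, exch)
}
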