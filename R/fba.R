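# Flux balance analysis, flux variability analysis, GPR-aware gene deletion.

#' Flux balance analysis
#'
#' Maximises flux through the model's objective (biomass) reaction subject to
#' steady-state mass balance \eqn{S v = 0} and the per-reaction flux bounds.
#'
#' @param model a \code{stoich_model}.
#' @return an object of class \code{flux_result}: list with \code{status}
#'   (\code{"optimal"}, \code{"infeasible"} or \code{"unbounded"}),
#'   \code{objective} (growth rate, undefined unless optimal) and
#'   \code{fluxes} (named per-reaction vector). An infeasible constraint set
#'   yields \code{status = "infeasible"}, never an error.
#' @examples
#' m <- make_toy_model(1, 0, 0, seed = 1)
#' fba(m)$objective
#' @export
fba <- function(model) {
  stopifnot(inherits(model, "stoich_model"))
  n <- length(model$reaction_ids)
  obj <- numeric(n)
  obj[match(model$objective, model$reaction_ids)] <- 1
  res <- lp_solve(obj, A_eq = as.matrix(model$S), b_eq = rep(0, nrow(model$S)),
                  lb = model$lb, ub = model$ub, maximize = TRUE)
  fluxes <- res$x
  names(fluxes) <- model$reaction_ids
  structure(list(status = res$status,
                 objective = if (res$status == "optimal") res$objective else NA_real_,
                 fluxes = fluxes),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat("flux_result:", x$status)
  if (x$status == "optimal") cat(", objective =", format(x$objective, digits = 6))
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For every reaction, the minimum and maximum attainable steady-state flux,
#' optionally while holding the objective at a required fraction of its
#' optimum. At \code{fraction_of_optimum = 0} the ranges describe the full
#' attainable flux space; these ranges are the effective \eqn{V_{max}} /
#' \eqn{V_{min}} used when probabilistic regulatory constraints are built.
#'
#' @param model a \code{stoich_model}.
#' @param fraction_of_optimum number in [0, 1]; minimum required objective as
#'   a fraction of the FBA optimum.
#' @return an object of class \code{fva_result}: data.frame with columns
#'   \code{reaction}, \code{min}, \code{max}, plus the fraction used.
#' @export
fva <- function(model, fraction_of_optimum = 0) {
  stopifnot(inherits(model, "stoich_model"),
            fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  n <- length(model$reaction_ids)
  Aub <- NULL; bub <- NULL
  if (fraction_of_optimum > 0) {
    wt <- fba(model)
    if (wt$status != "optimal")
      stop("cannot run FVA at fraction > 0: FBA status is '", wt$status, "'")
    Aub <- matrix(0, 1, n)
    Aub[1, match(model$objective, model$reaction_ids)] <- -1
    bub <- -fraction_of_optimum * wt$objective
  }
  Seq <- as.matrix(model$S)
  beq <- rep(0, nrow(Seq))
  vmin <- numeric(n); vmax <- numeric(n)
  for (j in seq_len(n)) {
    obj <- numeric(n); obj[j] <- 1
    lo <- lp_solve(obj, A_eq = Seq, b_eq = beq, A_ub = Aub, b_ub = bub,
                   lb = model$lb, ub = model$ub, maximize = FALSE)
    hi <- lp_solve(obj, A_eq = Seq, b_eq = beq, A_ub = Aub, b_ub = bub,
                   lb = model$lb, ub = model$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem for reaction '", model$reaction_ids[j],
           "' is ", lo$status)
    vmin[j] <- lo$objective; vmax[j] <- hi$objective
  }
  # snap tiny numerical inversions
  vmin <- pmin(vmin, vmax)
  structure(data.frame(reaction = model$reaction_ids, min = vmin, max = vmax,
                       stringsAsFactors = FALSE),
            fraction_of_optimum = fraction_of_optimum,
            class = c("fva_result", "data.frame"))
}

#' Delete genes from a model
#'
#' Returns a copy of the model in which every reaction whose GPR rule
#' evaluates to 0 under the deletion (deleted genes OFF, all other genes ON)
#' has both flux bounds set to zero. Reactions with no GPR, or whose rule is
#' still satisfied (e.g. one member of an isozyme \code{or} pair), are
#' untouched.
#'
#' @param model a \code{stoich_model}.
#' @param genes character vector of gene ids; must be a subset of
#'   \code{model_genes(model)}.
#' @return a \code{stoich_model}.
#' @export
delete_genes <- function(model, genes) {
  stopifnot(inherits(model, "stoich_model"))
  genes <- unique(as.character(genes))
  unknown <- setdiff(genes, model$genes)
  if (length(unknown))
    stop("gene(s) not in model: ", paste(unknown, collapse = ", "))
  if (!length(genes)) return(model)
  states <- stats::setNames(as.list(rep(1, length(model$genes))), model$genes)
  states[genes] <- 0
  off <- vapply(model$gpr_ast, function(ast) {
    !is.null(ast) && eval_gpr_ast(ast, states, missing = "error") < 0.5
  }, logical(1))
  model$lb[off] <- 0
  model$ub[off] <- 0
  model
}
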