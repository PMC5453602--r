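# Integration of a TF influence network with a stoichiometric model:
# per-TF retention probabilities on genes, propagated through GPR rules onto
# reactions, applied as probability-scaled flux bounds (V_max * Prob) during
# TF-knockout simulation.

#' Retention probability of a target gene after TF deletion
#'
#' The probability that the target gene stays ON when the TF is deleted,
#' under one of three integration schemes. \code{IDREAM}: a direct activator
#' edge retains only its bootstrap FDR worth of activity, a direct repressor
#' edge retains \code{1 - FDR}, and indirect edges are unconstrained
#' (probability 1). \code{IDREAM_hybrid}: direct edges as IDREAM, indirect
#' edges fall back to the PROM conditional probability. \code{PROM}: every
#' edge uses the PROM conditional probability.
#'
#' @param edge a single edge: list or one-row data.frame with fields
#'   \code{tf}, \code{target}, \code{evidence}, \code{sign}, \code{fdr},
#'   \code{prom_prob}.
#' @param variant \code{"IDREAM"}, \code{"IDREAM_hybrid"} or \code{"PROM"}.
#' @return retention probability in [0, 1].
#' @examples
#' e <- list(tf = "TF1", target = "g1", evidence = "direct",
#'           sign = "activator", fdr = 0.045, prom_prob = NA)
#' gene_probability(e, "IDREAM")  # 0.045
#' @export
gene_probability <- function(edge, variant = c("IDREAM", "IDREAM_hybrid", "PROM")) {
  variant <- match.arg(variant)
  lab <- paste0(edge$tf, " -> ", edge$target)
  need_fdr <- function() {
    if (is.null(edge$fdr) || is.na(edge$fdr))
      stop("edge ", lab, " needs an FDR under the ", variant, " variant")
    edge$fdr
  }
  need_prom <- function() {
    if (is.null(edge$prom_prob) || is.na(edge$prom_prob))
      stop("edge ", lab, " needs a PROM conditional probability under the ",
           variant, " variant")
    edge$prom_prob
  }
  if (variant == "PROM") return(need_prom())
  if (edge$evidence == "indirect") {
    return(if (variant == "IDREAM") 1 else need_prom())
  }
  # direct edge under IDREAM / IDREAM_hybrid
  fdr <- need_fdr()
  switch(as.character(edge$sign),
         activator = fdr,
         repressor = 1 - fdr,
         stop("edge ", lab, " has unresolved sign '", edge$sign,
              "'; classify_sign it before integration"))
}

#' Propagate gene retention probabilities onto reactions
#'
#' Evaluates each reaction's GPR with gene probabilities in place of boolean
#' states: \code{and} takes the minimum (a complex is as available as its
#' scarcest subunit), \code{or} the maximum (isozymes back each other up).
#' Genes without an entry, and reactions without a GPR, count as probability 1.
#'
#' @param model a \code{stoich_model}.
#' @param gene_probs named numeric vector of retention probabilities in [0,1].
#' @return named numeric vector, one probability per reaction.
#' @export
map_gene_probs_to_reactions <- function(model, gene_probs) {
  if (length(gene_probs) && (any(gene_probs < 0) || any(gene_probs > 1)))
    stop("gene probabilities must lie in [0, 1]")
  vals <- as.list(gene_probs)
  probs <- vapply(model$gpr_ast, function(ast) {
    if (is.null(ast)) return(1)
    eval_gpr_ast(ast, vals, missing = "one")
  }, numeric(1))
  stats::setNames(probs, model$reaction_ids)
}

#' Fit an integrated regulatory-metabolic model
#'
#' Combines a stoichiometric metabolic model with a TF influence network into
#' a constraint map ready for TF-knockout simulation. For every TF, each
#' regulated gene receives a retention probability ([gene_probability()]
#' under the chosen variant), probabilities are propagated through GPR rules
#' onto reactions ([map_gene_probs_to_reactions()]), and simulating a TF
#' knockout scales the affected reactions' attainable flux ranges (from flux
#' variability analysis) by those probabilities.
#'
#' When the variant needs PROM conditional probabilities that the network
#' does not already carry, they are estimated from \code{expression} via
#' [binarize_expression()] and [conditional_probability()].
#'
#' @param model a \code{stoich_model} with a positive wild-type FBA optimum.
#' @param network an \code{influence_network}.
#' @param expression optional genes x samples matrix, required to estimate
#'   missing PROM probabilities.
#' @param variant integration scheme; see [gene_probability()].
#' @param mode \code{"soft"} (default): scaled bounds may be exceeded at a
#'   linear objective penalty; \code{"hard"}: scaled bounds are strict.
#' @param kappa soft-mode penalty weight per unit bound violation, expressed
#'   in wild-type-growth units per effective-Vmax unit (weight
#'   \code{kappa * growth_wt / |Vmax|}); large kappa converges to hard mode.
#' @param fraction_of_optimum FVA fraction used to derive effective Vmax
#'   (default 0: the attainable range without an optimality requirement).
#' @param binarize_quantile quantile for PROM binarization.
#' @param min_off_samples guard for PROM probability estimation.
#' @param fva_result optional precomputed [fva()] result for \code{model} at
#'   \code{fraction_of_optimum} (the FVA of a model does not depend on the
#'   network, so it can be shared across fits, e.g. in permutation tests).
#' @return an object of class \code{idream}; see [predict.idream()],
#'   [coef.idream()], [summary.idream()].
#' @examples
#' fx <- make_fixture(seed = 1, n_samples = 60)
#' net <- fx$network
#' net$fdr <- 0.02  # pretend-perfect inference for illustration
#' fit <- idream(fx$model, net, fx$expression, variant = "IDREAM")
#' predict(fit)
#' @export
idream <- function(model, network, expression = NULL,
                   variant = c("IDREAM", "IDREAM_hybrid", "PROM"),
                   mode = c("soft", "hard"), kappa = 10,
                   fraction_of_optimum = 0, binarize_quantile = 1/3,
                   min_off_samples = 5, fva_result = NULL) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  stopifnot(inherits(model, "stoich_model"),
            inherits(network, "influence_network"),
            kappa > 0)
  wt <- fba(model)
  if (wt$status != "optimal")
    stop("wild-type FBA is ", wt$status, "; cannot integrate")

  needs_prom <- switch(variant,
                       PROM = rep(TRUE, nrow(network)),
                       IDREAM_hybrid = network$evidence == "indirect",
                       IDREAM = rep(FALSE, nrow(network)))
  if (any(needs_prom & is.na(network$prom_prob))) {
    if (is.null(expression))
      stop("variant ", variant, " needs PROM conditional probabilities; ",
           "supply `expression` or a network with prom_prob")
    bin <- binarize_expression(expression, binarize_quantile)
    todo <- which(needs_prom & is.na(network$prom_prob))
    network$prom_prob[todo] <- vapply(todo, function(i) {
      conditional_probability(bin, network$tf[i], network$target[i],
                              min_off_samples = min_off_samples)
    }, numeric(1))
  }

  fv <- if (is.null(fva_result)) fva(model, fraction_of_optimum) else {
    stopifnot(inherits(fva_result, "fva_result"),
              identical(fva_result$reaction, model$reaction_ids))
    fva_result
  }
  tfs <- network_tfs(network)
  constraints <- lapply(tfs, function(tf) {
    ed <- network[network$tf == tf, , drop = FALSE]
    gene_probs <- vapply(seq_len(nrow(ed)), function(i)
      gene_probability(ed[i, ], variant), numeric(1))
    names(gene_probs) <- ed$target
    rxn_probs <- map_gene_probs_to_reactions(model, gene_probs)
    list(gene_probs = gene_probs,
         rxn_probs = rxn_probs[rxn_probs < 1])
  })
  names(constraints) <- tfs

  structure(list(model = model, network = network, variant = variant,
                 mode = mode, kappa = kappa,
                 fraction_of_optimum = fraction_of_optimum,
                 fva = fv, wildtype = wt, constraints = constraints,
                 call = match.call()),
            class = "idream")
}

#' @export
print.idream <- function(x, ...) {
  n_con <- sum(vapply(x$constraints, function(cc) length(cc$rxn_probs), 0L))
  cat("Integrated regulatory-metabolic model (", x$variant, " variant)\n", sep = "")
  cat("  metabolic model: ", length(x$model$reaction_ids), " reactions, ",
      length(x$model$genes), " genes; wild-type growth ",
      format(x$wildtype$objective, digits = 6), "\n", sep = "")
  cat("  network: ", nrow(x$network), " edges over ",
      length(x$constraints), " TFs (",
      sum(x$network$evidence == "direct"), " direct)\n", sep = "")
  cat("  constrained (TF, reaction) pairs: ", n_con,
      "; mode ", x$mode, if (x$mode == "soft") paste0(" (kappa ", x$kappa, ")"),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.idream <- function(object, ...) {
  pred <- predict(object)
  print(object)
  cat("\nTF-knockout growth ratios:\n")
  print(summary(pred$ratio))
  invisible(list(fit = object, predictions = pred))
}

#' Constraint map of a fitted integrated model
#'
#' @param object an \code{idream} fit.
#' @param level \code{"gene"} for per-(TF, gene) retention probabilities,
#'   \code{"reaction"} for the GPR-propagated per-(TF, reaction)
#'   probabilities (only entries < 1 are listed).
#' @param ... unused.
#' @return data.frame with columns \code{tf}, \code{id}, \code{prob},
#'   \code{level}, \code{variant}.
#' @export
coef.idream <- function(object, level = c("gene", "reaction"), ...) {
  level <- match.arg(level)
  rows <- lapply(names(object$constraints), function(tf) {
    p <- if (level == "gene") object$constraints[[tf]]$gene_probs
         else object$constraints[[tf]]$rxn_probs
    if (!length(p)) return(NULL)
    data.frame(tf = tf, id = names(p), prob = as.numeric(p),
               level = level, variant = object$variant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tf = character(0), id = character(0), prob = numeric(0),
                      level = character(0), variant = character(0))
  rownames(out) <- NULL
  out
}

# probability-scaled bound tightening.
# Vmax scaling: a forward range [*, vmax>0] becomes ub' = prob*vmax; a
# reverse range [vmin<0, *] becomes lb' = prob*vmin; a dead direction
# (vmax <= 0 forward / vmin >= 0 reverse) is left alone, so a reaction that
# FVA already pins to zero is never resurrected.
scaled_bounds <- function(model, fv, probs) {
  lb <- model$lb; ub <- model$ub
  tightened <- integer(0)
  for (j in which(probs < 1)) {
    p <- probs[j]
    vmax <- fv$max[j]; vmin <- fv$min[j]
    changed <- FALSE
    if (vmax > 0) { ub[j] <- min(ub[j], p * vmax); changed <- TRUE }
    else if (vmax == 0 && ub[j] > 0) { ub[j] <- 0; changed <- TRUE }
    if (vmin < 0) { lb[j] <- max(lb[j], p * vmin); changed <- TRUE }
    else if (vmin == 0 && lb[j] < 0) { lb[j] <- 0; changed <- TRUE }
    if (changed) tightened <- c(tightened, j)
  }
  list(lb = lb, ub = ub, tightened = tightened)
}

# retention probabilities per reaction for a TF knockout composed with
# structural gene deletions: deleted genes enter the GPR propagation with
# probability 0, so deleting one isozyme exposes the TF's constraint on its
# partner
composed_rxn_probs <- function(fit, tf, delete = character(0)) {
  gene_probs <- if (!is.null(tf) && !is.na(tf) && tf %in% names(fit$constraints))
    fit$constraints[[tf]]$gene_probs else numeric(0)
  v <- gene_probs
  if (length(delete)) v[delete] <- 0
  if (!length(v)) return(stats::setNames(rep(1, length(fit$model$reaction_ids)),
                                         fit$model$reaction_ids))
  map_gene_probs_to_reactions(fit$model, v)
}

tf_tightened_bounds <- function(fit, tf) {
  probs <- composed_rxn_probs(fit, tf)
  scaled_bounds(fit$model, fit$fva, probs)
}

#' Hard-constrained model for one TF knockout
#'
#' Returns a copy of the metabolic model with the TF's probability-scaled
#' flux bounds applied strictly, e.g. for inspecting how the knockout shrinks
#' the feasible flux space via [fva()].
#'
#' @param fit an \code{idream} fit.
#' @param tf TF gene id.
#' @return a \code{stoich_model}.
#' @export
tf_constrained_model <- function(fit, tf) {
  stopifnot(inherits(fit, "idream"))
  tb <- tf_tightened_bounds(fit, tf)
  model <- fit$model
  model$lb <- pmin(tb$lb, tb$ub)
  model$ub <- tb$ub
  model
}

# growth under TF constraints (+ optional structural gene deletions), either
# strict (hard) or with penalized bound violations (soft).
constrained_growth <- function(fit, tf, delete = character(0),
                               mode = fit$mode, kappa = fit$kappa) {
  model <- fit$model
  probs <- composed_rxn_probs(fit, tf, delete)
  # structural deletions: reactions whose GPR is boolean-false under the
  # deletion are pinned to zero and never softened
  off <- integer(0)
  if (length(delete)) {
    dm <- delete_genes(model, delete)
    off <- which(dm$ub == 0 & dm$lb == 0 & !(model$ub == 0 & model$lb == 0))
    probs[off] <- 1  # handled as hard zeros below, not as scaled bounds
  }
  tb <- scaled_bounds(model, fit$fva, probs)
  n <- length(model$reaction_ids)
  obj_idx <- match(model$objective, model$reaction_ids)
  tightened <- setdiff(tb$tightened, off)

  if (mode == "hard" || !length(tightened)) {
    lb <- tb$lb; ub <- tb$ub
    lb[off] <- 0; ub[off] <- 0
    lb <- pmin(lb, ub)
    obj <- numeric(n); obj[obj_idx] <- 1
    res <- lp_solve(obj, A_eq = as.matrix(model$S), b_eq = rep(0, nrow(model$S)),
                    lb = lb, ub = ub, maximize = TRUE)
    if (res$status != "optimal")
      return(list(growth = 0, status = res$status, infeasible = TRUE))
    return(list(growth = res$objective, status = "optimal", infeasible = FALSE))
  }

  # soft mode: original bounds on v; tightened bounds as penalized rows
  lb0 <- model$lb; ub0 <- model$ub
  lb0[off] <- 0; ub0[off] <- 0
  rows <- list(); wts <- numeric(0)
  f_wt <- fit$wildtype$objective
  for (j in tightened) {
    if (tb$ub[j] < ub0[j]) {
      rows[[length(rows) + 1L]] <- list(j = j, sign = +1, rhs = tb$ub[j],
        w = kappa * f_wt / max(abs(fit$fva$max[j]), 1e-9))
    }
    if (tb$lb[j] > lb0[j]) {
      rows[[length(rows) + 1L]] <- list(j = j, sign = -1, rhs = -tb$lb[j],
        w = kappa * f_wt / max(abs(fit$fva$min[j]), 1e-9))
    }
  }
  ns <- length(rows)
  obj <- c(numeric(n), -vapply(rows, `[[`, 0, "w"))
  obj[obj_idx] <- 1
  A_ub <- matrix(0, ns, n + ns)
  b_ub <- numeric(ns)
  for (k in seq_len(ns)) {
    A_ub[k, rows[[k]]$j] <- rows[[k]]$sign
    A_ub[k, n + k] <- -1
    b_ub[k] <- rows[[k]]$rhs
  }
  A_eq <- cbind(as.matrix(model$S), matrix(0, nrow(model$S), ns))
  res <- lp_solve(obj, A_eq = A_eq, b_eq = rep(0, nrow(model$S)),
                  A_ub = A_ub, b_ub = b_ub,
                  lb = c(lb0, numeric(ns)), ub = c(ub0, rep(Inf, ns)),
                  maximize = TRUE)
  if (res$status != "optimal")
    return(list(growth = 0, status = res$status, infeasible = TRUE))
  list(growth = res$x[obj_idx], status = "optimal", infeasible = FALSE)
}

#' Growth after a single TF knockout
#'
#' Applies the TF's probability-scaled flux bounds and maximises biomass. In
#' hard mode each affected reaction's forward bound becomes
#' \code{Prob * Vmax} (and its reverse bound \code{Prob * Vmin}); in soft
#' mode those bounds may be exceeded at objective penalty
#' \code{kappa * growth_wt / |Vmax|} per flux unit of violation. A TF absent
#' from the network leaves the model unconstrained (ratio 1 by definition).
#' An infeasible mutant LP yields growth 0 with \code{infeasible = TRUE},
#' never an error.
#'
#' @param fit an \code{idream} fit.
#' @param tf TF gene id.
#' @param mode,kappa override the fit's defaults.
#' @return one-row data.frame: \code{tf}, \code{growth}, \code{wt_growth},
#'   \code{ratio}, \code{infeasible}.
#' @export
tf_knockout_growth <- function(fit, tf, mode = fit$mode, kappa = fit$kappa) {
  stopifnot(inherits(fit, "idream"))
  res <- constrained_growth(fit, tf, mode = mode, kappa = kappa)
  wt <- fit$wildtype$objective
  data.frame(tf = tf, growth = res$growth, wt_growth = wt,
             ratio = if (wt > 0) max(0, res$growth) / wt else NA_real_,
             infeasible = res$infeasible, stringsAsFactors = FALSE)
}

#' Predict growth ratios for TF knockouts
#'
#' Batch [tf_knockout_growth()] over a deterministic TF ordering; the
#' wild-type problem is solved once at fit time. TFs not present in the
#' network get ratio 1.
#'
#' @param object an \code{idream} fit.
#' @param tfs TF ids to simulate (default: every TF in the network).
#' @param mode,kappa override the fit's defaults.
#' @param ... unused.
#' @return data.frame of class \code{growth_prediction} with one row per TF:
#'   \code{tf}, \code{growth}, \code{wt_growth}, \code{ratio},
#'   \code{infeasible}.
#' @export
predict.idream <- function(object, tfs = names(object$constraints),
                           mode = object$mode, kappa = object$kappa, ...) {
  rows <- lapply(tfs, function(tf)
    tf_knockout_growth(object, tf, mode = mode, kappa = kappa))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tf = character(0), growth = numeric(0),
                      wt_growth = numeric(0), ratio = numeric(0),
                      infeasible = logical(0))
  rownames(out) <- NULL
  class(out) <- c("growth_prediction", "data.frame")
  out
}

#' @export
print.growth_prediction <- function(x, ...) {
  cat("growth_prediction:", nrow(x), "TF knockouts\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
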