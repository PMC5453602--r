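# Double-perturbation scanning: TF knockout (probabilistic constraints)
# crossed with metabolic gene deletion (structural), scored by the
# synthetic-interaction variation statistic.

#' Growth of a TF-knockout x gene-deletion double mutant
#'
#' Applies the TF's probability constraints and structurally deletes the
#' metabolic gene (GPR-aware, bounds pinned to zero), then maximises biomass.
#' The structural deletion is never softened; only the probabilistic TF
#' constraints respect the fit's soft/hard mode.
#'
#' @param fit an \code{idream} fit.
#' @param tf TF gene id (may be absent from the network: unconstrained).
#' @param gene metabolic gene id, must be in \code{model_genes}.
#' @param mode,kappa override the fit's defaults.
#' @return growth rate (0 when the constrained LP is infeasible).
#' @export
double_deletion_growth <- function(fit, tf, gene, mode = fit$mode,
                                   kappa = fit$kappa) {
  stopifnot(inherits(fit, "idream"))
  if (!gene %in% fit$model$genes)
    stop("gene '", gene, "' is not in the metabolic model")
  res <- constrained_growth(fit, tf, delete = gene, mode = mode, kappa = kappa)
  max(0, res$growth)
}

#' Synthetic-interaction variation statistic
#'
#' With Diff1 the growth lost by adding the gene deletion to the TF knockout
#' (\code{g_tf - g_double}) and Diff2 the growth lost by adding the TF
#' knockout to the gene deletion (\code{g_gene - g_double}), the variation is
#' \code{((Diff1 + Diff2)/2) / g_wt}. High variation with healthy singles
#' marks a synthetic (negative/aggravating) interaction.
#'
#' @param g_wt wild-type growth rate (> 0).
#' @param g_tf,g_gene single-perturbation growth rates.
#' @param g_double double-perturbation growth rate.
#' @return the variation (dimensionless fraction of wild-type growth).
#' @examples
#' interaction_variation(1, 1, 1, 0)  # 1: total synthetic lethality
#' interaction_variation(1, 1, 1, 1)  # 0: no interaction
#' @export
interaction_variation <- function(g_wt, g_tf, g_gene, g_double) {
  if (any(g_wt <= 0)) stop("wild-type growth must be positive")
  diff1 <- g_tf - g_double
  diff2 <- g_gene - g_double
  ((diff1 + diff2) / 2) / g_wt
}

#' Scan TF x gene pairs for synthetic interactions
#'
#' Simulates every (TF knockout, gene deletion) double perturbation, scores
#' it with [interaction_variation()], and returns the pairs whose variation
#' exceeds \code{variation_threshold} (strict) while both single
#' perturbations retain at least \code{single_retention} of wild-type growth.
#' Results are sorted by variation, descending.
#'
#' @param fit an \code{idream} fit.
#' @param tf_list TFs to knock out (default: all TFs in the network).
#' @param gene_list metabolic genes to delete (default: all model genes).
#' @param variation_threshold keep pairs with variation strictly above this.
#' @param single_retention minimum single-perturbation growth fraction.
#' @param full_matrix also return the unfiltered pair matrix as attribute
#'   \code{"matrix"}.
#' @param mode,kappa override the fit's defaults.
#' @return data.frame with columns \code{tf}, \code{gene}, \code{g_wt},
#'   \code{g_tf}, \code{g_gene}, \code{g_double}, \code{diff1}, \code{diff2},
#'   \code{variation}.
#' @export
scan_synthetic_pairs <- function(fit, tf_list = names(fit$constraints),
                                 gene_list = fit$model$genes,
                                 variation_threshold = 0.9,
                                 single_retention = 0.95,
                                 full_matrix = FALSE,
                                 mode = fit$mode, kappa = fit$kappa) {
  stopifnot(inherits(fit, "idream"))
  if (!length(tf_list) || !length(gene_list))
    stop("tf_list and gene_list must be nonempty")
  g_wt <- fit$wildtype$objective
  g_tf <- vapply(tf_list, function(tf)
    max(0, constrained_growth(fit, tf, mode = mode, kappa = kappa)$growth),
    numeric(1))
  g_gene <- vapply(gene_list, function(g)
    max(0, constrained_growth(fit, NA, delete = g, mode = mode,
                              kappa = kappa)$growth), numeric(1))
  rows <- list()
  for (tf in tf_list) {
    for (g in gene_list) {
      gd <- tryCatch(double_deletion_growth(fit, tf, g, mode = mode,
                                            kappa = kappa),
                     error = function(e) {
                       warning("pair (", tf, ", ", g, ") skipped: ",
                               conditionMessage(e))
                       NA_real_
                     })
      if (is.na(gd)) next
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, gene = g, g_wt = g_wt, g_tf = g_tf[[tf]],
        g_gene = g_gene[[g]], g_double = gd,
        diff1 = g_tf[[tf]] - gd, diff2 = g_gene[[g]] - gd,
        variation = interaction_variation(g_wt, g_tf[[tf]], g_gene[[g]], gd),
        stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(rbind, rows)
  keep <- mat$variation > variation_threshold &
    mat$g_tf / mat$g_wt >= single_retention &
    mat$g_gene / mat$g_wt >= single_retention
  out <- mat[keep, , drop = FALSE]
  out <- out[order(-out$variation), , drop = FALSE]
  rownames(out) <- NULL
  if (full_matrix) attr(out, "matrix") <- mat
  out
}

#' Draw benchmark control pairs
#'
#' Seeded uniform draw of non-interacting (TF, gene) pairs (variation below
#' 0.1) from a full scan matrix, for use as negative controls alongside
#' predicted synthetic interactions.
#'
#' @param pair_matrix full pair matrix (the \code{"matrix"} attribute of a
#'   [scan_synthetic_pairs()] run with \code{full_matrix = TRUE}).
#' @param n number of control pairs.
#' @param seed integer seed.
#' @return subset of \code{pair_matrix} rows.
#' @export
sample_control_pairs <- function(pair_matrix, n = 8, seed = 1) {
  pool <- which(pair_matrix$variation < 0.1)
  if (length(pool) < n)
    stop("only ", length(pool), " non-interacting pairs available")
  with_seed(substream_seed(seed, "control_pairs"), {
    idx <- sample(pool, n)
    pair_matrix[sort(idx), , drop = FALSE]
  })
}
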