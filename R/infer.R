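# Bootstrap sparse-regression inference of TF -> target influences with a
# per-edge false discovery rate and activator/repressor sign classification.
# This is a desk-scale, per-gene replacement for ensemble regulatory-network
# inference: each target gene is regressed on candidate TF expression with a
# lasso, once per random sample subset, and the FDR of an edge is one minus
# the fraction of subset models that select the TF.

#' Fit a sparse regulator model for one target gene
#'
#' Regresses the target gene's expression on the candidate TF expressions
#' over the given sample subset using a lasso whose regularization strength
#' is chosen by 5-fold cross-validation (the one-standard-error rule). A TF
#' is identified as a regulator iff its coefficient is nonzero at the fitted
#' regularization.
#'
#' @param expression numeric genes x samples matrix.
#' @param candidate_tfs character vector of candidate regulator gene ids
#'   (must not contain \code{target}).
#' @param target target gene id.
#' @param sample_subset sample names or indices to fit on (default: all).
#'   Must contain at least \code{max(10, length(candidate_tfs)/2)} samples.
#' @return named numeric vector of signed coefficients for the selected TFs
#'   (empty when nothing is selected, e.g. a constant target).
#' @export
fit_regulator_model <- function(expression, candidate_tfs, target,
                                sample_subset = NULL) {
  if (target %in% candidate_tfs)
    stop("target '", target, "' must not be among candidate_tfs")
  missing <- setdiff(c(candidate_tfs, target), rownames(expression))
  if (length(missing))
    stop("gene(s) absent from expression: ", paste(missing, collapse = ", "))
  if (is.null(sample_subset)) sample_subset <- seq_len(ncol(expression))
  n_min <- max(10, ceiling(length(candidate_tfs) / 2))
  if (length(sample_subset) < n_min)
    stop("sample subset too small: ", length(sample_subset), " < ", n_min)
  y <- expression[target, sample_subset]
  if (stats::sd(y) == 0) return(stats::setNames(numeric(0), character(0)))
  X <- t(expression[candidate_tfs, sample_subset, drop = FALSE])
  if (length(candidate_tfs) < 2) {
    # lasso needs >= 2 columns; fall back to a univariate regression test
    fit <- stats::lm(y ~ X[, 1])
    p <- summary(fit)$coefficients[2, 4]
    b <- stats::coef(fit)[2]
    if (is.na(p) || p >= 0.05) return(stats::setNames(numeric(0), character(0)))
    return(stats::setNames(as.numeric(b), candidate_tfs))
  }
  cv <- glmnet::cv.glmnet(X, y, nfolds = 5, standardize = TRUE)
  b <- as.numeric(stats::coef(cv, s = "lambda.1se"))[-1]
  sel <- which(b != 0)
  stats::setNames(b[sel], candidate_tfs[sel])
}

#' Tally regulator selections over bootstrap sample subsets
#'
#' Fits [fit_regulator_model()] on \code{n_subsets} independently drawn
#' sample subsets (a fraction of all samples, drawn without replacement),
#' plus once on the full data set. \code{counts[tf]} is the number of subset
#' models selecting that TF; the full-data fit is kept for sign/coefficient
#' reporting only and never enters the FDR denominator.
#'
#' @inheritParams fit_regulator_model
#' @param n_subsets number of random subset models (>= 1).
#' @param subset_fraction fraction of samples per subset, in (0, 1].
#' @param seed integer seed; identical seeds give identical tallies.
#' @return list of class \code{bootstrap_tally}: \code{target},
#'   \code{counts} (named integer vector over \code{candidate_tfs}),
#'   \code{n_subsets}, \code{full_model} (signed coefficients of the
#'   full-data fit).
#' @export
bootstrap_tally <- function(expression, candidate_tfs, target,
                            n_subsets = 200, subset_fraction = 0.632,
                            seed = 1) {
  if (n_subsets < 1) stop("n_subsets must be >= 1")
  if (subset_fraction <= 0 || subset_fraction > 1)
    stop("subset_fraction must lie in (0, 1]")
  ns <- ncol(expression)
  size <- ceiling(subset_fraction * ns)
  counts <- stats::setNames(integer(length(candidate_tfs)), candidate_tfs)
  full <- NULL
  with_seed(substream_seed(seed, paste0("tally:", target)), {
    for (b in seq_len(n_subsets)) {
      idx <- sample.int(ns, size)
      sel <- tryCatch(
        fit_regulator_model(expression, candidate_tfs, target, idx),
        error = function(e) stop("subset ", b, " for target '", target, "': ",
                                 conditionMessage(e), call. = FALSE))
      counts[names(sel)] <- counts[names(sel)] + 1L
    }
    full <<- fit_regulator_model(expression, candidate_tfs, target)
  })
  structure(list(target = target, counts = counts, n_subsets = n_subsets,
                 full_model = full),
            class = "bootstrap_tally")
}

#' Bootstrap FDR from a selection tally
#'
#' An edge selected in \code{count} of \code{n_subsets} subset models gets
#' FDR \code{1 - count/n_subsets}: a factor selected in 191 of 200 models has
#' FDR 0.045. The FDR doubles as the activator retention probability: it is
#' the fraction of the target's activity not controlled by the regulator.
#'
#' @param count integer selection count(s), each in \code{[0, n_subsets]}.
#' @param n_subsets total number of subset models.
#' @return numeric FDR value(s) in [0, 1].
#' @examples
#' fdr_from_tally(191, 200)  # 0.045
#' @export
fdr_from_tally <- function(count, n_subsets) {
  if (n_subsets < 1) stop("n_subsets must be >= 1")
  if (any(count < 0 | count > n_subsets))
    stop("count must lie in [0, n_subsets]")
  1 - count / n_subsets
}

#' Classify a regulator as activator or repressor
#'
#' Pearson-correlates the TF's expression with its target's over the given
#' samples: positive correlation means activator, negative means repressor.
#'
#' @param expression numeric genes x samples matrix.
#' @param tf,target gene ids, both present in \code{expression}.
#' @param sample_subset optional sample names/indices restricting the
#'   correlation to a condition-relevant subset (default: all samples).
#' @return \code{"activator"} or \code{"repressor"}. A constant series or an
#'   exactly zero correlation is an error surfaced to the caller.
#' @export
classify_sign <- function(expression, tf, target, sample_subset = NULL) {
  missing <- setdiff(c(tf, target), rownames(expression))
  if (length(missing))
    stop("gene(s) absent from expression: ", paste(missing, collapse = ", "))
  if (is.null(sample_subset)) sample_subset <- seq_len(ncol(expression))
  if (length(sample_subset) < 3) stop("need at least 3 samples to classify sign")
  x <- expression[tf, sample_subset]
  y <- expression[target, sample_subset]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("cannot classify sign of '", tf, "' -> '", target,
         "': constant expression series")
  r <- stats::cor(x, y)
  if (r == 0) stop("sign of '", tf, "' -> '", target,
                   "' is tied (correlation exactly 0)")
  if (r > 0) "activator" else "repressor"
}

#' Infer a TF influence network by bootstrap regression
#'
#' Runs [bootstrap_tally()] for every target gene and keeps exactly the
#' (TF, target) pairs whose bootstrap FDR is at or below \code{fdr_cutoff}.
#' Each retained edge carries its FDR and its [classify_sign()] result;
#' evidence defaults to \code{"indirect"} until annotated against a
#' binding-evidence reference (see [annotate_evidence()]). Self-edges are
#' excluded.
#'
#' @inheritParams bootstrap_tally
#' @param tfs candidate regulator gene ids.
#' @param targets target gene ids (default: all non-TF genes in
#'   \code{expression}).
#' @param fdr_cutoff maximum bootstrap FDR for edge inclusion.
#' @return an \code{influence_network}.
#' @export
infer_network <- function(expression, tfs,
                          targets = setdiff(rownames(expression), tfs),
                          n_subsets = 200, subset_fraction = 0.632,
                          fdr_cutoff = 0.05, seed = 1) {
  rows <- list()
  for (target in targets) {
    cand <- setdiff(tfs, target)
    if (!length(cand)) next
    tal <- bootstrap_tally(expression, cand, target,
                           n_subsets = n_subsets,
                           subset_fraction = subset_fraction, seed = seed)
    fdr <- fdr_from_tally(tal$counts, tal$n_subsets)
    keep <- names(fdr)[fdr <= fdr_cutoff]
    for (tf in keep) {
      sign <- tryCatch(classify_sign(expression, tf, target),
                       error = function(e) "unknown")
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, target = target, evidence = "indirect", sign = sign,
        fdr = unname(fdr[tf]), prom_prob = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(influence_network(data.frame(
      tf = character(0), target = character(0), evidence = character(0),
      sign = character(0), fdr = numeric(0), prom_prob = numeric(0))))
  }
  influence_network(do.call(rbind, rows))
}

#' Annotate inferred edges with binding evidence from a reference network
#'
#' Marks an inferred edge \code{direct} when the same (TF, target) pair is
#' listed as \code{direct} in the reference network (e.g. a curated database
#' of TF-chromatin binding evidence); all other edges stay \code{indirect}.
#'
#' @param network an inferred \code{influence_network}.
#' @param reference an \code{influence_network} carrying evidence labels.
#' @return the network with updated \code{evidence}.
#' @export
annotate_evidence <- function(network, reference) {
  key <- function(df) paste(df$tf, df$target, sep = "\r")
  direct <- key(reference)[reference$evidence == "direct"]
  network$evidence <- ifelse(key(network) %in% direct, "direct", "indirect")
  network
}
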