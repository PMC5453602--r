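# Evaluation statistics for predicted vs observed knockout phenotypes:
# Matthews correlation with threshold binarization, Pearson correlation with
# Fisher-Z comparison, residual t-tests, ROC/AUC, and permutation nulls.

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' ranging from -1 (predictions exactly opposite the reference) to +1
#' (perfect agreement). When any factor of the denominator is zero the
#' conventional value 0 is returned, flagged with attribute
#' \code{zero_denominator}.
#'
#' @param tp,tn,fp,fn non-negative confusion-matrix counts; at least one
#'   must be positive.
#' @return MCC in [-1, 1].
#' @examples
#' mcc(5, 5, 0, 0)   #  1
#' mcc(0, 0, 5, 5)   # -1
#' mcc(2, 3, 1, 4)   #  2/sqrt(504)
#' @export
mcc <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be >= 0")
  if (tp + tn + fp + fn == 0) stop("all confusion counts are zero")
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) {
    return(structure(0, zero_denominator = TRUE))
  }
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Binarize growth ratios into defect calls
#'
#' A knockout is called growth-defective iff its mutant/wild-type ratio is
#' strictly below the threshold.
#'
#' @param ratios numeric growth-ratio vector.
#' @param threshold defect threshold in (0, 1).
#' @return logical vector (TRUE = growth defect).
#' @export
binarize_growth_calls <- function(ratios, threshold) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly in (0, 1)")
  ratios < threshold
}

#' MCC across a sweep of growth-ratio thresholds
#'
#' Binarizes predictions and observations at each threshold and computes the
#' MCC of the resulting confusion matrix. Thresholds at which the observed
#' calls are single-class leave the MCC undefined and are reported as
#' \code{NA}, never silently 0.
#'
#' @param pred_ratios,obs_ratios aligned numeric vectors.
#' @param thresholds thresholds to sweep (default 0.1 to 0.95).
#' @return named numeric vector of MCC values (names = thresholds).
#' @export
mcc_threshold_sweep <- function(pred_ratios, obs_ratios,
                                thresholds = seq(0.1, 0.95, by = 0.05)) {
  if (length(pred_ratios) != length(obs_ratios))
    stop("pred_ratios and obs_ratios differ in length")
  out <- vapply(thresholds, function(th) {
    p <- binarize_growth_calls(pred_ratios, th)
    o <- binarize_growth_calls(obs_ratios, th)
    if (all(o) || all(!o)) return(NA_real_)
    as.numeric(mcc(sum(p & o), sum(!p & !o), sum(p & !o), sum(!p & o)))
  }, numeric(1))
  stats::setNames(out, format(thresholds, trim = TRUE))
}

#' Pearson correlation with p-value
#'
#' @param x,y aligned numeric vectors, n >= 4.
#' @return list with \code{r} and \code{p} (two-sided).
#' @export
pearson_with_pvalue <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 4) stop("need at least 4 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (constant) series")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t-test on absolute residuals of two predictors
#'
#' Tests the null hypothesis that the mean absolute residual
#' \code{|pred - obs|} is the same for two sets of predictions of the same
#' observations (two-tailed, paired).
#'
#' @param pred_a,pred_b two prediction vectors.
#' @param obs the common observation vector.
#' @return two-sided p-value.
#' @export
residual_ttest <- function(pred_a, pred_b, obs) {
  ra <- abs(pred_a - obs); rb <- abs(pred_b - obs)
  if (stats::sd(ra - rb) == 0) stop("degenerate residual difference (zero variance)")
  stats::t.test(ra, rb, paired = TRUE)$p.value
}

#' Compare two Pearson correlations via Fisher's Z transform
#'
#' \code{z = atanh(r)}; the statistic \code{(z1 - z2) /
#' sqrt(1/(n1-3) + 1/(n2-3))} is referred to a standard normal, two-tailed.
#'
#' @param r1,r2 correlations with |r| < 1.
#' @param n1,n2 sample sizes (> 3).
#' @return two-sided p-value.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1 for Fisher Z")
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * stats::pnorm(-abs(z))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, ties counted half.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels (1/TRUE = positive); both classes must occur.
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (all(labels) || all(!labels)) stop("roc_auc needs both classes present")
  n1 <- sum(labels); n0 <- sum(!labels)
  r <- rank(scores)  # average ranks give the ties-counted-half convention
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Permutation significance of a pipeline's MCC
#'
#' Re-runs a full prediction pipeline on permuted inputs and reports the
#' fraction of permutations whose MCC exceeds the observed one. In
#' \code{"expression"} mode each gene's values are permuted independently
#' across samples (gene count fixed; set \code{per_gene = FALSE} for a
#' whole-matrix shuffle). In \code{"network"} mode each TF's connections are
#' rewired to targets drawn from the network's target pool (TF and gene
#' counts fixed), keeping per-edge annotations.
#'
#' @param pipeline function \code{(expression, network) -> MCC} closing over
#'   everything else (model, constraints, observations).
#' @param observed_mcc the MCC of the unpermuted pipeline.
#' @param expression genes x samples matrix handed to \code{pipeline}.
#' @param network \code{influence_network} handed to \code{pipeline}.
#' @param regenerate which input to permute.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; identical seeds give identical p-values.
#' @param per_gene expression mode: permute per gene row (default) or the
#'   whole matrix.
#' @return permutation p-value in [0, 1].
#' @export
permutation_test <- function(pipeline, observed_mcc, expression, network,
                             regenerate = c("expression", "network"),
                             n_perm = 500, seed = 1, per_gene = TRUE) {
  regenerate <- match.arg(regenerate)
  if (n_perm < 1) stop("n_perm must be >= 1")
  targets <- unique(network$target)
  perm_mcc <- vapply(seq_len(n_perm), function(b) {
    with_seed(substream_seed(seed, paste0("perm:", regenerate, ":", b)), {
      if (regenerate == "expression") {
        ex <- expression
        if (per_gene) {
          for (i in seq_len(nrow(ex))) ex[i, ] <- ex[i, sample(ncol(ex))]
        } else {
          ex[] <- sample(as.vector(ex))
        }
        pipeline(ex, network)
      } else {
        net <- network
        for (tf in unique(net$tf)) {
          idx <- which(net$tf == tf)
          pool <- setdiff(targets, tf)
          net$target[idx] <- sample(pool, length(idx))
        }
        pipeline(expression, net)
      }
    })
  }, numeric(1))
  mean(perm_mcc > observed_mcc)
}

#' Score predictions against observed growth ratios
#'
#' Bundles the package's evaluation statistics for one prediction set:
#' MCC across a threshold sweep, Pearson correlation with p-value, raw and
#' normalized sums of squared error, mean absolute residual, and AUC per
#' threshold (scores \code{1 - predicted ratio}, positives = observed
#' defect). AUC entries are \code{NA} at thresholds where the observed calls
#' are single-class.
#'
#' @param pred_ratios,obs_ratios aligned numeric growth-ratio vectors.
#' @param thresholds growth-defect thresholds to sweep.
#' @return object of class \code{eval_report}.
#' @export
evaluate_predictions <- function(pred_ratios, obs_ratios,
                                 thresholds = seq(0.1, 0.95, by = 0.05)) {
  if (length(pred_ratios) != length(obs_ratios))
    stop("pred_ratios and obs_ratios differ in length")
  res <- pred_ratios - obs_ratios
  pcc <- tryCatch(pearson_with_pvalue(pred_ratios, obs_ratios),
                  error = function(e) list(r = NA_real_, p = NA_real_))
  auc <- vapply(thresholds, function(th) {
    o <- binarize_growth_calls(obs_ratios, th)
    if (all(o) || all(!o)) return(NA_real_)
    roc_auc(1 - pred_ratios, o)
  }, numeric(1))
  structure(list(
    mcc_by_threshold = mcc_threshold_sweep(pred_ratios, obs_ratios, thresholds),
    pcc = pcc$r, pcc_pvalue = pcc$p,
    sse = sum(res^2),
    sse_per_n = mean(res^2),
    sse_normalized = sum(res^2) / sum((obs_ratios - mean(obs_ratios))^2),
    mean_abs_residual = mean(abs(res)),
    auc_by_threshold = stats::setNames(auc, format(thresholds, trim = TRUE)),
    n = length(pred_ratios)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report over", x$n, "knockouts\n")
  cat(sprintf("  PCC %.4f (p = %.3g), SSE %.4g (per-n %.4g, normalized %.4g)\n",
              x$pcc, x$pcc_pvalue, x$sse, x$sse_per_n, x$sse_normalized))
  cat(sprintf("  mean |residual| %.4f\n", x$mean_abs_residual))
  ok <- !is.na(x$mcc_by_threshold)
  if (any(ok))
    cat(sprintf("  MCC sweep: max %.3f at threshold %s (%d/%d defined)\n",
                max(x$mcc_by_threshold[ok]),
                names(which.max(x$mcc_by_threshold)), sum(ok), length(ok)))
  ok <- !is.na(x$auc_by_threshold)
  if (any(ok))
    cat(sprintf("  AUC sweep: mean %.3f (%d/%d defined)\n",
                mean(x$auc_by_threshold[ok]), sum(ok), length(ok)))
  invisible(x)
}
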