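# PROM-style conditional probabilities P(target ON | TF OFF) estimated from
# quantile-binarized expression.

#' Binarize an expression matrix
#'
#' Per gene, a sample is ON (1) iff its value exceeds that gene's
#' \code{threshold_quantile} quantile across samples. A constant gene is
#' never above its own quantile and binarizes to all zeros.
#'
#' @param expression numeric genes x samples matrix.
#' @param threshold_quantile quantile in (0, 1); the conventional PROM
#'   threshold is the lower tertile (1/3).
#' @return object of class \code{binary_expression}: list with \code{states}
#'   (0/1 matrix, same dimnames) and \code{threshold_quantile}.
#' @export
binarize_expression <- function(expression, threshold_quantile = 1/3) {
  if (threshold_quantile <= 0 || threshold_quantile >= 1)
    stop("threshold_quantile must lie strictly in (0, 1)")
  thr <- apply(expression, 1, stats::quantile, probs = threshold_quantile,
               names = FALSE)
  states <- (expression > thr) * 1L
  structure(list(states = states, threshold_quantile = threshold_quantile),
            class = "binary_expression")
}

#' @export
print.binary_expression <- function(x, ...) {
  cat("binary_expression:", nrow(x$states), "genes x", ncol(x$states),
      "samples, ON fraction", round(mean(x$states), 3),
      "(quantile", round(x$threshold_quantile, 3), ")\n")
  invisible(x)
}

#' PROM conditional probability P(target ON | TF OFF)
#'
#' The fraction of samples, among those where the TF is OFF, in which the
#' target gene is ON. This is the retention probability the PROM scheme
#' applies to the target's reactions after deleting the TF. When fewer than
#' \code{min_off_samples} TF-OFF samples exist the probability is not
#' estimable and the pair is left unconstrained (probability 1) with a
#' warning.
#'
#' @param binary a \code{binary_expression}.
#' @param tf,target gene ids present in the binarized matrix.
#' @param min_off_samples minimum number of TF-OFF samples required.
#' @return probability in [0, 1].
#' @examples
#' b <- structure(list(states = rbind(tf = c(0,0,0,0,1,1),
#'                                    tg = c(1,1,0,1,1,1)),
#'                     threshold_quantile = 1/3),
#'                class = "binary_expression")
#' conditional_probability(b, "tf", "tg", min_off_samples = 3)  # 0.75
#' @export
conditional_probability <- function(binary, tf, target, min_off_samples = 5) {
  stopifnot(inherits(binary, "binary_expression"))
  missing <- setdiff(c(tf, target), rownames(binary$states))
  if (length(missing))
    stop("gene(s) absent from binarized expression: ",
         paste(missing, collapse = ", "))
  off <- which(binary$states[tf, ] == 0)
  if (length(off) < min_off_samples) {
    warning("only ", length(off), " TF-OFF samples for '", tf,
            "'; leaving '", target, "' unconstrained (probability 1)")
    return(1)
  }
  mean(binary$states[target, off] == 1)
}

# annotate every edge of a network with its PROM conditional probability
prom_annotate <- function(network, binary, min_off_samples = 5) {
  network$prom_prob <- vapply(seq_len(nrow(network)), function(i) {
    conditional_probability(binary, network$tf[i], network$target[i],
                            min_off_samples = min_off_samples)
  }, numeric(1))
  network
}
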