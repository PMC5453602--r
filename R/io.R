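# Readers and writers for regulatory networks, expression matrices and
# phenotype tables. All are plain TSV; readers validate invariants and refuse
# malformed input rather than repairing it.

#' Construct a TF influence network
#'
#' An edge list of transcription-factor to target-gene influences. Each edge
#' carries an evidence class (\code{direct} = physical binding evidence,
#' \code{indirect} = inferred influence only), a regulatory sign
#' (\code{activator}/\code{repressor}/\code{unknown}), an optional bootstrap
#' FDR and an optional PROM conditional probability
#' \eqn{P(\mathrm{target\,ON} \mid \mathrm{TF\,OFF})}.
#'
#' @param edges data.frame with columns \code{tf}, \code{target},
#'   \code{evidence}, \code{sign} and optionally \code{fdr}, \code{prom_prob}.
#' @return an object of class \code{influence_network} (a data.frame).
#' @export
influence_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("tf", "target")
  miss <- setdiff(req, names(edges))
  if (length(miss)) stop("network is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(edges$evidence)) edges$evidence <- "indirect"
  if (is.null(edges$sign)) edges$sign <- "unknown"
  if (is.null(edges$fdr)) edges$fdr <- NA_real_
  if (is.null(edges$prom_prob)) edges$prom_prob <- NA_real_
  canonical <- c("tf", "target", "evidence", "sign", "fdr", "prom_prob")
  edges <- edges[, c(canonical, setdiff(names(edges), canonical))]
  edges$tf <- as.character(edges$tf); edges$target <- as.character(edges$target)
  bad <- which(!edges$evidence %in% c("direct", "indirect"))
  if (length(bad))
    stop("unknown evidence token '", edges$evidence[bad[1]], "' (edge ", bad[1], ")")
  bad <- which(!edges$sign %in% c("activator", "repressor", "unknown"))
  if (length(bad))
    stop("unknown sign token '", edges$sign[bad[1]], "' (edge ", bad[1], ")")
  for (col in c("fdr", "prom_prob")) {
    v <- edges[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad))
      stop(col, " out of [0,1] on edge ", bad[1], " (", edges$tf[bad[1]], " -> ",
           edges$target[bad[1]], ")")
  }
  bad <- which(edges$tf == edges$target)
  if (length(bad)) stop("self-edge not allowed: ", edges$tf[bad[1]])
  dup <- which(duplicated(edges[, c("tf", "target")]))
  if (length(dup))
    stop("duplicate edge for (", edges$tf[dup[1]], ", ", edges$target[dup[1]], ")")
  rownames(edges) <- NULL
  class(edges) <- c("influence_network", "data.frame")
  edges
}

#' @export
print.influence_network <- function(x, ...) {
  cat("influence_network:", nrow(x), "edges,",
      length(unique(x$tf)), "TFs,", length(unique(x$target)), "targets",
      sprintf("(%d direct)\n", sum(x$evidence == "direct")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' TFs / targets of an influence network
#' @param network an \code{influence_network}.
#' @return character vector.
#' @export
network_tfs <- function(network) sort(unique(network$tf))

#' @rdname network_tfs
#' @export
network_targets <- function(network) sort(unique(network$target))

#' Read / write an influence network TSV
#'
#' TSV columns: \code{tf}, \code{target}, \code{evidence}, \code{sign} and
#' optionally \code{fdr}, \code{prom_prob}. Duplicate (tf, target) rows,
#' unknown tokens and out-of-range probabilities are rejected.
#'
#' @param path file path.
#' @return an \code{influence_network}.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("tf", "target", "evidence", "sign")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("network TSV ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  tryCatch(influence_network(df), error = function(e)
    stop("while reading ", path, ": ", conditionMessage(e), call. = FALSE))
}

#' @param network an \code{influence_network}.
#' @rdname read_network
#' @export
write_network <- function(network, path) {
  utils::write.table(as.data.frame(network), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix TSV
#'
#' Genes x samples, log-scale values; first column holds gene identifiers,
#' remaining columns one sample each. Duplicate gene ids, non-numeric or
#' non-finite cells are rejected.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene id in ", path, ": '", genes[duplicated(genes)][1], "'")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression cell in ", path)
  if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at gene '", genes[bad[1]], "', sample '",
         colnames(mat)[bad[2]], "'")
  }
  rownames(mat) <- genes
  mat
}

#' @param expression numeric genes x samples matrix with dimnames.
#' @rdname read_expression
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a TF-knockout phenotype table TSV
#'
#' Columns: \code{tf}, \code{condition}, \code{growth_ratio} (mutant /
#' wild-type growth rate, finite and non-negative).
#'
#' @param path file path.
#' @return data.frame with the three columns above.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("tf", "condition", "growth_ratio"), names(df))
  if (length(miss))
    stop("phenotype TSV is missing column(s): ", paste(miss, collapse = ", "))
  gr <- df$growth_ratio
  if (!is.numeric(gr) || any(!is.finite(gr)))
    stop("growth_ratio must be finite numeric in ", path)
  bad <- which(gr < 0)
  if (length(bad))
    stop("negative growth_ratio for tf '", df$tf[bad[1]], "' in ", path)
  df$tf <- as.character(df$tf)
  df[, c("tf", "condition", "growth_ratio")]
}

#' @param phenotypes data.frame as returned by \code{read_phenotypes}.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
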