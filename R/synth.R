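# Seeded generators for synthetic regulatory-metabolic benchmark systems:
# toy metabolic models, planted regulons, expression compendia and
# ground-truth knockout phenotypes. Every generator is deterministic given
# its seed, so parameter-recovery tests are exactly reproducible.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# derive an independent integer seed (< 2^31) for a named substream
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483587)
}

#' Generate a toy metabolic model
#'
#' Builds a small connected metabolic network with a single substrate intake
#' (exchange upper bound 10), a serial backbone of capacity-limited reactions
#' (every third one gated by a two-gene \code{and} complex), optional
#' isozyme-gated steps (\code{or} GPRs), optional pairs of parallel branch
#' routes that converge again, and a biomass drain as objective. Capacities
#' are drawn from the seed; the FBA optimum is always positive.
#'
#' @param n_linear number of serial backbone reactions.
#' @param n_isozyme_pairs number of steps gated by an isozyme (\code{or}) pair.
#' @param n_branches number of parallel two-route segments.
#' @param seed integer seed.
#' @return a \code{stoich_model}.
#' @examples
#' m <- make_toy_model(1, 0, 0, seed = 1)
#' fba(m)$objective  # the single backbone capacity
#' @export
make_toy_model <- function(n_linear, n_isozyme_pairs = 0, n_branches = 0, seed = 1) {
  stopifnot(n_linear >= 0, n_isozyme_pairs >= 0, n_branches >= 0)
  with_seed(substream_seed(seed, "toy_model"), {
    mets <- "M000"
    rxn <- list()
    add <- function(id, stoich, lb, ub, gpr = "", exchange = FALSE) {
      rxn[[length(rxn) + 1L]] <<- list(id = id, stoich = stoich, lb = lb,
                                       ub = ub, gpr = gpr, exchange = exchange)
    }
    add("EX_in", c(M000 = 1), 0, 10, exchange = TRUE)
    cur <- "M000"; k <- 0L
    new_met <- function() {
      k <<- k + 1L
      m <- sprintf("M%03d", k)
      mets <<- c(mets, m)
      m
    }
    for (i in seq_len(n_linear)) {
      nxt <- new_met()
      cap <- round(stats::runif(1, 6, 9), 2)
      g <- if (i %% 3 == 0) {
        sprintf("(gL%02da and gL%02db)", i, i)
      } else sprintf("gL%02d", i)
      st <- c(-1, 1); names(st) <- c(cur, nxt)
      add(sprintf("LIN%02d", i), st, 0, cap, g)
      cur <- nxt
    }
    for (i in seq_len(n_isozyme_pairs)) {
      nxt <- new_met()
      cap <- round(stats::runif(1, 6, 9), 2)
      st <- c(-1, 1); names(st) <- c(cur, nxt)
      add(sprintf("ISO%02d", i), st, 0, cap,
          sprintf("(gI%02da or gI%02db)", i, i))
      cur <- nxt
    }
    for (i in seq_len(n_branches)) {
      nxt <- new_met()
      caps <- round(stats::runif(2, 2.5, 5), 2)
      st <- c(-1, 1); names(st) <- c(cur, nxt)
      add(sprintf("BRA%02d", i), st, 0, caps[1], sprintf("gB%02da", i))
      add(sprintf("BRB%02d", i), st, 0, caps[2], sprintf("gB%02db", i))
      cur <- nxt
    }
    st <- c(-1); names(st) <- cur
    add("BIOMASS", st, 0, 1000, "", exchange = TRUE)
    n <- length(rxn)
    S <- Matrix::Matrix(0, length(mets), n, sparse = TRUE,
                        dimnames = list(mets, vapply(rxn, `[[`, "", "id")))
    for (j in seq_len(n)) S[names(rxn[[j]]$stoich), j] <- rxn[[j]]$stoich
    stoich_model(mets, colnames(S), S,
                 lb = vapply(rxn, `[[`, 0, "lb"),
                 ub = vapply(rxn, `[[`, 0, "ub"),
                 gpr = vapply(rxn, `[[`, "", "gpr"),
                 objective = "BIOMASS",
                 exchange = vapply(rxn, `[[`, FALSE, "exchange"))
  })
}

#' Generate a planted regulon
#'
#' Assigns each transcription factor a set of target genes with signed linear
#' influence strengths (\code{+effect_size} for activators,
#' \code{-effect_size} for repressors) and an evidence label. \code{direct}
#' edges stand for influences with physical binding evidence whose loss of an
#' activating TF abolishes target function; \code{indirect} edges shape
#' expression but carry no causal effect on enzyme availability.
#'
#' @param n_tfs number of transcription factors (named \code{TF1}, ...).
#' @param targets_per_tf targets drawn per TF (without replacement).
#' @param genes gene pool to draw targets from (typically
#'   \code{model_genes(model)}).
#' @param activator_fraction fraction of edges that are activators, in [0,1].
#' @param effect_size absolute influence strength.
#' @param direct_fraction fraction of edges labelled \code{direct}.
#' @param seed integer seed.
#' @return an \code{influence_network} with an extra \code{strength} column.
#' @export
make_regulon <- function(n_tfs, targets_per_tf, genes,
                         activator_fraction = 0.7, effect_size = 2,
                         direct_fraction = 0.5, seed = 1) {
  if (activator_fraction < 0 || activator_fraction > 1)
    stop("activator_fraction must lie in [0,1]")
  stopifnot(n_tfs >= 0, targets_per_tf >= 0)
  tfs <- sprintf("TF%d", seq_len(n_tfs))
  if (n_tfs == 0 || targets_per_tf == 0) {
    return(influence_network(data.frame(
      tf = character(0), target = character(0), evidence = character(0),
      sign = character(0), fdr = numeric(0), prom_prob = numeric(0),
      strength = numeric(0))))
  }
  if (targets_per_tf > length(genes))
    stop("targets_per_tf exceeds the size of the gene pool")
  with_seed(substream_seed(seed, "regulon"), {
    rows <- lapply(tfs, function(tf) {
      tg <- sample(genes, targets_per_tf)
      act <- stats::runif(targets_per_tf) < activator_fraction
      dir <- stats::runif(targets_per_tf) < direct_fraction
      data.frame(tf = tf, target = tg,
                 evidence = ifelse(dir, "direct", "indirect"),
                 sign = ifelse(act, "activator", "repressor"),
                 fdr = NA_real_, prom_prob = NA_real_,
                 strength = ifelse(act, effect_size, -effect_size),
                 stringsAsFactors = FALSE)
    })
    influence_network(do.call(rbind, rows))
  })
}

#' Simulate an expression compendium from a planted regulon
#'
#' TF expression is standard normal per sample; in a fraction of samples one
#' randomly chosen TF is clamped to its minimum observed value (emulating a
#' perturbation/knockout array, and keeping ON/OFF binarization meaningful).
#' Each target gene is the sum of its signed TF influences plus Gaussian
#' noise; decoy genes are pure noise.
#'
#' @param network an \code{influence_network} with a \code{strength} column
#'   (see [make_regulon()]).
#' @param n_samples number of samples (arrays).
#' @param noise_sd standard deviation of additive expression noise.
#' @param knockout_fraction fraction of samples carrying a TF clamp.
#' @param n_decoys number of unregulated pure-noise genes.
#' @param seed integer seed.
#' @return numeric genes x samples matrix (TFs, targets, then decoys).
#' @export
simulate_expression <- function(network, n_samples = 200, noise_sd = 0.2,
                                knockout_fraction = 0.2, n_decoys = 6,
                                seed = 1) {
  if (is.null(network$strength))
    stop("network must carry a 'strength' column (see make_regulon)")
  tfs <- sort(unique(network$tf))
  targets <- sort(unique(network$target))
  with_seed(substream_seed(seed, "expression"), {
    tf_mat <- matrix(stats::rnorm(length(tfs) * n_samples),
                     nrow = length(tfs),
                     dimnames = list(tfs, sprintf("S%03d", seq_len(n_samples))))
    n_ko <- floor(knockout_fraction * n_samples)
    if (n_ko > 0 && length(tfs)) {
      ko_samples <- sample(n_samples, n_ko)
      ko_tf <- sample(length(tfs), n_ko, replace = TRUE)
      mins <- apply(tf_mat, 1, min)
      tf_mat[cbind(ko_tf, ko_samples)] <- mins[ko_tf]
    }
    tgt_mat <- matrix(0, length(targets), n_samples,
                      dimnames = list(targets, colnames(tf_mat)))
    for (i in seq_along(targets)) {
      ed <- network[network$target == targets[i], ]
      sig <- crossprod(matrix(ed$strength, ncol = 1),
                       tf_mat[ed$tf, , drop = FALSE])
      tgt_mat[i, ] <- as.vector(sig) + stats::rnorm(n_samples, sd = noise_sd)
    }
    dec_mat <- if (n_decoys > 0) {
      matrix(stats::rnorm(n_decoys * n_samples), n_decoys, n_samples,
             dimnames = list(sprintf("decoy%d", seq_len(n_decoys)),
                             colnames(tf_mat)))
    } else NULL
    rbind(tf_mat, tgt_mat, dec_mat)
  })
}

#' Ground-truth TF-knockout growth ratios
#'
#' Computes the "true" mutant/wild-type growth ratio for each planted TF by
#' treating the TF's activator edges as gene losses (the activating input is
#' gone, so the target enzyme is not produced), deleting those genes through
#' the GPR rules and re-running FBA. By default only \code{direct} edges are
#' causal; \code{indirect} edges have no effect on enzyme availability.
#'
#' @param model a \code{stoich_model}.
#' @param network the planted \code{influence_network}.
#' @param evidence \code{"direct"} (default) or \code{"all"}: which activator
#'   edges are treated as causal gene losses.
#' @return named numeric vector, one mutant/wild-type ratio per TF.
#' @export
simulate_truth_phenotypes <- function(model, network,
                                      evidence = c("direct", "all")) {
  evidence <- match.arg(evidence)
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective <= 0)
    stop("wild-type model has no positive growth optimum")
  tfs <- sort(unique(network$tf))
  ratios <- vapply(tfs, function(tf) {
    sel <- network$tf == tf & network$sign == "activator" &
      (evidence == "all" | network$evidence == "direct")
    lost <- intersect(network$target[sel], model$genes)
    if (!length(lost)) return(1)
    res <- fba(delete_genes(model, lost))
    if (res$status != "optimal") return(0)
    max(0, res$objective) / wt$objective
  }, numeric(1))
  names(ratios) <- tfs
  ratios
}

#' Generate a complete synthetic benchmark fixture
#'
#' Bundles [make_toy_model()], [make_regulon()], [simulate_expression()] and
#' [simulate_truth_phenotypes()] into one ground-truth object. The defaults
#' define the standard benchmark used throughout the package's recovery
#' tests: 5 TFs with 8 targets each drawn from a ~30-gene toy metabolic
#' network, influence strength 2.0 against noise sd 0.2, 6 decoy genes and a
#' 200-sample compendium with 20% TF-clamp samples.
#'
#' @param n_tfs,targets_per_tf,activator_fraction,direct_fraction,effect_size
#'   regulon parameters, see [make_regulon()].
#' @param n_samples,noise_sd,knockout_fraction,n_decoys compendium
#'   parameters, see [simulate_expression()].
#' @param n_linear,n_isozyme_pairs,n_branches model topology, see
#'   [make_toy_model()].
#' @param seed integer seed driving all substreams.
#' @return list of class \code{idream_fixture} with elements \code{model},
#'   \code{network} (planted truth), \code{expression},
#'   \code{true_growth_ratios} and \code{config}.
#' @export
make_fixture <- function(n_tfs = 5, targets_per_tf = 8,
                         activator_fraction = 0.7, direct_fraction = 0.5,
                         effect_size = 2, n_samples = 200, noise_sd = 0.2,
                         knockout_fraction = 0.2, n_decoys = 6,
                         n_linear = 12, n_isozyme_pairs = 4, n_branches = 3,
                         seed = 1) {
  model <- make_toy_model(n_linear, n_isozyme_pairs, n_branches, seed = seed)
  network <- make_regulon(n_tfs, targets_per_tf, model_genes(model),
                          activator_fraction = activator_fraction,
                          effect_size = effect_size,
                          direct_fraction = direct_fraction, seed = seed)
  expression <- simulate_expression(network, n_samples = n_samples,
                                    noise_sd = noise_sd,
                                    knockout_fraction = knockout_fraction,
                                    n_decoys = n_decoys, seed = seed)
  truth <- simulate_truth_phenotypes(model, network)
  cfg <- list(n_tfs = n_tfs, targets_per_tf = targets_per_tf,
              activator_fraction = activator_fraction,
              direct_fraction = direct_fraction, effect_size = effect_size,
              n_samples = n_samples, noise_sd = noise_sd,
              knockout_fraction = knockout_fraction, n_decoys = n_decoys,
              n_linear = n_linear, n_isozyme_pairs = n_isozyme_pairs,
              n_branches = n_branches, seed = seed)
  structure(list(model = model, network = network, expression = expression,
                 true_growth_ratios = truth, config = cfg),
            class = "idream_fixture")
}

#' @export
print.idream_fixture <- function(x, ...) {
  cat("idream_fixture: seed", x$config$seed, "\n")
  print(x$model)
  print(x$network)
  cat("expression:", nrow(x$expression), "genes x", ncol(x$expression),
      "samples\n")
  invisible(x)
}

#' Write a fixture to a directory of plain-text files
#'
#' Emits \code{model.json}, \code{network.tsv}, \code{expression.tsv},
#' \code{phenotypes.tsv} and \code{config.json}.
#'
#' @param fixture an \code{idream_fixture}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(fixture$model, file.path(dir, "model.json"))
  write_network(fixture$network, file.path(dir, "network.tsv"))
  write_expression(fixture$expression, file.path(dir, "expression.tsv"))
  ph <- data.frame(tf = names(fixture$true_growth_ratios),
                   condition = "synthetic",
                   growth_ratio = as.numeric(fixture$true_growth_ratios))
  write_phenotypes(ph, file.path(dir, "phenotypes.tsv"))
  jsonlite::write_json(fixture$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
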