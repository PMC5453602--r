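# small planted-regulator expression sets used across the inference tests
planted_expression <- function(n_samples = 100, noise_sd = 0.05, seed = 1,
                               beta = 2) {
  set.seed(seed)
  tfs <- matrix(rnorm(6 * n_samples), 6, n_samples,
                dimnames = list(paste0("tf", 1:6), paste0("s", seq_len(n_samples))))
  y <- beta * tfs["tf1", ] + rnorm(n_samples, sd = noise_sd)
  rbind(tfs, tg = y)
}

test_that("lasso identifies a planted regulator with the right sign", {
  ex <- planted_expression(n_samples = 100, noise_sd = 0.05, seed = 1)
  sel <- fit_regulator_model(ex, paste0("tf", 1:6), "tg")
  expect_true("tf1" %in% names(sel))
  expect_gt(sel[["tf1"]], 0)

  # exact anti-correlation, no noise
  ex2 <- planted_expression(noise_sd = 0, seed = 2, beta = -1)
  sel2 <- fit_regulator_model(ex2, paste0("tf", 1:6), "tg")
  expect_true("tf1" %in% names(sel2))
  expect_lt(sel2[["tf1"]], 0)
})

test_that("null targets yield empty or near-empty selections", {
  n_sel <- vapply(1:10, function(seed) {
    set.seed(seed)
    ex <- matrix(rnorm(7 * 100), 7, 100,
                 dimnames = list(c(paste0("tf", 1:6), "tg"), NULL))
    length(fit_regulator_model(ex, paste0("tf", 1:6), "tg"))
  }, numeric(1))
  expect_lte(mean(n_sel), 0.5)
})

test_that("degenerate inputs are handled per contract", {
  ex <- planted_expression()
  ex["tg", ] <- 1  # constant target: empty selection, not an error
  expect_length(fit_regulator_model(ex, paste0("tf", 1:6), "tg"), 0)
  expect_error(fit_regulator_model(ex, paste0("tf", 1:6), "tg",
                                   sample_subset = 1:5),
               "too small")
  expect_error(fit_regulator_model(ex, c("tf1", "tg"), "tg"), "must not be among")
})

test_that("bootstrap tally counts planted regulators and is deterministic", {
  ex <- planted_expression(n_samples = 120, noise_sd = 0.1, seed = 3)
  tal <- bootstrap_tally(ex, paste0("tf", 1:6), "tg", n_subsets = 50, seed = 7)
  expect_s3_class(tal, "bootstrap_tally")
  expect_gte(tal$counts[["tf1"]] / 50, 0.9)
  expect_true(all(tal$counts <= 50))
  tal2 <- bootstrap_tally(ex, paste0("tf", 1:6), "tg", n_subsets = 50, seed = 7)
  expect_identical(tal$counts, tal2$counts)

  tal1 <- bootstrap_tally(ex, paste0("tf", 1:6), "tg", n_subsets = 1, seed = 1)
  expect_true(all(tal1$counts %in% c(0L, 1L)))
})

test_that("tally FDR follows the 1 - count/n rule", {
  expect_equal(fdr_from_tally(191, 200), 0.045)
  expect_identical(fdr_from_tally(200, 200), 0)
  expect_identical(fdr_from_tally(0, 200), 1)
  expect_error(fdr_from_tally(201, 200), "count must lie")
  expect_error(fdr_from_tally(-1, 200), "count must lie")
  # strictly decreasing in count, always within [0,1]
  f <- fdr_from_tally(0:200, 200)
  expect_true(all(diff(f) < 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("sign classification uses marginal Pearson correlation", {
  set.seed(4)
  tf <- rnorm(50)
  ex <- rbind(tf = tf, up = tf + rnorm(50, sd = 0.3), down = -tf)
  expect_identical(classify_sign(ex, "tf", "up"), "activator")
  expect_identical(classify_sign(ex, "tf", "down"), "repressor")
  ex["tf", ] <- 1
  expect_error(classify_sign(ex, "tf", "up"), "constant")
})

test_that("network inference recovers a planted regulon at FDR 0.05", {
  # 3 TFs x 6 targets, strong effects, plus decoys
  net <- make_regulon(3, 6, paste0("g", 1:18), activator_fraction = 0.6,
                      effect_size = 2, seed = 11)
  ex <- simulate_expression(net, n_samples = 150, noise_sd = 0.1,
                            n_decoys = 2, seed = 11)
  inf <- infer_network(ex, tfs = network_tfs(net), n_subsets = 20, seed = 11)
  key <- function(df) paste(df$tf, df$target)
  expect_true(all(key(net) %in% key(inf)))      # full sensitivity
  expect_true(all(key(inf) %in% key(net)))      # no false edges
  m <- match(key(inf), key(net))
  expect_identical(inf$sign, net$sign[m])       # signs recovered
  expect_true(all(inf$fdr <= 0.05))
  expect_identical(unique(inf$evidence), "indirect")

  # invariant to sample ordering (edge set and signs)
  perm <- sample(ncol(ex))
  inf2 <- infer_network(ex[, perm], tfs = network_tfs(net), n_subsets = 20,
                        seed = 11)
  expect_setequal(key(inf2), key(inf))
})

test_that("pure-noise expression yields no edges at cutoff 0.05", {
  set.seed(21)
  ex <- matrix(rnorm(8 * 120), 8, 120,
               dimnames = list(c(paste0("TF", 1:3), paste0("g", 1:5)), NULL))
  inf <- infer_network(ex, tfs = paste0("TF", 1:3), n_subsets = 10, seed = 5)
  expect_equal(nrow(inf), 0)
})

test_that("cutoff 0 keeps only unanimously selected edges", {
  net <- make_regulon(2, 3, paste0("g", 1:6), effect_size = 3, seed = 2)
  ex <- simulate_expression(net, n_samples = 120, noise_sd = 0.05,
                            n_decoys = 1, seed = 2)
  inf <- infer_network(ex, tfs = network_tfs(net), n_subsets = 10,
                       fdr_cutoff = 0, seed = 3)
  expect_true(all(inf$fdr == 0))
})

test_that("evidence annotation marks reference-supported edges direct", {
  ref <- influence_network(data.frame(
    tf = c("TF1", "TF1"), target = c("g1", "g2"),
    evidence = c("direct", "indirect"), sign = "activator"))
  net <- influence_network(data.frame(
    tf = c("TF1", "TF1", "TF2"), target = c("g1", "g2", "g1"),
    evidence = "indirect", sign = "activator"))
  out <- annotate_evidence(net, ref)
  expect_identical(out$evidence, c("direct", "indirect", "indirect"))
})
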