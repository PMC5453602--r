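test_that("MCC handles perfect, inverted and worked examples", {
  expect_equal(mcc(5, 5, 0, 0), 1)
  expect_equal(mcc(0, 0, 5, 5), -1)
  expect_equal(as.numeric(mcc(2, 3, 1, 4)), 2 / sqrt(504))
  expect_error(mcc(0, 0, 0, 0), "all confusion counts are zero")
  expect_error(mcc(-1, 2, 3, 4), ">= 0")
  z <- mcc(3, 0, 0, 2)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "zero_denominator"))
})

test_that("MCC equals the brute-force phi coefficient", {
  set.seed(99)
  for (i in 1:200) {
    counts <- rmultinom(1, size = sample(4:40, 1), prob = runif(4, 0.05, 1))
    tp <- counts[1]; tn <- counts[2]; fp <- counts[3]; fn <- counts[4]
    pred <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
    obs <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
    if (sd(pred) == 0 || sd(obs) == 0) {
      expect_equal(as.numeric(mcc(tp, tn, fp, fn)), 0)
    } else {
      expect_equal(as.numeric(mcc(tp, tn, fp, fn)), cor(pred, obs),
                   tolerance = 1e-12)
    }
  }
})

test_that("growth-defect calls binarize strictly below the threshold", {
  expect_true(binarize_growth_calls(0.4, 0.5))
  expect_false(binarize_growth_calls(0.5, 0.5))
  expect_error(binarize_growth_calls(0.4, 0), "strictly in")
  # defect count is monotone non-decreasing in the threshold
  set.seed(12)
  r <- runif(50)
  counts <- vapply(seq(0.1, 0.95, by = 0.05),
                   function(th) sum(binarize_growth_calls(r, th)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the MCC threshold sweep flags undefined thresholds", {
  obs <- c(0.05, 0.1, 0.3, 0.8, 0.9, 1)
  sweep <- mcc_threshold_sweep(obs, obs)
  # where both classes occur, a perfect predictor scores 1
  defined <- !is.na(sweep)
  expect_true(any(defined))
  expect_true(all(sweep[defined] == 1))
  # below the smallest observation the truth is single-class: undefined
  expect_true(is.na(sweep[["0.10"]]) || min(obs) < 0.1)
  expect_error(mcc_threshold_sweep(1:3 / 4, 1:4 / 5), "length")
})

test_that("independent predictions give small MCCs across the sweep", {
  set.seed(6)
  obs <- runif(50)
  pred <- sample(obs)
  sweep <- mcc_threshold_sweep(pred, obs)
  expect_true(all(abs(sweep[!is.na(sweep)]) <= 0.3))
})

test_that("Pearson helpers implement the standard definitions", {
  set.seed(3)
  x <- rnorm(30); y <- x + rnorm(30)
  pw <- pearson_with_pvalue(x, y)
  ct <- cor.test(x, y)
  expect_equal(pw$r, unname(ct$estimate))
  expect_equal(pw$p, ct$p.value)
  expect_error(pearson_with_pvalue(1:3, 1:3), "at least 4")

  expect_equal(fisher_z_compare(0.5, 40, 0.5, 40), 1)
  # closed form: z = atanh(0.8)/sqrt(2/97)
  p <- fisher_z_compare(0.8, 100, 0, 100)
  expect_lt(p, 0.001)
  expect_equal(p, 2 * pnorm(-atanh(0.8) / sqrt(2 / 97)), tolerance = 1e-12)
  expect_error(fisher_z_compare(1, 10, 0.5, 10), "< 1")
  expect_error(fisher_z_compare(0.5, 3, 0.5, 10), "n > 3")
})

test_that("residual t-test separates a biased predictor", {
  set.seed(5)
  obs <- runif(30)
  pred_a <- obs + rnorm(30, sd = 0.05)
  pred_b <- obs + 0.5 + rnorm(30, sd = 0.05)
  expect_lt(residual_ttest(pred_a, pred_b, obs), 0.01)
  expect_error(residual_ttest(obs, obs, obs), "degenerate")
})

test_that("AUC follows the Mann-Whitney convention with ties half", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(1, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  auc_brute <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(41)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    l <- rbinom(n, 1, 0.5)
    if (sum(l) %in% c(0, n)) next
    expect_equal(roc_auc(s, l), auc_brute(s, l), tolerance = 1e-12)
    expect_equal(roc_auc(s, l),
                 as.numeric(pROC::auc(l, s, direction = "<", quiet = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("permutation p-values are deterministic and bounded", {
  set.seed(2)
  ex <- matrix(rnorm(3 * 20), 3, 20, dimnames = list(c("a", "b", "c"), NULL))
  net <- influence_network(data.frame(tf = "a", target = c("b", "c")))
  obs_calls <- rep(c(TRUE, FALSE), 10)
  pipeline <- function(expression, network) {
    calls <- expression["a", ] > stats::median(expression["a", ])
    as.numeric(mcc(sum(calls & obs_calls), sum(!calls & !obs_calls),
                   sum(calls & !obs_calls), sum(!calls & obs_calls)))
  }
  p1 <- permutation_test(pipeline, pipeline(ex, net), ex, net,
                         "expression", n_perm = 50, seed = 9)
  p2 <- permutation_test(pipeline, pipeline(ex, net), ex, net,
                         "expression", n_perm = 50, seed = 9)
  expect_identical(p1, p2)
  expect_true(p1 >= 0 && p1 <= 1)
  # nothing scores below the MCC floor
  expect_equal(permutation_test(pipeline, -1, ex, net, "expression",
                                n_perm = 30, seed = 1), 1)
  expect_error(permutation_test(pipeline, 0, ex, net, n_perm = 0), "n_perm")
})

test_that("network permutation rewires targets but keeps structure", {
  net <- influence_network(data.frame(
    tf = rep(c("T1", "T2"), each = 3),
    target = c("a", "b", "c", "b", "c", "d"),
    evidence = "direct", sign = "activator", fdr = 0.01))
  seen <- new.env()
  pipeline <- function(expression, network) {
    expect_identical(sort(unique(network$tf)), c("T1", "T2"))
    expect_equal(nrow(network), 6)
    expect_true(all(network$target %in% c("a", "b", "c", "d")))
    expect_true(all(network$evidence == "direct"))
    assign(paste(network$target, collapse = ""), TRUE, envir = seen)
    0
  }
  ex <- matrix(0, 1, 1, dimnames = list("a", NULL))
  p <- permutation_test(pipeline, -1, ex, net, "network", n_perm = 20, seed = 4)
  expect_equal(p, 1)
  expect_gt(length(ls(seen)), 1)  # connections actually vary
})

test_that("null-pipeline permutation p-values are approximately uniform", {
  net <- influence_network(data.frame(tf = "t", target = "g"))
  pvals <- vapply(1:200, function(r) {
    set.seed(r + 1000)
    ex <- matrix(rnorm(40), 2, 20, dimnames = list(c("g1", "g2"), NULL))
    pipeline <- function(expression, network) mean(expression["g1", 1:7])
    permutation_test(pipeline, pipeline(ex, net), ex, net, "expression",
                     n_perm = 99, seed = r)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("evaluate_predictions bundles the report consistently", {
  set.seed(6)
  obs <- runif(40)
  pred <- pmin(1, pmax(0, obs + rnorm(40, sd = 0.1)))
  rep <- evaluate_predictions(pred, obs)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$pcc, cor(pred, obs))
  expect_equal(rep$sse, sum((pred - obs)^2))
  expect_equal(rep$sse_per_n, rep$sse / 40)
  expect_equal(rep$sse_normalized, rep$sse / sum((obs - mean(obs))^2))
  expect_equal(rep$mean_abs_residual, mean(abs(pred - obs)))
  expect_true(all(rep$auc_by_threshold >= 0 & rep$auc_by_threshold <= 1,
                  na.rm = TRUE))
  expect_output(print(rep), "eval_report")
})
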