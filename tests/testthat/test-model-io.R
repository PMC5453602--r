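test_that("native JSON model round-trips structurally intact", {
  m <- make_toy_model(3, 1, 1, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$reaction_ids, m$reaction_ids)
  expect_identical(m2$metabolite_ids, m$metabolite_ids)
  expect_equal(as.matrix(m2$S), as.matrix(m$S))
  expect_equal(m2$lb, m$lb)
  expect_equal(m2$ub, m$ub)
  expect_identical(m2$gpr, m$gpr)
  expect_identical(m2$objective, m$objective)
  expect_identical(m2$exchange, m$exchange)
  # write(read(x)) == read(x): a second round trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("minimal JSON model parses and invariant violations are rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "metabolites": ["A", "B"],
    "reactions": [
      {"id": "EX", "stoich": {"A": 1}, "lb": 0, "ub": 10, "gpr": "", "exchange": true},
      {"id": "AB", "stoich": {"A": -1, "B": 1}, "lb": 0, "ub": 5, "gpr": "g1"},
      {"id": "BIO", "stoich": {"B": -1}, "lb": 0, "ub": 1000}
    ],
    "objective": "BIO"
  }', path)
  m <- read_model(path)
  expect_length(m$reaction_ids, 3)
  expect_identical(model_genes(m), "g1")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "metabolites": ["A"],
    "reactions": [{"id": "EX", "stoich": {"A": 1}, "lb": 3, "ub": 1}],
    "objective": "EX"
  }', bad)
  expect_error(read_model(bad), "lower_bound > upper_bound.*EX")

  noobj <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "metabolites": ["A"],
    "reactions": [{"id": "EX", "stoich": {"A": 1}, "lb": 0, "ub": 1}]
  }', noobj)
  expect_error(read_model(noobj), "objective")
})

test_that("stoich_model validates its invariants", {
  expect_error(stoich_model("A", c("R1", "R1"), matrix(1, 1, 2),
                            c(0, 0), c(1, 1), objective = "R1"),
               "duplicate reaction")
  expect_error(stoich_model("A", "R1", matrix(1, 1, 1), 0, 1,
                            objective = "R9"),
               "objective")
  expect_error(stoich_model("A", "R1", matrix(1, 1, 1), 0, 1,
                            gpr = "g1 and", objective = "R1"),
               "GPR parse error")
})

test_that("SBML L3 fbc ingestion maps onto the native container", {
  m <- read_model(test_path("fixtures", "mini_fbc.sbml.xml"), format = "sbml")
  expect_identical(m$reaction_ids, c("EX_in", "AB", "BIOMASS"))
  expect_identical(m$objective, "BIOMASS")
  expect_identical(m$gpr[2], "(g1 or g2)")
  expect_identical(model_genes(m), c("g1", "g2"))
  expect_equal(m$ub, c(10, 5, 1000))
  # equivalent to the hand-built linear model with an isozyme pair
  expect_equal(fba(m)$objective, 5)
})

test_that("network TSV reader enforces tokens, ranges and uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf\ttarget\tevidence\tsign\tfdr\tprom_prob",
               "TF1\tg1\tdirect\tactivator\t0.02\t0.4",
               "TF1\tg2\tindirect\trepressor\t0.05\tNA",
               "TF2\tg1\tdirect\tunknown\tNA\t0.9"), path)
  net <- read_network(path)
  expect_s3_class(net, "influence_network")
  expect_equal(nrow(net), 3)
  expect_identical(network_tfs(net), c("TF1", "TF2"))
  rt <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, rt)
  expect_equal(as.data.frame(read_network(rt)), as.data.frame(net))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf\ttarget\tevidence\tsign\tfdr\tprom_prob",
               "TF1\tg1\tdirect\tactivator\t0.02\t0.4",
               "TF1\tg1\tdirect\tactivator\t0.03\t0.4"), dup)
  expect_error(read_network(dup), "duplicate edge")

  badfdr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf\ttarget\tevidence\tsign\tfdr\tprom_prob",
               "TF1\tg1\tdirect\tactivator\t1.2\tNA"), badfdr)
  expect_error(read_network(badfdr), "fdr out of \\[0,1\\]")

  badtok <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf\ttarget\tevidence\tsign\tfdr\tprom_prob",
               "TF1\tg1\tchip-seq\tactivator\t0.1\tNA"), badtok)
  expect_error(read_network(badtok), "unknown evidence token.*edge 1")
})

test_that("expression TSV reader validates shape and values", {
  ex <- matrix(rnorm(50), 5, 10,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(ex, path)
  ex2 <- read_expression(path)
  expect_equal(ex2, ex)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), dup)
  expect_error(read_expression(dup), "duplicate gene id.*g1")

  nan <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\tNaN"), nan)
  expect_error(read_expression(nan), "non-finite")
})

test_that("phenotype TSV reader rejects negative growth ratios", {
  ok <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf\tcondition\tgrowth_ratio", "TF1\tglucose\t0.8",
               "TF2\tglucose\t0"), ok)
  ph <- read_phenotypes(ok)
  expect_equal(ph$growth_ratio, c(0.8, 0))
  rt <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(ph, rt)
  expect_equal(read_phenotypes(rt), ph)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf\tcondition\tgrowth_ratio", "TF1\tglucose\t-0.1"), bad)
  expect_error(read_phenotypes(bad), "negative growth_ratio.*TF1")
})

test_that("influence_network rejects self-edges and keeps extra columns", {
  expect_error(influence_network(data.frame(tf = "a", target = "a")),
               "self-edge")
  net <- influence_network(data.frame(tf = "a", target = "b", strength = 2))
  expect_equal(net$strength, 2)
  expect_identical(net$evidence, "indirect")
  expect_identical(net$sign, "unknown")
})
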