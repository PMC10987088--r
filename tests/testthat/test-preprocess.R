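design_for <- function(cues, sentinels) {
  enumerate_design(
    data.frame(drug = character(), stimulus = character(),
               with_anchor = logical()),
    stimuli = character(), inhibitors = c(FLT3i = cues[1]),
    sentinels = data.frame(analyte = sentinels,
                           activity = rep(1L, length(sentinels))))
}

test_that("compression collapses chains with the sign product", {
  d <- design_for("A", "C")
  # A -> B -> C, B undesignated
  net <- designate_nodes(causal_network(data.frame(
    source = c("A", "B"), target = c("B", "C"), sign = 1L)), d)
  cm <- compress(net, d)
  expect_equal(cm$nodes$name, c("A", "C"))
  expect_equal(cm$edges, data.frame(source = "A", target = "C", sign = 1L,
                                    provenance = "curated"))

  # A -| B -| C gives A -> C with sign (+1) = (-1)(-1)
  net <- designate_nodes(causal_network(data.frame(
    source = c("A", "B"), target = c("B", "C"), sign = -1L)), d)
  cm <- compress(net, d)
  expect_equal(cm$edges$sign, 1L)

  # undesignated sink B is deleted together with its edge
  net <- designate_nodes(causal_network(data.frame(
    source = "A", target = "B", sign = 1L)), d)
  cm <- compress(net, d)
  expect_false("B" %in% cm$nodes$name)
  expect_equal(nrow(cm$edges), 0)
})

test_that("compression protects designated nodes and preserves path signs", {
  d <- design_for("A", "E")
  # chain with two removable intermediates of mixed sign
  net <- designate_nodes(causal_network(data.frame(
    source = c("A", "B", "C"), target = c("B", "C", "E"),
    sign = c(1L, -1L, -1L))), d)
  cm <- compress(net, d)
  expect_setequal(cm$nodes$name, c("A", "E"))
  expect_equal(cm$edges$sign, 1L)  # (+1)(-1)(-1)

  # measured intermediate survives
  d2 <- design_for("A", c("B", "E"))
  net2 <- designate_nodes(causal_network(data.frame(
    source = c("A", "B", "C"), target = c("B", "C", "E"),
    sign = c(1L, -1L, -1L))), d2)
  cm2 <- compress(net2, d2)
  expect_true("B" %in% cm2$nodes$name)
  expect_false("C" %in% cm2$nodes$name)
})

test_that("large hubs and self-loop nodes are not bypassed", {
  d <- enumerate_design(
    data.frame(drug = character(), stimulus = character(),
               with_anchor = logical()),
    stimuli = character(),
    inhibitors = c(FLT3i = "A", Ui = "U1", Vi = "U2"),
    sentinels = data.frame(analyte = c("Z", "D1"), activity = c(1L, 1L)))
  # hub H with 3 protected inputs and 2 protected outputs: 6 > max_fan, kept
  e <- data.frame(
    source = c("A", "U1", "U2", "H", "H"),
    target = c("H", "H", "H", "Z", "D1"),
    sign = 1L)
  net <- designate_nodes(causal_network(e), d)
  cm <- compress(net, d, max_fan = 4)
  expect_true("H" %in% cm$nodes$name)
  expect_equal(nrow(cm$edges), 5)

  # self-loop node is deleted only when dangling, never bypassed
  e2 <- data.frame(source = c("A", "L", "L"), target = c("L", "L", "Z"),
                   sign = 1L)
  net2 <- designate_nodes(causal_network(e2), d)
  cm2 <- compress(net2, d)
  expect_true("L" %in% cm2$nodes$name)
})

test_that("expansion builds k single-input gates plus bounded AND combinations", {
  d <- design_for("A", "C")
  net <- designate_nodes(causal_network(data.frame(
    source = c("A", "B"), target = c("C", "C"), sign = c(1L, 1L))), d)
  sc <- expand(net, max_gate_inputs = 2)
  outC <- Filter(function(g) g$output == "C", sc$gates)
  expect_length(outC, 3)
  expect_equal(sc$n_and, 1)

  # gate-count formula: k singles + sum_{j=2..min(k,m)} C(k,j)
  for (k in 2:4) for (m in 2:4) {
    e <- data.frame(source = paste0("R", 1:k), target = "C", sign = 1L)
    neti <- designate_nodes(causal_network(e), d)
    sci <- expand(neti, max_gate_inputs = m)
    expected <- k + sum(vapply(2:min(k, m), function(j) choose(k, j),
                               numeric(1)))
    expect_length(Filter(function(g) g$output == "C", sci$gates), expected)
  }

  # single regulator: one gate, no AND operator
  net1 <- designate_nodes(causal_network(data.frame(
    source = "A", target = "C", sign = 1L)), d)
  sc1 <- expand(net1)
  expect_length(sc1$gates, 1)
  expect_equal(sc1$n_and, 0)
})

test_that("mixed-sign AND gates carry literal semantics into simulation", {
  d <- design_for("A", "C")
  net <- designate_nodes(causal_network(data.frame(
    source = c("A", "B"), target = c("C", "C"), sign = c(1L, -1L))), d)
  sc <- expand(net, max_gate_inputs = 2)
  and_gate <- which(vapply(sc$gates, function(g) length(g$inputs) == 2,
                           logical(1)))
  sel <- integer(length(sc$gates)); sel[and_gate] <- 1L
  m <- logic_model(sc, sel)
  on <- function(on, off) simulate_synchronous(m, list(on = on, off = off))$state[["C"]]
  expect_equal(on(c("A"), c("B")), 1L)   # A=1, B=0 fires
  expect_equal(on(c("A", "B"), character()), 0L)
})

test_that("correlation imputation screens pairs at the threshold with signs", {
  tr <- make_truth(n_nodes = 10, n_inhibitable = 5, n_sentinels = 4, seed = 5)
  raw <- simulate_dataset(tr, noise_sd = 0, seed = 5)
  ds <- normalize_dataset(raw, tr$design)
  a <- colnames(ds$t1)[1]; b <- colnames(ds$t1)[2]

  # construct a network with no edge between two perfectly correlated analytes
  ds2 <- ds
  ds2$t1[, b] <- ds2$t1[, a]
  net <- designate_nodes(causal_network(
    data.frame(source = "IGF1", target = a, sign = 1L),
    nodes = data.frame(name = c("IGF1", colnames(ds$t1)))), tr$design)
  imp <- impute_data_edges(net, ds2, r_threshold = 0.75)
  expect_true(any(imp$source == a & imp$target == b & imp$sign == 1L))
  expect_true(all(imp$provenance == "imputed"))

  # anti-correlated profile yields a negative-sign edge
  ds2$t1[, b] <- 1 - ds2$t1[, a]
  imp <- impute_data_edges(net, ds2, r_threshold = 0.75)
  expect_true(any(imp$source == a & imp$target == b & imp$sign == -1L))

  # a sub-threshold correlation adds nothing between that pair
  set.seed(1)
  ds2$t1[, b] <- runif(nrow(ds2$t1))
  r <- abs(cor(ds2$t1[, a], ds2$t1[, b]))
  expect_true(r < 0.75)
  imp <- impute_data_edges(net, ds2, r_threshold = 0.75)
  expect_false(any(imp$source == a & imp$target == b))

  # imputation is additive: curated edges survive the merge
  merged <- add_edges(net, imp)
  expect_true(all(paste(net$edges$source, net$edges$target) %in%
                    paste(merged$edges$source, merged$edges$target)))
})

test_that("scaffold serialization writes JSON and SIF with AND pseudo-nodes", {
  d <- design_for("A", "C")
  net <- designate_nodes(causal_network(data.frame(
    source = c("A", "B"), target = c("C", "C"), sign = c(1L, -1L))), d)
  sc <- expand(net, max_gate_inputs = 2)
  pj <- withr::local_tempfile(fileext = ".json")
  write_scaffold_json(sc, pj)
  parsed <- jsonlite::read_json(pj)
  expect_length(parsed$gates, 3)

  ps <- withr::local_tempfile(fileext = ".sif")
  write_scaffold_sif(sc, ps)
  lines <- readLines(ps)
  expect_true(any(grepl("^and1\t1\tC$", lines)))
  expect_true(any(grepl("^B\t-1\tand1$", lines)))
})
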