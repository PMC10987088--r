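# small scaffold + noise-free dataset generated from a known sub-selection,
# shared by the GA oracle tests
ga_fixture <- function(seed = 2, n_nodes = 8, n_sentinels = 4) {
  tr <- make_truth(n_nodes = n_nodes, n_inhibitable = 5,
                   n_sentinels = n_sentinels, seed = seed)
  raw <- simulate_dataset(tr, noise_sd = 0, seed = seed)
  list(truth = tr, dataset = normalize_dataset(raw, tr$design))
}

test_that("the GA attains the exhaustive-search optimum on small scaffolds", {
  fx <- ga_fixture(seed = 2)
  tr <- fx$truth
  # restrict to a sub-scaffold of <= 12 gates so 2^G enumeration is exact:
  # keep all truth gates plus the first decoy gates
  ordered <- c(tr$truth_gates,
               setdiff(seq_along(tr$scaffold$gates), tr$truth_gates))
  keep <- sort(utils::head(ordered, 12))
  sub <- tr$scaffold
  sub$gates <- sub$gates[keep]
  sub$n_and <- sum(vapply(sub$gates, function(g) length(g$inputs) >= 2,
                          logical(1)))
  brute <- oracle_exhaustive(sub, fx$dataset, tr$design)
  g <- ga_optimize(sub, fx$dataset, tr$design, ga_params(seed = 7))
  expect_equal(g$fitness$total, brute$total, tolerance = 1e-12)
})

test_that("the GA is deterministic given its seed", {
  fx <- ga_fixture(seed = 2)
  a <- ga_optimize(fx$truth$scaffold, fx$dataset, fx$truth$design,
                   ga_params(seed = 5))
  b <- ga_optimize(fx$truth$scaffold, fx$dataset, fx$truth$design,
                   ga_params(seed = 5))
  expect_identical(a$selection, b$selection)
  expect_equal(a$fitness$total, b$fitness$total)
})

test_that("degenerate training inputs are rejected", {
  fx <- ga_fixture(seed = 2)
  empty <- fx$truth$scaffold
  empty$gates <- list()
  expect_error(ga_optimize(empty, fx$dataset, fx$truth$design), "empty scaffold")
  masked <- fx$dataset
  masked$t1[] <- NA
  expect_error(ga_optimize(fx$truth$scaffold, masked, fx$truth$design),
               "no fit points")
})

test_that("families are sorted, sized and seeded as requested", {
  fx <- ga_fixture(seed = 2)
  p <- ga_params(pop_size = 20, generations = 30, stall = 10)
  fam <- build_family(fx$truth$scaffold, fx$dataset, fx$truth$design,
                      n_runs = 10, keep = 3, base_seed = 100, params = p)
  expect_length(fam$members, 3)
  totals <- vapply(fam$members, function(m) m$fitness$total, numeric(1))
  expect_true(all(diff(totals) >= 0))
  expect_true(all(vapply(fam$members, `[[`, numeric(1), "seed") %in% 100:109))

  all_kept <- build_family(fx$truth$scaffold, fx$dataset, fx$truth$design,
                           n_runs = 4, keep = 4, base_seed = 100, params = p)
  expect_length(all_kept$members, 4)
  expect_error(build_family(fx$truth$scaffold, fx$dataset, fx$truth$design,
                            n_runs = 2, keep = 3), "n_runs >= keep")
})

test_that("edge frequencies are family fractions", {
  fx <- ga_fixture(seed = 2)
  G <- length(fx$truth$scaffold$gates)
  fam <- structure(list(
    scaffold = fx$truth$scaffold,
    members = list(
      list(selection = rep(1L, G), fitness = list(total = 0.1), seed = 1),
      list(selection = rep(0L, G), fitness = list(total = 0.2), seed = 2),
      list(selection = c(1L, rep(0L, G - 1)), fitness = list(total = 0.3),
           seed = 3)),
    n_runs = 3), class = "model_family")
  freq <- edge_frequencies(fam)
  expect_equal(unname(freq[1]), 2 / 3)
  expect_equal(unname(freq[2]), 1 / 3)
  expect_length(freq, G)
})

test_that("best-model selection breaks ties by size then bitstring", {
  sc <- structure(list(species = c("A", "B"),
                       gates = list(
                         list(output = "B", inputs = "A", signs = 1L,
                              provenance = "curated"),
                         list(output = "A", inputs = "B", signs = 1L,
                              provenance = "curated")),
                       n_and = 0, measured = character(),
                       targeted = character()), class = "scaffold_model")
  mk <- function(sel, tot, seed) list(selection = sel,
                                      fitness = list(total = tot), seed = seed)
  fam <- structure(list(scaffold = sc, members = list(
    mk(c(1L, 1L), 0.12, 1), mk(c(0L, 1L), 0.10, 2), mk(c(1L, 0L), 0.10, 3)),
    n_runs = 3), class = "model_family")
  best <- select_best(fam)
  # tie at 0.10, equal sizes: lexicographically smaller "01" wins
  expect_equal(best$selection, c(0L, 1L))

  fam$members[[2]]$selection <- c(1L, 1L)
  best <- select_best(fam)  # tie broken by fewer gates
  expect_equal(best$selection, c(1L, 0L))
})

test_that("high-confidence restriction is strict at the threshold", {
  sc <- structure(list(species = "A",
                       gates = replicate(3, list(output = "A", inputs = "A",
                                                 signs = 1L,
                                                 provenance = "curated"),
                                         simplify = FALSE),
                       n_and = 0, measured = character(),
                       targeted = character()), class = "scaffold_model")
  best <- logic_model(sc, c(1L, 1L, 1L))
  hc <- high_confidence_submodel(best, c(0.9, 0.4, 0.41), threshold = 0.4)
  expect_equal(hc$selection, c(1L, 0L, 1L))
  expect_equal(high_confidence_submodel(best, c(0.5, 0.5, 0.5),
                                        threshold = 0)$selection,
               c(1L, 1L, 1L))
  expect_warning(high_confidence_submodel(best, c(0.1, 0.2, 0.3)),
                 "no gate")
  # threshold 1 keeps only unanimous gates
  expect_equal(suppressWarnings(
    high_confidence_submodel(best, c(1, 0.99, 1), threshold = 1))$selection,
    c(0L, 0L, 0L))
})

test_that("family serialization records seeds and fitness breakdowns", {
  fx <- ga_fixture(seed = 2)
  p <- ga_params(pop_size = 15, generations = 20, stall = 8)
  fam <- build_family(fx$truth$scaffold, fx$dataset, fx$truth$design,
                      n_runs = 3, keep = 2, base_seed = 7, params = p)
  path <- withr::local_tempfile(fileext = ".json")
  write_family_json(fam, path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed$members, 2)
  expect_true(all(vapply(parsed$members, function(m)
    nchar(m$selection) == length(fx$truth$scaffold$gates), logical(1))))
})
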