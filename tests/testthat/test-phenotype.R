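test_that("endpoint regulators are annotated terminal nodes only", {
  dm <- demo_model_pair()
  reg <- rbind(dm$regulators,
               data.frame(node = "AKT", phenotype = "proliferation",
                          effect = 1L))
  ep <- endpoint_regulators(dm$sensitive, reg)
  expect_equal(ep$apoptosis$node, "BAD")
  # AKT is annotated but relays into BAD/RPS6 gates: not an endpoint
  expect_false("AKT" %in% ep$proliferation$node)
  expect_true("RPS6" %in% ep$proliferation$node)

  # unannotated terminal node (ERK) is excluded
  expect_false("ERK" %in% unlist(lapply(ep, `[[`, "node")))

  reg_empty <- dm$regulators[dm$regulators$phenotype == "apoptosis", ]
  expect_warning(endpoint_regulators(dm$sensitive, reg_empty),
                 "no endpoint regulator for proliferation")
})

test_that("phenotype scores normalize signed endpoint sums into [-1, 1]", {
  ep <- list(
    apoptosis = data.frame(node = c("C3", "C7"), effect = c(1L, 1L)),
    proliferation = data.frame(node = c("M1", "M2"), effect = c(1L, -1L)))
  s <- c(C3 = 1, C7 = 1, M1 = 1, M2 = 0)
  sc <- phenotype_scores(s, ep)
  # all apoptosis activators ON: maximal apoptosis, inhibition = -1
  expect_equal(sc$apoptosis_inhibition, -1)
  # one activator ON, one inhibitor OFF over 2 endpoints
  expect_equal(sc$proliferation_activation, 0.5)

  # activator and inhibitor both ON cancel
  sc <- phenotype_scores(c(C3 = 0, C7 = 0, M1 = 1, M2 = 1), ep)
  expect_equal(sc$proliferation_activation, 0)
  expect_equal(sc$apoptosis_inhibition, 0)

  # two activators ON with no inhibitor: maximum
  ep2 <- list(apoptosis = data.frame(node = character(), effect = integer()),
              proliferation = data.frame(node = c("M1", "M2"),
                                         effect = c(1L, 1L)))
  sc <- phenotype_scores(c(M1 = 1, M2 = 1), ep2)
  expect_equal(sc$proliferation_activation, 1)
  expect_true(is.na(sc$apoptosis_inhibition))

  # unresolved endpoints enter as 0.5
  sc <- phenotype_scores(c(C3 = NA, C7 = 1, M1 = 0, M2 = 0), ep)
  expect_equal(sc$apoptosis_inhibition, -0.75)
})

test_that("screen conditions build the documented clamp sets", {
  dm <- demo_model_pair()
  ep <- endpoint_regulators(dm$sensitive, dm$regulators)

  unt <- run_condition(dm$sensitive, "untreated", ep)
  expect_equal(unname(unt$state$state[c("FLT3", "AKT", "RPS6", "BAD")]),
               c(1L, 1L, 1L, 0L))
  expect_equal(unt$scores$proliferation_activation, 1)
  expect_equal(unt$scores$apoptosis_inhibition, 0)

  fi <- run_condition(dm$sensitive, "FLT3i", ep)
  expect_equal(unname(fi$state$state[["FLT3"]]), 0L)
  expect_gt(unt$scores$proliferation_activation,
            fi$scores$proliferation_activation)
  expect_equal(fi$scores$apoptosis_inhibition, -1)

  # FLT3i+FLT3KO is identical to FLT3i
  ko <- run_condition(dm$sensitive, "FLT3i+FLT3KO", ep)
  expect_equal(ko$scores$proliferation_activation,
               fi$scores$proliferation_activation)
  expect_equal(ko$scores$apoptosis_inhibition, fi$scores$apoptosis_inhibition)

  expect_error(run_condition(dm$sensitive, "FLT3i+NOPEKO", ep),
               "unknown knockout")
  expect_error(run_condition(dm$sensitive, "weird", ep), "unrecognized")
})

test_that("knockout of a disconnected node is a no-op on the scores", {
  dm <- demo_model_pair()
  ep <- endpoint_regulators(dm$sensitive, dm$regulators)
  fi <- run_condition(dm$sensitive, "FLT3i", ep)$scores
  ko <- run_condition(dm$sensitive, "FLT3i+ERKKO", ep)$scores
  expect_equal(ko$apoptosis_inhibition, fi$apoptosis_inhibition)
  expect_equal(ko$proliferation_activation, fi$proliferation_activation)
})

test_that("the screen enumerates untreated, anchor and resolvable combos", {
  dm <- demo_model_pair()
  ep <- endpoint_regulators(dm$resistant, dm$regulators)
  scr <- ko_screen(dm$resistant, ep)
  expect_equal(scr$condition[1:2], c("untreated", "FLT3i"))
  expect_setequal(na.omit(scr$target), c("IGF1R", "JNK", "PI3K"))
  expect_setequal(attr(scr, "unresolved"),
                  c("ERK1/2", "MEK1/2", "GSK3A/B", "KRAS", "MTOR", "PDPK1",
                    "p38"))
  expect_false(anyDuplicated(scr$condition) > 0)

  # custom fully-resolvable target list: 2 + n rows
  scr2 <- ko_screen(dm$resistant, ep, targets = c("JNK", "PI3K", "AKT"))
  expect_equal(nrow(scr2), 5)
  scr0 <- ko_screen(dm$resistant, ep, targets = character())
  expect_equal(nrow(scr0), 2)
})

test_that("complex target labels expand to member nodes and clamp them all", {
  net <- causal_network(data.frame(
    source = c("FLT3", "ERK1", "ERK2"), target = c("ERK1", "OUT", "OUT"),
    sign = 1L))
  m <- logic_model(expand(net))
  reg <- data.frame(node = "OUT", phenotype = "proliferation", effect = 1L)
  class(reg) <- c("regulator_table", "data.frame")
  ep <- suppressWarnings(endpoint_regulators(m, reg))
  # ERK2 has no regulator: clamp both members so OUT really goes dark
  r <- run_condition(m, "FLT3i+ERK1/2KO", ep, receptors = "FLT3")
  expect_equal(unname(r$state$state[c("ERK1", "ERK2", "OUT")]), c(0L, 0L, 0L))
})

test_that("rescue calling is a conjunction over both phenotype axes", {
  dm <- demo_model_pair()
  ep_s <- endpoint_regulators(dm$sensitive, dm$regulators)
  ep_r <- endpoint_regulators(dm$resistant, dm$regulators)
  ref <- run_condition(dm$sensitive, "FLT3i", ep_s)$scores
  scr <- ko_screen(dm$resistant, ep_r)

  expect_equal(rescue_hits(scr, ref), "JNK")
  # a large epsilon saturates the bound: every combo is a hit
  expect_setequal(rescue_hits(scr, ref, epsilon = 2),
                  na.omit(scr$target))
  # better on one axis but worse on the other is not a hit
  fake <- scr
  fake$apoptosis_inhibition[fake$target == "JNK"] <- ref$apoptosis_inhibition + 0.1
  fake$proliferation_activation[fake$target == "JNK"] <-
    ref$proliferation_activation - 0.5
  expect_length(rescue_hits(fake, ref), 0)
})

test_that("scores are antitone in endpoint clamping", {
  dm <- demo_model_pair()
  ep <- endpoint_regulators(dm$resistant, dm$regulators)
  base <- run_condition(dm$resistant, "FLT3i", ep)$scores
  # forcing the apoptosis-activator endpoint ON never raises apoptosis_inhibition
  st <- simulate_synchronous(dm$resistant,
                             list(on = c("IGF1R", "TNFR", "BAD"),
                                  off = "FLT3"))
  forced <- phenotype_scores(st, ep)
  expect_lte(forced$apoptosis_inhibition, base$apoptosis_inhibition)
})
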