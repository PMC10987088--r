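chain_model <- function() {
  net <- causal_network(data.frame(source = c("A", "B"), target = c("B", "C"),
                                   sign = 1L))
  logic_model(expand(net))
}

test_that("a clamped chain propagates to a verified fixpoint", {
  m <- chain_model()
  st <- simulate_synchronous(m, list(on = "A", off = character()))
  expect_equal(unname(st$state[c("A", "B", "C")]), c(1L, 1L, 1L))
  expect_true(st$converged)
  expect_lte(st$iterations, 3 + 1)
  # re-applying the update to the fixpoint changes nothing
  st2 <- simulate_synchronous(m, list(on = "A", off = character()),
                              initial = st$state)
  expect_equal(st2$state, st$state)
  expect_equal(st2$iterations, 1)
})

test_that("a negative feedback loop oscillates and is reported unresolved", {
  # A -> B, B -| A from (1,0): (1,0) -> (1,1) -> (0,1) -> (0,0) -> (1,0)
  net <- causal_network(data.frame(source = c("A", "B"), target = c("B", "A"),
                                   sign = c(1L, -1L)))
  m <- logic_model(expand(net))
  st <- simulate_synchronous(m, initial = c(A = 1L, B = 0L))
  expect_equal(st$attractor, "cycle")
  expect_false(st$converged)
  expect_true(all(is.na(st$state)))
  # the oracle agrees on the period-4 trajectory
  o <- oracle_simulate(m, initial = c(A = 1L, B = 0L))
  expect_equal(o$attractor, "cycle")
  expect_equal(unname(o$state), unname(st$state))
})

test_that("fully clamped models reach the clamp state in one iteration", {
  m <- chain_model()
  st <- simulate_synchronous(m, list(on = c("A", "C"), off = "B"))
  expect_equal(unname(st$state[c("A", "B", "C")]), c(1L, 0L, 1L))
  expect_equal(st$iterations, 1)
  expect_true(st$converged)
})

test_that("clamped nodes never change and conflicting clamps are rejected", {
  m <- chain_model()
  st <- simulate_synchronous(m, list(on = "A", off = "B"))
  expect_equal(unname(st$state[["B"]]), 0L)
  expect_equal(unname(st$state[["C"]]), 0L)
  expect_error(simulate_synchronous(m, list(on = "A", off = "A")), "both")
  expect_error(simulate_synchronous(m, list(on = "Q", off = character())),
               "unknown node")
})

test_that("the simulator agrees with the naive trajectory oracle on random models", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    m <- random_model(n_nodes = n, n_gates = sample(2:12, 1), seed = 1000 + i)
    species <- m$scaffold$species
    clamped <- sample(species, sample(0:2, 1))
    cond <- list(on = sample(clamped, floor(length(clamped) / 2)),
                 off = character())
    cond$off <- setdiff(clamped, cond$on)
    init <- stats::setNames(sample(0:1, n, replace = TRUE), species)
    got <- simulate_synchronous(m, cond, initial = init)
    want <- oracle_simulate(m, cond, initial = init)
    expect_equal(got$state, want$state)
    expect_equal(got$attractor, want$attractor)
    expect_equal(got$converged, want$converged)
  }
})

test_that("fitness is zero on perfect predictions and quadratic otherwise", {
  tr <- make_truth(n_nodes = 10, n_inhibitable = 5, n_sentinels = 4, seed = 3)
  raw <- simulate_dataset(tr, noise_sd = 0, seed = 3)
  ds <- normalize_dataset(raw, tr$design)
  # noiseless data equals the truth states up to the Hill endpoints 0.001/0.999
  f <- mse_fitness(tr$truth_model, ds, tr$design, theta_size = 0)
  expect_lt(f$mse, 1e-5)
  expect_equal(f$na_penalty, 0)

  # single-cell arithmetic: prediction 1 against 0.5 gives mse 0.25
  ds1 <- ds
  ds1$t1[] <- NA
  on_cond <- tr$design$conditions$name[9]  # a stimulus-only condition
  a <- colnames(ds$t1)[1]
  st <- simulate_synchronous(tr$truth_model,
                             condition_clamps(tr$design, on_cond))
  ds1$t1[on_cond, a] <- if (st$state[[a]] == 1L) 0.5 else 0.5
  f1 <- mse_fitness(tr$truth_model, ds1, tr$design, theta_size = 0)
  expect_equal(f1$n_points, 1)
  expect_equal(f1$mse, 0.25, tolerance = 1e-12)

  # masked cells are excluded from n_points
  ds2 <- ds
  ds2$t1[1, 1] <- NA
  f2 <- mse_fitness(tr$truth_model, ds2, tr$design)
  expect_equal(f2$n_points, f$n_points - 1)
})

test_that("fitness is invariant under condition reordering", {
  tr <- make_truth(n_nodes = 10, n_inhibitable = 5, n_sentinels = 4, seed = 3)
  raw <- simulate_dataset(tr, noise_sd = 0.05, seed = 4)
  ds <- normalize_dataset(raw, tr$design)
  f <- mse_fitness(tr$truth_model, ds, tr$design)

  perm <- sample(nrow(ds$t1))
  ds_p <- ds
  ds_p$t1 <- ds$t1[perm, , drop = FALSE]
  ds_p$t0 <- ds$t0[perm, , drop = FALSE]
  f_p <- mse_fitness(tr$truth_model, ds_p, tr$design)
  expect_equal(f_p$total, f$total, tolerance = 1e-12)
})

test_that("deselecting a wrong-prediction gate cannot worsen the fit", {
  # truth: A alone drives C; distractor gate B -> C is wrong under B=1
  net <- causal_network(data.frame(source = c("A", "B"), target = c("C", "C"),
                                   sign = 1L))
  nodes <- data.frame(name = c("A", "B", "C"),
                      is_measured = c(FALSE, FALSE, TRUE),
                      is_targeted = c(TRUE, TRUE, FALSE))
  net <- causal_network(net$edges, nodes)
  sc <- expand(net, max_gate_inputs = 2)
  conditions <- data.frame(name = c("ctrl", "Aon", "Bon", "ABon"),
                           stimuli_on = I(list(character(), "A", "B",
                                               c("A", "B"))),
                           inhibitors_on = I(list(character(), character(),
                                                  character(), character())))
  design <- experimental_design(
    conditions, stimuli = c("A", "B"), inhibitors = c(dummy = "A"),
    sentinels = data.frame(analyte = "C", activity = 1L))
  # data generated from the A-only truth
  truth_sel <- vapply(sc$gates, function(g)
    as.integer(identical(g$inputs, "A")), integer(1))
  ds <- list(design = design)
  t1 <- sapply(design$conditions$name, function(cn) {
    st <- simulate_synchronous(logic_model(sc, truth_sel),
                               condition_clamps(design, cn))
    st$state[["C"]]
  })
  ds$t1 <- matrix(pmin(pmax(t1, 0.001), 0.999),
                  dimnames = list(design$conditions$name, "C"))
  class(ds) <- "normalized_dataset"
  with_b <- mse_fitness(logic_model(sc, rep(1L, length(sc$gates))), ds, design)
  wo_b <- mse_fitness(logic_model(sc, truth_sel), ds, design)
  expect_lt(wo_b$total, with_b$total)
})

test_that("activity modulation is the clipped difference with NA masking", {
  t1 <- c(A = 1, B = 0.3, C = NA, D = 0)
  t0 <- c(A = 0, B = 0.8, C = 1, D = 0)
  mod <- activity_modulation(t1, t0)
  expect_equal(unname(mod[c("A", "B", "D")]), c(1, -0.5, 0))
  expect_true(is.na(mod[["C"]]))
  expect_true(all(mod >= -1 & mod <= 1, na.rm = TRUE))
})
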