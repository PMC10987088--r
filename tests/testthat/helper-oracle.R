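# Independent oracles used across the suite.

# Naive synchronous trajectory simulator, written against the update rule
# directly (plain R, no shared code with the package internals beyond the
# scaffold data structure). Returns the same fields as simulate_synchronous.
oracle_simulate <- function(model, condition = list(on = character(),
                                                    off = character()),
                            initial = NULL, max_iter = 100) {
  scaffold <- model$scaffold
  species <- scaffold$species
  state <- stats::setNames(rep(0L, length(species)), species)
  if (!is.null(initial)) state[names(initial)] <- as.integer(initial)
  clamp <- function(s) {
    s[condition$on] <- 1L
    s[condition$off] <- 0L
    s
  }
  gate_fires <- function(g, s) {
    all(ifelse(g$signs > 0, s[g$inputs] == 1L, s[g$inputs] == 0L))
  }
  step <- function(s) {
    ns <- s
    for (v in species) {
      gs <- scaffold$gates[model$selection == 1L &
                             vapply(scaffold$gates, function(g)
                               g$output == v, logical(1))]
      # careful: index gates by selection first, then by output
      if (length(gs)) {
        ns[v] <- as.integer(any(vapply(gs, gate_fires, logical(1), s = s)))
      }
    }
    clamp(ns)
  }
  state <- clamp(state)
  hist <- list(state)
  attractor <- "none"; converged <- FALSE; iterations <- 0L
  cyc_start <- NA
  for (it in seq_len(max_iter)) {
    ns <- step(state)
    iterations <- it
    if (identical(unname(ns), unname(state))) {
      converged <- TRUE; attractor <- "fixpoint"; state <- ns; break
    }
    for (h in seq_along(hist)) {
      if (identical(unname(hist[[h]]), unname(ns))) { cyc_start <- h; break }
    }
    state <- ns
    hist[[length(hist) + 1L]] <- state
    if (!is.na(cyc_start)) { attractor <- "cycle"; break }
  }
  out <- state
  if (attractor == "cycle") {
    cyc <- do.call(rbind, hist[cyc_start:length(hist)])
    for (v in species) {
      if (length(unique(cyc[, v])) > 1) out[v] <- NA_integer_
    }
  } else if (attractor == "none") {
    free <- setdiff(species, c(condition$on, condition$off))
    out[free] <- NA_integer_
  }
  list(state = out, iterations = iterations, converged = converged,
       attractor = attractor)
}

# Brute-force fitness minimum over all 2^G selections.
oracle_exhaustive <- function(scaffold, dataset, design, theta_size = 1e-4,
                              theta_na = 1) {
  G <- length(scaffold$gates)
  stopifnot(G <= 14)
  best <- Inf; best_sel <- NULL
  for (code in 0:(2^G - 1)) {
    sel <- as.integer(intToBits(code)[1:G])
    f <- mse_fitness(logic_model(scaffold, sel), dataset, design,
                     theta_size = theta_size, theta_na = theta_na)
    if (f$total < best) { best <- f$total; best_sel <- sel }
  }
  list(total = best, selection = best_sel)
}

# Random small logic model for property tests: n nodes, random gates.
random_model <- function(n_nodes, n_gates, seed) {
  set.seed(seed)
  species <- paste0("n", seq_len(n_nodes))
  gates <- lapply(seq_len(n_gates), function(i) {
    arity <- sample(1:2, 1)
    inputs <- sample(species, arity)
    list(output = sample(species, 1), inputs = inputs,
         signs = sample(c(-1L, 1L), arity, replace = TRUE),
         provenance = "curated")
  })
  scaffold <- structure(list(species = species, gates = gates,
                             n_and = sum(vapply(gates, function(g)
                               length(g$inputs) >= 2, logical(1))),
                             measured = character(), targeted = character()),
                        class = "scaffold_model")
  logic_model(scaffold, sample(0:1, n_gates, replace = TRUE))
}

# Small raw long-format dataset built by hand for dataprep tests.
toy_raw <- function(design, analyte_values, control = 1000, beads = 120) {
  # analyte_values: list analyte -> named vector of T1 MFIs per condition
  rows <- list()
  for (cn in design$conditions$name) {
    for (rep_i in 1:3) for (tp in c("T0", "T1")) {
      for (a in names(analyte_values)) {
        v <- if (tp == "T1") analyte_values[[a]][cn] else analyte_values[[a]][1]
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cn, analyte = a, replicate = rep_i, timepoint = tp,
          mfi = unname(v), beads = beads, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cn, analyte = "b-Tubulin", replicate = rep_i,
        timepoint = tp, mfi = control, beads = beads, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
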