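#' Genetic-algorithm hyperparameters
#'
#' @param pop_size population size.
#' @param generations generation cap.
#' @param mutation per-bit mutation probability.
#' @param elitism number of best individuals copied unchanged.
#' @param tournament tournament size for parent selection.
#' @param stall stop after this many generations without improvement.
#' @param seed RNG seed; recorded in the run output.
#' @return list of class `ga_params`.
#' @export
ga_params <- function(pop_size = 50, generations = 200, mutation = 0.01,
                      elitism = 2, tournament = 3, stall = 50, seed = 1) {
  stopifnot(pop_size >= 2, generations >= 1, mutation > 0, mutation < 1,
            elitism >= 0, elitism < pop_size, tournament >= 1, stall >= 1)
  structure(list(pop_size = pop_size, generations = generations,
                 mutation = mutation, elitism = elitism,
                 tournament = tournament, stall = stall, seed = seed),
            class = "ga_params")
}

#' Optimize a gate selection with a genetic algorithm
#'
#' Minimizes the total fitness ([mse_fitness()]) of the selection bitstring
#' over the scaffold's gates: tournament selection, uniform crossover,
#' per-bit mutation, elitism, with a stall-based early stop. Fitness
#' evaluations are cached per bitstring; the returned model's fitness is
#' the minimum over every individual ever evaluated. Deterministic given
#' `params$seed`.
#'
#' @param scaffold a `scaffold_model` with at least one gate.
#' @param dataset a `normalized_dataset`.
#' @param design an `experimental_design`.
#' @param params a [ga_params()].
#' @param theta_size,theta_na fitness penalty weights (see [mse_fitness()]).
#' @return list of class `ga_result`: `selection`, `fitness`
#'   (`fitness_result`), `seed`, `evaluations`, `generations_run`.
#' @export
ga_optimize <- function(scaffold, dataset, design, params = ga_params(),
                        theta_size = 1e-4, theta_na = 1) {
  if (!length(scaffold$gates)) stop("empty scaffold: no gates to select")
  fi <- fitness_inputs(scaffold, dataset, design)
  if (all(is.na(fi$data))) stop("no fit points: all data cells are masked")
  n_gates <- length(scaffold$gates)
  init0 <- rep(0L, fi$cs$n_nodes)

  cache <- new.env(parent = emptyenv())
  evals <- 0L
  evaluate <- function(pop) {
    keys <- apply(pop, 1, paste, collapse = "")
    new <- !vapply(keys, exists, logical(1), envir = cache)
    if (any(new)) {
      uk <- !duplicated(keys) & new
      m <- fitness_batch_cpp(pop[uk, , drop = FALSE], fi$cs$n_nodes,
                             fi$cs$gate_out, fi$cs$gate_ptr, fi$cs$gate_in,
                             fi$cs$gate_sign, fi$clamps, fi$data,
                             fi$sent_idx, fi$sent_act, init0, 100L,
                             theta_size, theta_na)
      evals <<- evals + sum(uk)
      for (i in seq_len(sum(uk)))
        assign(keys[uk][i], m[i, ], envir = cache)
    }
    t(vapply(keys, get, numeric(5), envir = cache))
  }

  set.seed(params$seed)
  pop <- matrix(as.integer(stats::runif(params$pop_size * n_gates) < 0.5),
                params$pop_size, n_gates)
  pop[1, ] <- 1L  # the full scaffold is always evaluated

  best_sel <- NULL; best_fit <- Inf; best_row <- NULL
  stall <- 0L; gen_run <- 0L
  for (gen in seq_len(params$generations)) {
    gen_run <- gen
    fit <- evaluate(pop)
    ord <- order(fit[, "total"])
    if (fit[ord[1], "total"] < best_fit - 1e-15) {
      best_fit <- fit[ord[1], "total"]
      best_sel <- pop[ord[1], ]
      best_row <- fit[ord[1], ]
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= params$stall) break
    elite <- pop[ord[seq_len(min(params$elitism, nrow(pop)))], , drop = FALSE]
    pick <- function() {
      cand <- sample.int(nrow(pop), params$tournament, replace = TRUE)
      cand[which.min(fit[cand, "total"])]
    }
    n_off <- params$pop_size - nrow(elite)
    off <- matrix(0L, n_off, n_gates)
    for (i in seq_len(n_off)) {
      a <- pop[pick(), ]; b <- pop[pick(), ]
      mask <- stats::runif(n_gates) < 0.5
      child <- ifelse(mask, a, b)
      flip <- stats::runif(n_gates) < params$mutation
      child[flip] <- 1L - child[flip]
      off[i, ] <- child
    }
    pop <- rbind(elite, off)
  }
  structure(list(selection = as.integer(best_sel),
                 fitness = structure(lapply(as.list(best_row), unname),
                                     class = "fitness_result"),
                 seed = params$seed, evaluations = evals,
                 generations_run = gen_run),
            class = "ga_result")
}

#' Train a family of optimized models
#'
#' Runs the genetic algorithm `n_runs` times with consecutive seeds
#' (`base_seed`, `base_seed + 1`, ...) and keeps the `keep` lowest-fitness
#' results, sorted ascending. Averaging discrete states across the family
#' yields quantitative (fractional) predictions, and per-gate selection
#' frequencies give edge confidence.
#'
#' @param scaffold a `scaffold_model`.
#' @param dataset a `normalized_dataset`.
#' @param design an `experimental_design`.
#' @param n_runs number of independent GA runs (>= `keep`).
#' @param keep family size retained.
#' @param base_seed first seed.
#' @param params shared [ga_params()] (its seed field is overridden per run).
#' @param theta_size,theta_na fitness weights.
#' @return object of class `model_family`: `scaffold`, `members` (list of
#'   `selection`/`fitness`/`seed`, fitness ascending), `n_runs`.
#' @export
build_family <- function(scaffold, dataset, design, n_runs = 100, keep = 20,
                         base_seed = 1, params = ga_params(),
                         theta_size = 1e-4, theta_na = 1) {
  stopifnot(n_runs >= keep)
  runs <- lapply(seq_len(n_runs) - 1L, function(k) {
    p <- params; p$seed <- base_seed + k
    ga_optimize(scaffold, dataset, design, p, theta_size, theta_na)
  })
  totals <- vapply(runs, function(r) r$fitness$total, numeric(1))
  ord <- order(totals)[seq_len(keep)]
  structure(list(scaffold = scaffold,
                 members = lapply(runs[ord], function(r)
                   r[c("selection", "fitness", "seed")]),
                 n_runs = n_runs),
            class = "model_family")
}

#' @export
print.model_family <- function(x, ...) {
  totals <- vapply(x$members, function(m) m$fitness$total, numeric(1))
  cat(sprintf("model_family: %d models kept of %d runs; total fitness %.4g - %.4g\n",
              length(x$members), x$n_runs, min(totals), max(totals)))
  invisible(x)
}

#' Per-gate selection frequency across a model family
#'
#' @param family a `model_family`.
#' @return numeric vector in `[0, 1]`, one entry per scaffold gate, named
#'   by gate label.
#' @export
edge_frequencies <- function(family) {
  stopifnot(length(family$members) > 0)
  sel <- do.call(rbind, lapply(family$members, `[[`, "selection"))
  freq <- colMeans(sel)
  names(freq) <- vapply(family$scaffold$gates, gate_label, character(1))
  freq
}

#' Select the best model of a family
#'
#' Lowest total fitness; ties are broken by fewer selected gates, then by
#' the lexicographically smallest bitstring.
#'
#' @param family a `model_family`.
#' @return a `logic_model`.
#' @export
select_best <- function(family) {
  stopifnot(length(family$members) > 0)
  totals <- vapply(family$members, function(m) m$fitness$total, numeric(1))
  sizes <- vapply(family$members, function(m) sum(m$selection), numeric(1))
  keys <- vapply(family$members, function(m)
    paste(m$selection, collapse = ""), character(1))
  best <- order(totals, sizes, keys)[1]
  logic_model(family$scaffold, family$members[[best]]$selection)
}

#' Restrict a model to its high-confidence gates
#'
#' Keeps the gates of `best` whose family frequency is strictly greater
#' than `threshold`; the resulting submodel is used for display and for
#' endpoint/phenotype analysis.
#'
#' @param best a `logic_model` (typically from [select_best()]).
#' @param conf per-gate frequencies from [edge_frequencies()].
#' @param threshold confidence cutoff (strict).
#' @return a `logic_model`; a warning is emitted if no gate survives.
#' @export
high_confidence_submodel <- function(best, conf, threshold = 0.4) {
  stopifnot(length(conf) == length(best$selection))
  sel <- as.integer(best$selection == 1L & conf > threshold)
  if (!sum(sel)) warning("no gate above the confidence threshold")
  logic_model(best$scaffold, sel)
}

#' Average steady state over a model family
#'
#' Simulates every family member under the same condition and averages the
#' node states, yielding fractional activities; unresolved states enter as
#' 0.5.
#'
#' @param family a `model_family`.
#' @param condition clamp list as in [simulate_synchronous()].
#' @param max_iter iteration cap.
#' @return named numeric vector of mean activities in `[0, 1]`.
#' @export
family_state <- function(family, condition, max_iter = 100) {
  states <- vapply(family$members, function(m) {
    st <- simulate_synchronous(logic_model(family$scaffold, m$selection),
                               condition, max_iter = max_iter)$state
    ifelse(is.na(st), 0.5, st)
  }, numeric(length(family$scaffold$species)))
  rowMeans(states)
}

#' Serialize a model family to JSON
#'
#' @param family a `model_family`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_json <- function(family, path) {
  obj <- list(
    n_runs = family$n_runs,
    gates = vapply(family$scaffold$gates, gate_label, character(1)),
    members = lapply(family$members, function(m)
      list(selection = paste(m$selection, collapse = ""),
           seed = m$seed, fitness = unclass(m$fitness))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
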