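#' Build a logic model from a scaffold and a gate selection
#'
#' A logic model is a scaffold (the AND/OR hypergraph of candidate gates)
#' plus a 0/1 selection bitstring saying which gates are active. Node
#' update semantics: a node is the OR over its selected gates; a gate is an
#' AND of literals (a +1 input must be 1, a -1 input must be 0); a node
#' with no selected gate holds its value.
#'
#' @param scaffold a `scaffold_model`.
#' @param selection integer 0/1 vector, one per gate (default: all gates
#'   selected).
#' @return object of class `logic_model`.
#' @export
logic_model <- function(scaffold, selection = NULL) {
  stopifnot(inherits(scaffold, "scaffold_model"))
  if (is.null(selection)) selection <- rep(1L, length(scaffold$gates))
  selection <- as.integer(selection)
  if (length(selection) != length(scaffold$gates))
    stop("selection length must equal gate count")
  stopifnot(all(selection %in% c(0L, 1L)))
  structure(list(scaffold = scaffold, selection = selection),
            class = "logic_model")
}

#' @export
print.logic_model <- function(x, ...) {
  cat(sprintf("logic_model: %d/%d gates selected over %d species\n",
              sum(x$selection), length(x$selection),
              length(x$scaffold$species)))
  invisible(x)
}

# Flatten a scaffold into the 0-based index arrays the C++ simulator uses.
compile_scaffold <- function(scaffold) {
  species <- scaffold$species
  arities <- vapply(scaffold$gates, function(g) length(g$inputs), integer(1))
  list(
    n_nodes = length(species),
    species = species,
    gate_out = vapply(scaffold$gates, function(g)
      match(g$output, species), integer(1)) - 1L,
    gate_ptr = c(0L, cumsum(arities)),
    gate_in = unlist(lapply(scaffold$gates, function(g)
      match(g$inputs, species)), use.names = FALSE) - 1L,
    gate_sign = unlist(lapply(scaffold$gates, function(g) g$signs),
                       use.names = FALSE))
}

# clamp spec (list(on=, off=)) -> -1/0/1 vector over species
clamp_vector <- function(species, condition) {
  bad <- intersect(condition$on, condition$off)
  if (length(bad)) stop("node clamped both on and off: ",
                        paste(bad, collapse = ", "))
  unknown <- setdiff(c(condition$on, condition$off), species)
  if (length(unknown)) stop("clamp refers to unknown node: ",
                            paste(unknown, collapse = ", "))
  cl <- rep(-1L, length(species))
  cl[species %in% condition$on] <- 1L
  cl[species %in% condition$off] <- 0L
  cl
}

#' Synchronous Boolean simulation to steady state
#'
#' All nodes are updated simultaneously each step; clamped nodes are
#' reapplied after every step. The trajectory stops at a fixpoint; if a
#' state recurs with period > 1, nodes that vary within the cycle are
#' reported unresolved (NA) and nodes constant over the cycle keep their
#' value. If `max_iter` is reached with neither, all unclamped nodes are
#' unresolved.
#'
#' @param model a `logic_model`.
#' @param condition list with character vectors `on` (clamped to 1) and
#'   `off` (clamped to 0); may be empty vectors.
#' @param initial named 0/1 vector of initial values; defaults to all
#'   nodes inactive (0).
#' @param max_iter iteration cap.
#' @return object of class `steady_state`: named integer vector `state`
#'   (NA = unresolved), `iterations`, `converged` (TRUE only at a
#'   fixpoint), `attractor` (`"fixpoint"`, `"cycle"`, `"none"`).
#' @export
simulate_synchronous <- function(model, condition = list(on = character(),
                                                         off = character()),
                                 initial = NULL, max_iter = 100) {
  stopifnot(inherits(model, "logic_model"))
  cs <- compile_scaffold(model$scaffold)
  init <- rep(0L, cs$n_nodes)
  if (!is.null(initial)) {
    idx <- match(names(initial), cs$species)
    if (anyNA(idx)) stop("initial state names unknown: ",
                         paste(names(initial)[is.na(idx)], collapse = ", "))
    init[idx] <- as.integer(initial)
  }
  cl <- clamp_vector(cs$species, condition)
  res <- sim_logic_cpp(cs$n_nodes, cs$gate_out, cs$gate_ptr, cs$gate_in,
                       cs$gate_sign, model$selection, cl, init, max_iter)
  state <- res$state
  names(state) <- cs$species
  structure(list(state = state, iterations = res$iterations,
                 converged = res$converged, attractor = res$attractor),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady_state (%s, %d iterations): %d on, %d off, %d unresolved\n",
              x$attractor, x$iterations, sum(x$state == 1, na.rm = TRUE),
              sum(x$state == 0, na.rm = TRUE), sum(is.na(x$state))))
  invisible(x)
}

#' Write a steady state as TSV
#' @param state a `steady_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_steady_state <- function(state, path) {
  utils::write.table(
    data.frame(node = names(state$state), value = unname(state$state),
               converged = state$converged),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# conditions x nodes clamp matrix + data matrix for the fitness routine
fitness_inputs <- function(scaffold, dataset, design) {
  cs <- compile_scaffold(scaffold)
  sentinels <- design$sentinels$analyte
  missing <- setdiff(sentinels, cs$species)
  if (length(missing)) stop("sentinel not in model: ",
                            paste(missing, collapse = ", "))
  conds <- design$conditions$name
  clamps <- t(vapply(conds, function(cn)
    clamp_vector(cs$species, condition_clamps(design, cn)),
    integer(cs$n_nodes)))
  data <- dataset$t1[conds, sentinels, drop = FALSE]
  list(cs = cs, clamps = clamps, data = unname(data),
       sent_idx = match(sentinels, cs$species) - 1L,
       sent_act = as.integer(design$sentinels$activity))
}

#' Fitness of a logic model against a normalized dataset
#'
#' Each design condition is simulated under its clamps (stimuli on,
#' inhibited targets off, constitutive receptors on unless inhibited) from
#' the all-inactive initial state; the mean squared deviation between the
#' simulated sentinel states and the normalized T1 values is computed over
#' unmasked cells. An unresolved prediction contributes `theta_na` in
#' place of a squared deviation; a parsimony term
#' `theta_size * selected-gate-inputs / total-gate-inputs` breaks ties
#' toward smaller models. Sentinels whose measured phosphosite reports
#' inhibition (activity -1) are compared against the complement of the
#' simulated state.
#'
#' @param model a `logic_model`.
#' @param dataset a `normalized_dataset`.
#' @param design an `experimental_design`.
#' @param theta_size size-penalty weight (set 0 for pure mse).
#' @param theta_na penalty per unresolved fitted cell.
#' @param max_iter simulation iteration cap.
#' @return list of class `fitness_result`: `mse`, `na_penalty`,
#'   `size_penalty`, `total`, `n_points`.
#' @export
mse_fitness <- function(model, dataset, design, theta_size = 1e-4,
                        theta_na = 1, max_iter = 100) {
  fi <- fitness_inputs(model$scaffold, dataset, design)
  m <- fitness_batch_cpp(matrix(model$selection, nrow = 1), fi$cs$n_nodes,
                         fi$cs$gate_out, fi$cs$gate_ptr, fi$cs$gate_in,
                         fi$cs$gate_sign, fi$clamps, fi$data, fi$sent_idx,
                         fi$sent_act, rep(0L, fi$cs$n_nodes), max_iter,
                         theta_size, theta_na)
  structure(list(mse = unname(m[1, "mse"]),
                 na_penalty = unname(m[1, "na_penalty"]),
                 size_penalty = unname(m[1, "size_penalty"]),
                 total = unname(m[1, "total"]),
                 n_points = unname(m[1, "n_points"])),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("fitness: total %.6g (mse %.6g, na %.4g, size %.4g) over %d points\n",
              x$total, x$mse, x$na_penalty, x$size_penalty, x$n_points))
  invisible(x)
}

#' Activity modulation between an endpoint and a baseline state
#'
#' Per-node difference `T1 - T0`, clipped to `[-1, 1]`. States may be
#' fractional (family-averaged); unresolved nodes in either state are
#' masked.
#'
#' @param state_t1 named numeric vector (endpoint state).
#' @param baseline_t0 named numeric vector over the same nodes.
#' @return named numeric vector in `[-1, 1]`, NA where either input is
#'   unresolved.
#' @export
activity_modulation <- function(state_t1, baseline_t0) {
  stopifnot(setequal(names(state_t1), names(baseline_t0)))
  d <- state_t1 - baseline_t0[names(state_t1)]
  pmin(pmax(d, -1), 1)
}
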