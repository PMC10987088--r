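#' Generate a synthetic ground-truth signaling network
#'
#' Builds a random signed, layered network shaped like the FLT3-ITD
#' perturbation study: a stimulus layer (IGF1, TNFa), a constitutively
#' active receptor (FLT3), drug-inhibitable kinases wired under the cue
#' panel of [flt3_design()], optional downstream nodes, a sentinel layer
#' (the downstream-most nodes, measured), and terminal phenotype
#' regulators. The truth logic model is the OR-model over the true edges;
#' the distractor scaffold adds decoy edges obtained by degree-preserving
#' rewiring of the truth, then expands everything into AND/OR gates.
#' The generator redraws internally (deterministically from `seed`) until
#' every sentinel responds to the design and at least 90% of
#' (condition, sentinel) steady states are resolved.
#'
#' @param n_nodes total species count (stimuli + kinases + extras).
#' @param n_stimuli 1 or 2 stimuli (IGF1 branch first).
#' @param n_inhibitable number of drug targets, 1..7, taken in the order
#'   FLT3, p38, JNK, PI3K, mTOR, MEK1/2, GSK3 (FLT3 is always included).
#' @param n_sentinels number of measured nodes (<= n_nodes).
#' @param n_phenotype_regs number of phenotype-regulator annotations.
#' @param seed RNG seed; the truth is reproducible byte for byte.
#' @param p_extra_edge probability of each optional kinase-to-downstream
#'   shortcut edge.
#' @param p_inhibitory probability that a non-backbone edge is inhibitory.
#' @return object of class `synthetic_truth`: `network` (true edges only),
#'   `full_network` (with decoys), `scaffold` (expanded distractor
#'   scaffold), `truth_model` (a `logic_model` on that scaffold),
#'   `truth_gates` (indices), `design`, `regulators` (a `regulator_table`),
#'   `seed`.
#' @export
make_truth <- function(n_nodes = 12, n_stimuli = 2, n_inhibitable = 7,
                       n_sentinels = 5, n_phenotype_regs = 2, seed = 1,
                       p_extra_edge = 0.15, p_inhibitory = 0.25) {
  stimuli_all <- c("IGF1", "TNFa")
  targets_all <- c("FLT3", "p38", "JNK", "PI3K", "mTOR", "MEK1/2", "GSK3")
  if (n_stimuli < 1 || n_stimuli > 2) stop("n_stimuli must be 1 or 2")
  if (n_inhibitable < 1 || n_inhibitable > 7)
    stop("n_inhibitable must be in 1..7")
  n_extra <- n_nodes - n_stimuli - n_inhibitable
  if (n_extra < 0) stop("n_nodes too small for the requested layers")
  if (n_sentinels > n_nodes) stop("n_sentinels cannot exceed n_nodes")
  stimuli <- stimuli_all[seq_len(n_stimuli)]
  targets <- targets_all[seq_len(n_inhibitable)]
  inhibitors_all <- c(FLT3i = "FLT3", p38i = "p38", JNKi = "JNK",
                      PI3Ki = "PI3K", mTORi = "mTOR", MEKi = "MEK1/2",
                      GSK3i = "GSK3")
  pair_all <- data.frame(
    drug = c("p38i", "JNKi", "PI3Ki", "mTORi", "MEKi", "GSK3i"),
    stimulus = c("TNFa", "TNFa", "IGF1", "IGF1", "IGF1", "IGF1"),
    with_anchor = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  inhibitors <- inhibitors_all[inhibitors_all %in% targets]
  pairings <- pair_all[pair_all$drug %in% names(inhibitors) &
                         pair_all$stimulus %in% stimuli, , drop = FALSE]
  extras <- if (n_extra) paste0("X", seq_len(n_extra)) else character()
  # downstream order: stimuli, FLT3, kinases, extras
  kinases <- setdiff(targets, "FLT3")
  species <- c(stimuli, "FLT3", kinases, extras)
  sentinels <- rev(rev(species)[seq_len(n_sentinels)])  # downstream-most

  set.seed(seed)
  for (attempt in 1:50) {
    edges <- list()
    add <- function(s, t, sg) edges[[length(edges) + 1L]] <<-
      data.frame(source = s, target = t, sign = as.integer(sg),
                 stringsAsFactors = FALSE)
    # backbone: each paired inhibitor target is driven by its stimulus
    for (i in seq_len(nrow(pairings)))
      add(pairings$stimulus[i], unname(inhibitors[pairings$drug[i]]), 1L)
    # the constitutive receptor feeds one or two kinases
    if (length(kinases)) {
      fed <- sample(kinases, min(2, length(kinases)))
      for (k in fed) add("FLT3", k, 1L)
    }
    # optional kinase-to-kinase shortcuts, downstream only in list order
    ord <- c(kinases, extras)
    for (i in seq_along(ord)) for (j in seq_along(ord)) {
      if (j <= i) next
      if (stats::runif(1) < p_extra_edge) {
        sg <- if (stats::runif(1) < p_inhibitory) -1L else 1L
        add(ord[i], ord[j], sg)
      }
    }
    # every extra node needs at least one regulator
    upstream_of <- function(x) {
      pos <- match(x, ord)
      c(stimuli, "FLT3", ord[seq_len(pos - 1)])
    }
    e <- unique(do.call(rbind, edges))
    for (x in extras) {
      if (!any(e$target == x)) {
        src <- sample(upstream_of(x), 1)
        sg <- if (stats::runif(1) < p_inhibitory) -1L else 1L
        e <- rbind(e, data.frame(source = src, target = x, sign = sg,
                                 stringsAsFactors = FALSE))
      }
    }
    # every kinase needs a downstream substrate, as in the real panel where
    # each inhibitor is paired with a sentinel reporting its branch
    for (k in kinases) {
      down <- ord[seq_along(ord) > match(k, ord)]
      if (length(down) && !any(e$source == k)) {
        e <- rbind(e, data.frame(source = k, target = sample(down, 1),
                                 sign = 1L, stringsAsFactors = FALSE))
      }
    }
    e <- unique(e)
    nodes <- data.frame(
      name = species,
      category = ifelse(species %in% stimuli, "stimulus", "protein"),
      is_measured = species %in% sentinels,
      is_targeted = species %in% c(stimuli, targets),
      stringsAsFactors = FALSE)
    net <- causal_network(edges = e, nodes = nodes)
    design <- enumerate_design(
      pairings, stimuli = stimuli, inhibitors = inhibitors,
      anchor = "FLT3i",
      sentinels = data.frame(analyte = sentinels,
                             activity = rep(1L, length(sentinels)),
                             stringsAsFactors = FALSE),
      constitutive = "FLT3")
    # minimality: drop true edges with no observable signature under the
    # design (identical condition x sentinel steady states and baseline
    # without them), so recovery against the truth is well-defined
    obs_signature <- function(edges_df) {
      netk <- causal_network(edges = edges_df, nodes = nodes)
      sck <- expand(netk, max_gate_inputs = 1)
      mk <- logic_model(sck)
      conds <- c(list(list(on = "FLT3", off = character())),
                 lapply(design$conditions$name, condition_clamps,
                        design = design))
      unlist(lapply(conds, function(cc)
        simulate_synchronous(mk, cc)$state[sentinels]))
    }
    ref <- obs_signature(e)
    i <- nrow(e)
    while (i >= 1) {
      cand <- e[-i, , drop = FALSE]
      if (identical(obs_signature(cand), ref)) e <- cand
      i <- i - 1L
    }
    net <- causal_network(edges = e, nodes = nodes)
    # decoys: rewire true-edge targets, degree-preserving
    perm <- sample(nrow(e))
    decoy <- data.frame(source = e$source, target = e$target[perm],
                        sign = e$sign, stringsAsFactors = FALSE)
    decoy <- decoy[decoy$source != decoy$target &
                     !(decoy$target %in% stimuli), , drop = FALSE]
    key <- function(d) paste(d$source, d$target, d$sign)
    decoy <- decoy[!(key(decoy) %in% key(e)), , drop = FALSE]
    decoy <- decoy[!duplicated(key(decoy)), , drop = FALSE]
    full <- causal_network(edges = rbind(e, decoy), nodes = nodes)
    scaffold <- expand(full, max_gate_inputs = 2)
    truth_gates <- which(vapply(scaffold$gates, function(g)
      length(g$inputs) == 1 &&
        any(e$source == g$inputs & e$target == g$output & e$sign == g$signs),
      logical(1)))
    sel <- integer(length(scaffold$gates))
    sel[truth_gates] <- 1L
    truth_model <- logic_model(scaffold, sel)
    # quality gates: resolved steady states and responsive sentinels
    states <- vapply(design$conditions$name, function(cn) {
      st <- simulate_synchronous(truth_model,
                                 condition_clamps(design, cn))$state
      st[sentinels]
    }, numeric(length(sentinels)))
    resolved <- mean(!is.na(states))
    varies <- apply(states, 1, function(r)
      length(unique(stats::na.omit(r))) > 1)
    valid <- validate_network(net, design)$ok
    if (resolved >= 0.9 && all(varies) && valid) {
      reg_pool <- rev(species)[seq_len(min(length(species),
                                           max(n_phenotype_regs, 2)))]
      regulators <- data.frame(
        node = reg_pool[seq_len(n_phenotype_regs)],
        phenotype = rep(c("apoptosis", "proliferation"),
                        length.out = n_phenotype_regs),
        effect = ifelse(stats::runif(n_phenotype_regs) < 0.5, -1L, 1L),
        stringsAsFactors = FALSE)
      class(regulators) <- c("regulator_table", "data.frame")
      return(structure(list(network = net, full_network = full,
                            scaffold = scaffold, truth_model = truth_model,
                            truth_gates = truth_gates, design = design,
                            regulators = regulators, seed = seed),
                       class = "synthetic_truth"))
    }
  }
  stop("could not generate a responsive truth in 50 attempts; relax counts")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth (seed %d): %d nodes, %d true edges, %d scaffold gates (%d true)\n",
              x$seed, length(x$scaffold$species), nrow(x$network$edges),
              length(x$scaffold$gates), length(x$truth_gates)))
  invisible(x)
}

#' Simulate a raw bead-array dataset from a synthetic truth
#'
#' For every design condition the truth model's steady state is computed;
#' node states are mapped to median fluorescence intensities through a
#' per-analyte affine range (about 500-20000 arbitrary units), multiplied
#' by a shared per-well loading factor and by multiplicative log-normal
#' noise. A loading-control channel (`b-Tubulin`) with its own noise is
#' emitted per well, bead counts are drawn around `bead_mean` with a
#' fraction `low_bead_rate` forced below the reliability threshold, and T0
#' rows are generated from the unstimulated baseline (constitutive
#' receptor on, no stimuli, no drugs).
#'
#' @param truth a `synthetic_truth`.
#' @param replicates biological replicates per condition.
#' @param noise_sd log-scale SD of the multiplicative noise (0 = noiseless).
#' @param bead_mean Poisson mean of the bead counts.
#' @param low_bead_rate fraction of wells forced below 50 beads.
#' @param seed RNG seed.
#' @return long-format data.frame (`condition`, `analyte`, `replicate`,
#'   `timepoint`, `mfi`, `beads`) ready for [normalize_dataset()].
#' @export
simulate_dataset <- function(truth, replicates = 3, noise_sd = 0.05,
                             bead_mean = 120, low_bead_rate = 0.02,
                             seed = 1) {
  design <- truth$design
  sentinels <- design$sentinels$analyte
  set.seed(seed)
  base <- stats::runif(length(sentinels), 500, 2000)
  top <- stats::runif(length(sentinels), 10000, 20000)
  names(base) <- names(top) <- sentinels
  tub_level <- 5000

  state_of <- function(cond) {
    st <- simulate_synchronous(truth$truth_model, cond)$state[sentinels]
    ifelse(is.na(st), 0.5, st)
  }
  t0_state <- state_of(list(on = design$constitutive, off = character()))
  rows <- vector("list", 0)
  for (cn in design$conditions$name) {
    t1_state <- state_of(condition_clamps(design, cn))
    for (rep_i in seq_len(replicates)) for (tp in c("T0", "T1")) {
      st <- if (tp == "T0") t0_state else t1_state
      loading <- exp(stats::rnorm(1, 0, noise_sd / 2))
      mfi_true <- c(base + st * (top - base), `b-Tubulin` = tub_level)
      noise <- exp(stats::rnorm(length(mfi_true), 0, noise_sd))
      mfi <- mfi_true * loading * noise
      n_w <- length(mfi)
      beads <- stats::rpois(n_w, bead_mean)
      low <- stats::runif(n_w) < low_bead_rate
      beads[low] <- sample(0:49, sum(low), replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cn, analyte = names(mfi), replicate = rep_i,
        timepoint = tp, mfi = unname(mfi), beads = beads,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gate-recovery metrics against a synthetic truth
#'
#' Treats the gates whose family frequency exceeds `threshold` as predicted
#' positives and compares them with the truth gates.
#'
#' @param truth a `synthetic_truth`.
#' @param conf per-gate frequencies from [edge_frequencies()] computed on
#'   the truth's distractor scaffold.
#' @param threshold confidence cutoff (strict).
#' @return list with `precision`, `recall`, `f1`, `n_predicted`, `n_truth`.
#' @export
recovery_report <- function(truth, conf, threshold = 0.4) {
  stopifnot(length(conf) == length(truth$scaffold$gates))
  predicted <- which(conf > threshold)
  tp <- length(intersect(predicted, truth$truth_gates))
  precision <- if (length(predicted)) tp / length(predicted) else 0
  recall <- if (length(truth$truth_gates)) tp / length(truth$truth_gates) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_predicted = length(predicted), n_truth = length(truth$truth_gates))
}
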