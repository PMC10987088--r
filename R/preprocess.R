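#' Flag measured and targeted nodes of a network from a design
#'
#' Sets `is_measured` on sentinel analytes and `is_targeted` on cues
#' (stimuli, inhibitor targets, constitutive receptors); these designations
#' drive compression.
#'
#' @param net a `causal_network`.
#' @param design an `experimental_design`.
#' @return the network with updated node flags.
#' @export
designate_nodes <- function(net, design) {
  nodes <- net$nodes
  nodes$is_measured <- nodes$name %in% design$sentinels$analyte
  nodes$is_targeted <- nodes$name %in%
    c(design$stimuli, unname(design$inhibitors), design$constitutive)
  causal_network(edges = net$edges, nodes = nodes)
}

#' Compress a prior knowledge network
#'
#' Removes nodes that carry no information for training: species that are
#' neither measured (sentinels) nor targeted (cues) nor phenotypes.
#' A removable pass-through node (in-degree and out-degree both >= 1) is
#' bypassed, connecting every (upstream, downstream) pair with the product
#' of the two signs; removable sources and sinks are simply deleted with
#' their incident edges. The rule iterates to a fixpoint. To avoid a
#' quadratic edge blow-up, a node is bypassed only when
#' `in-degree * out-degree <= max_fan`; larger hubs are retained. Nodes
#' with a self-loop are never bypassed.
#'
#' @param net a `causal_network`.
#' @param design an `experimental_design` naming cues and sentinels; these
#'   (plus phenotype-category nodes) are protected.
#' @param max_fan bypass bound on in-degree x out-degree.
#' @return the compressed `causal_network`.
#' @export
compress <- function(net, design, max_fan = 4) {
  stopifnot(inherits(net, "causal_network"))
  protected <- unique(c(design$stimuli, unname(design$inhibitors),
                        design$sentinels$analyte, design$constitutive,
                        net$nodes$name[net$nodes$category == "phenotype"]))
  edges <- net$edges
  nodes <- net$nodes
  repeat {
    changed <- FALSE
    for (v in setdiff(nodes$name, protected)) {
      inc <- edges$target == v & edges$source != v
      out <- edges$source == v & edges$target != v
      selfloop <- any(edges$source == v & edges$target == v)
      din <- sum(inc); dout <- sum(out)
      if (din == 0 || dout == 0) {
        edges <- edges[edges$source != v & edges$target != v, , drop = FALSE]
        nodes <- nodes[nodes$name != v, , drop = FALSE]
        changed <- TRUE
        break
      }
      if (!selfloop && din * dout <= max_fan) {
        up <- edges[inc, , drop = FALSE]
        down <- edges[out, , drop = FALSE]
        new <- do.call(rbind, lapply(seq_len(nrow(up)), function(i) {
          data.frame(source = up$source[i], target = down$target,
                     sign = up$sign[i] * down$sign,
                     provenance = ifelse(up$provenance[i] == "imputed" |
                                           down$provenance == "imputed",
                                         "imputed", "curated"),
                     stringsAsFactors = FALSE)
        }))
        edges <- edges[!inc & !out, , drop = FALSE]
        edges <- unique(rbind(edges, new[new$source != new$target, , drop = FALSE]))
        nodes <- nodes[nodes$name != v, , drop = FALSE]
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  if (!nrow(nodes)) warning("compression removed every node")
  causal_network(edges = edges, nodes = nodes)
}

# gates stored as list(output, inputs (chr), signs (int), provenance (chr))
gate_label <- function(g) {
  lits <- paste0(ifelse(g$signs < 0, "!", ""), g$inputs)
  paste0(paste(lits, collapse = "&"), "->", g$output)
}

#' Expand a compressed network into an AND/OR scaffold
#'
#' Every node with regulator set R is connected to each single regulator
#' (the OR branches) and to each AND combination of 2..`max_gate_inputs`
#' regulators. A gate fires when every positive-sign input is 1 and every
#' negative-sign input is 0; a node's value is the OR over its selected
#' gates. AND gates of arity >= 2 are counted as operator nodes. Gate order
#' is deterministic (lexicographic per output).
#'
#' @param net a compressed `causal_network`.
#' @param max_gate_inputs maximum AND arity (>= 1; 1 disables AND gates).
#' @return object of class `scaffold_model`: `species`, `gates` (list),
#'   `n_and` (operator-node count), `measured`, `targeted` flags.
#' @export
expand <- function(net, max_gate_inputs = 2) {
  stopifnot(inherits(net, "causal_network"), max_gate_inputs >= 1)
  gates <- list()
  for (v in net$nodes$name) {
    reg <- net$edges[net$edges$target == v, , drop = FALSE]
    if (!nrow(reg)) next
    reg <- unique(reg[, c("source", "sign", "provenance")])
    reg <- reg[order(reg$source, reg$sign), , drop = FALSE]
    k <- nrow(reg)
    for (i in seq_len(k)) {
      gates[[length(gates) + 1L]] <- list(
        output = v, inputs = reg$source[i], signs = reg$sign[i],
        provenance = reg$provenance[i])
    }
    if (k >= 2) {
      for (j in 2:min(k, max_gate_inputs)) {
        combos <- utils::combn(seq_len(k), j, simplify = FALSE)
        for (cb in combos) {
          gates[[length(gates) + 1L]] <- list(
            output = v, inputs = reg$source[cb], signs = reg$sign[cb],
            provenance = if (any(reg$provenance[cb] == "imputed"))
              "imputed" else "curated")
        }
      }
    }
  }
  structure(list(
    species = net$nodes$name,
    gates = gates,
    n_and = sum(vapply(gates, function(g) length(g$inputs) >= 2, logical(1))),
    measured = net$nodes$name[net$nodes$is_measured],
    targeted = net$nodes$name[net$nodes$is_targeted]),
    class = "scaffold_model")
}

#' @export
print.scaffold_model <- function(x, ...) {
  cat(sprintf("scaffold_model: %d species, %d gates (%d AND operators)\n",
              length(x$species), length(x$gates), x$n_and))
  invisible(x)
}

#' Impute candidate edges from perturbation-data correlations
#'
#' Adds co-regulations present in the data but missing from the prior
#' knowledge: for each ordered pair of measured analytes with no existing
#' directed edge, the Pearson correlation of their normalized T1 profiles
#' across conditions is screened at `|r| >= r_threshold`; passing pairs
#' yield a candidate edge with the correlation's sign and provenance
#' `"imputed"`. Each cue's on/off vector across conditions is screened the
#' same way against every analyte profile; for a stimulus the edge runs
#' from the stimulus node, for a drug from the drug's target node with the
#' sign flipped (drug applied = target off). Constant profiles are skipped.
#'
#' @param net the (compressed) `causal_network`.
#' @param dataset a `normalized_dataset` with >= 4 conditions.
#' @param r_threshold absolute-correlation screen threshold.
#' @return data.frame of imputed `CausalEdge` rows (possibly empty).
#' @export
impute_data_edges <- function(net, dataset, r_threshold = 0.75) {
  design <- dataset$design
  if (nrow(dataset$t1) < 4) stop("imputation needs >= 4 conditions")
  analytes <- intersect(colnames(dataset$t1), net$nodes$name)
  has_edge <- function(u, v)
    any(net$edges$source == u & net$edges$target == v)
  out <- list()
  add <- function(u, v, s) {
    out[[length(out) + 1L]] <<- data.frame(
      source = u, target = v, sign = s, provenance = "imputed",
      stringsAsFactors = FALSE)
  }
  usable <- function(x) sum(!is.na(x)) >= 4 && stats::sd(x, na.rm = TRUE) > 0
  for (u in analytes) for (v in analytes) {
    if (u == v || has_edge(u, v)) next
    xu <- dataset$t1[, u]; xv <- dataset$t1[, v]
    if (!usable(xu) || !usable(xv)) next
    r <- suppressWarnings(stats::cor(xu, xv, use = "pairwise.complete.obs"))
    if (!is.na(r) && abs(r) >= r_threshold) add(u, v, as.integer(sign(r)))
  }
  conds <- design$conditions
  cue_vec <- function(label, field) vapply(seq_len(nrow(conds)), function(i)
    as.integer(label %in% conds[[field]][[i]]), integer(1))
  cues <- c(
    stats::setNames(lapply(design$stimuli, cue_vec, field = "stimuli_on"),
                    design$stimuli),
    stats::setNames(lapply(names(design$inhibitors), cue_vec,
                           field = "inhibitors_on"),
                    names(design$inhibitors)))
  for (cu in names(cues)) {
    is_drug <- cu %in% names(design$inhibitors)
    src <- if (is_drug) unname(design$inhibitors[cu]) else cu
    for (v in analytes) {
      if (src == v || has_edge(src, v)) next
      cv <- cues[[cu]]; xv <- dataset$t1[, v]
      if (stats::sd(cv) == 0 || !usable(xv)) next
      r <- suppressWarnings(stats::cor(cv, xv, use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) >= r_threshold) {
        add(src, v, as.integer(if (is_drug) -sign(r) else sign(r)))
      }
    }
  }
  if (!length(out))
    return(data.frame(source = character(), target = character(),
                      sign = integer(), provenance = character(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' Merge imputed edges into a network
#'
#' @param net a `causal_network`.
#' @param imputed data.frame from [impute_data_edges()].
#' @return a `causal_network` containing the union of edges; all curated
#'   edges survive.
#' @export
add_edges <- function(net, imputed) {
  causal_network(edges = rbind(net$edges, imputed), nodes = net$nodes)
}

#' Serialize a scaffold to JSON
#'
#' @param scaffold a `scaffold_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scaffold_json <- function(scaffold, path) {
  obj <- list(
    species = scaffold$species,
    measured = scaffold$measured,
    targeted = scaffold$targeted,
    gates = lapply(scaffold$gates, function(g)
      list(output = g$output, inputs = g$inputs, signs = g$signs,
           provenance = g$provenance)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export a scaffold to SIF with materialized AND nodes
#'
#' AND gates of arity >= 2 become `and<k>` pseudo-nodes: each input feeds
#' the operator node with its sign, and the operator node activates the
#' gate's output.
#'
#' @param scaffold a `scaffold_model`.
#' @param path output path.
#' @param selection optional 0/1 vector restricting the export to selected
#'   gates.
#' @return `path`, invisibly.
#' @export
write_scaffold_sif <- function(scaffold, path, selection = NULL) {
  if (is.null(selection)) selection <- rep(1L, length(scaffold$gates))
  lines <- character(); k <- 0L
  for (i in seq_along(scaffold$gates)) {
    if (!selection[i]) next
    g <- scaffold$gates[[i]]
    if (length(g$inputs) == 1) {
      lines <- c(lines, sprintf("%s\t%d\t%s", g$inputs, g$signs, g$output))
    } else {
      k <- k + 1L
      andnode <- sprintf("and%d", k)
      lines <- c(lines,
                 sprintf("%s\t%d\t%s", g$inputs, g$signs, andnode),
                 sprintf("%s\t1\t%s", andnode, g$output))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
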