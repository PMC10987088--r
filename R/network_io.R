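#' Construct a causal signaling network
#'
#' A causal network is a signed directed graph over named species: the prior
#' knowledge network (PKN) of a signaling system. Nodes carry a category and
#' two designation flags used by compression: `is_measured` (sentinel
#' analytes) and `is_targeted` (cues: stimulated receptors or drug-inhibited
#' kinases).
#'
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (+1 activating, -1 inhibitory) and optionally `provenance`
#'   (`"curated"` or `"imputed"`).
#' @param nodes optional data.frame with columns `name`, `category`
#'   (`protein`, `complex`, `stimulus`, `small-molecule`, `phenotype`),
#'   `is_measured`, `is_targeted`. Missing nodes referenced by edges are
#'   added as undesignated proteins.
#' @return an object of class `causal_network` with elements `nodes` and
#'   `edges` (both data.frames, deduplicated, deterministically ordered).
#' @export
causal_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    stopifnot(all(c("source", "target", "sign") %in% names(edges)))
    if (!all(edges$sign %in% c(-1L, 1L))) {
      stop("edge sign must be +1 or -1")
    }
    if (is.null(edges$provenance)) edges$provenance <- "curated"
    edges <- unique(edges[, c("source", "target", "sign", "provenance")])
    edges <- edges[order(edges$source, edges$target, edges$sign), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), provenance = character(),
                        stringsAsFactors = FALSE)
  }
  referenced <- unique(c(edges$source, edges$target))
  if (is.null(nodes)) {
    nodes <- data.frame(name = referenced, stringsAsFactors = FALSE)
  } else {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    stopifnot("name" %in% names(nodes))
    if (anyDuplicated(nodes$name)) stop("duplicate node names")
    missing <- setdiff(referenced, nodes$name)
    if (length(missing)) {
      extra <- data.frame(name = missing, stringsAsFactors = FALSE)
      for (col in setdiff(names(nodes), "name")) extra[[col]] <- NA
      nodes <- rbind(nodes, extra)
    }
  }
  if (any(!nzchar(nodes$name))) stop("empty node name")
  if (is.null(nodes$category)) nodes$category <- rep("protein", nrow(nodes))
  nodes$category[is.na(nodes$category)] <- "protein"
  for (flag in c("is_measured", "is_targeted")) {
    if (is.null(nodes[[flag]])) nodes[[flag]] <- rep(FALSE, nrow(nodes))
    nodes[[flag]][is.na(nodes[[flag]])] <- FALSE
  }
  nodes <- nodes[order(nodes$name), c("name", "category", "is_measured", "is_targeted")]
  rownames(nodes) <- NULL
  bad <- nodes$name[nodes$category == "phenotype" & nodes$name %in% edges$source]
  if (length(bad)) stop("phenotype nodes cannot have outgoing edges: ",
                        paste(bad, collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf("causal_network: %d nodes, %d edges (%d imputed)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$provenance == "imputed")))
  invisible(x)
}

# SIGNOR effect vocabulary -> sign; ambiguous effects are rejected
.effect_to_sign <- function(effect, line_no) {
  out <- integer(length(effect))
  for (i in seq_along(effect)) {
    e <- trimws(effect[i])
    if (e %in% c("1", "+1")) {
      out[i] <- 1L
    } else if (e %in% c("-1", "−1")) {
      out[i] <- -1L
    } else if (grepl("^up-regulates", e)) {
      out[i] <- 1L
    } else if (grepl("^down-regulates", e)) {
      out[i] <- -1L
    } else {
      stop(sprintf(paste0(
        "line %d: effect '%s' is not sign-definite; accepted: 1, -1, ",
        "'up-regulates*', 'down-regulates*'"), line_no[i], e))
    }
  }
  out
}

#' Read a causal interaction table
#'
#' Parses either a three-column SIF file (`source<TAB>sign<TAB>target`,
#' sign in {1,-1}) or a SIGNOR-style causal TSV with header columns
#' `ENTITYA`, `EFFECT`, `ENTITYB` (extra columns ignored; effect vocabulary
#' `up-regulates*` / `down-regulates*` or numeric signs). Duplicate
#' identical rows are collapsed; row order is irrelevant.
#'
#' @param path file path.
#' @param dialect `"three-column-sif"` or `"signor-tsv"`.
#' @return a [causal_network()].
#' @export
read_causal_table <- function(path, dialect = c("three-column-sif", "signor-tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "three-column-sif") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)))
    if (!length(keep)) return(causal_network(edges = NULL))
    parts <- strsplit(lines[keep], "[\t ]+")
    nfield <- lengths(parts)
    if (any(nfield != 3)) {
      stop(sprintf("line %d: expected 3 fields (source sign target), got %d",
                   keep[which(nfield != 3)[1]], nfield[nfield != 3][1]))
    }
    m <- do.call(rbind, parts)
    sign <- .effect_to_sign(m[, 2], keep)
    edges <- data.frame(source = m[, 1], target = m[, 3], sign = sign,
                        stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
    need <- c("ENTITYA", "EFFECT", "ENTITYB")
    if (!all(need %in% names(tab))) {
      stop("SIGNOR table must have columns ENTITYA, EFFECT, ENTITYB; found: ",
           paste(names(tab), collapse = ", "))
    }
    if (!nrow(tab)) return(causal_network(edges = NULL))
    sign <- .effect_to_sign(tab$EFFECT, seq_len(nrow(tab)) + 1L)
    edges <- data.frame(source = tab$ENTITYA, target = tab$ENTITYB,
                        sign = sign, stringsAsFactors = FALSE)
  }
  if (any(!nzchar(edges$source) | !nzchar(edges$target))) {
    stop("empty entity name in interaction table")
  }
  causal_network(edges = edges)
}

#' Write a network as a SIF file
#'
#' Tab-separated `source<TAB>sign<TAB>target`, one line per edge, no header.
#' `read_causal_table(write_sif(net))` reproduces the edge set exactly.
#'
#' @param net a `causal_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "causal_network"))
  lines <- sprintf("%s\t%d\t%s", net$edges$source, net$edges$sign, net$edges$target)
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype-regulator table
#'
#' TSV with columns `node`, `phenotype`, `effect` — the output of a
#' pathway-proximity annotation linking model proteins to the apoptosis and
#' proliferation phenotypes. Rows for other phenotypes are dropped (a count
#' is reported via `message()`); a (node, phenotype) pair listed with
#' conflicting signs is an error.
#'
#' @param path file path.
#' @return data.frame of class `regulator_table` with columns `node`,
#'   `phenotype` (`apoptosis` or `proliferation`), `effect` (+1 activator,
#'   -1 inhibitor).
#' @export
read_regulator_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node", "phenotype", "effect")
  if (!all(need %in% names(tab))) {
    stop("regulator table must have columns node, phenotype, effect")
  }
  if (any(is.na(tab$effect))) stop("missing sign in regulator table")
  tab$effect <- as.integer(tab$effect)
  if (!all(tab$effect %in% c(-1L, 1L))) stop("regulator effect must be +1 or -1")
  drop <- !(tab$phenotype %in% c("apoptosis", "proliferation"))
  if (any(drop)) {
    message(sum(drop), " row(s) with phenotypes other than apoptosis/proliferation dropped")
    tab <- tab[!drop, , drop = FALSE]
  }
  tab <- unique(tab[, need])
  key <- paste(tab$node, tab$phenotype)
  if (anyDuplicated(key)) {
    stop("conflicting signs for (node, phenotype): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  rownames(tab) <- NULL
  class(tab) <- c("regulator_table", "data.frame")
  tab
}

#' Check that a network can transmit every cue to some readout
#'
#' A trainable network must be able to display a modulation of at least one
#' sentinel for any cue applied. The report lists cues with no directed path
#' to any sentinel ("dead inputs"), sentinels unreachable from every cue
#' ("unreachable readouts"), and isolated nodes. A measured cue reports
#' itself, and a sentinel that is itself a cue is directly controlled, so
#' neither is flagged.
#'
#' @param net a `causal_network`.
#' @param design an [experimental_design()]; its stimuli, inhibitor targets
#'   and sentinel analytes must all be network nodes.
#' @return list of class `validation_report` with character vectors
#'   `dead_inputs`, `unreachable_readouts`, `isolated`, and logical `ok`.
#' @export
validate_network <- function(net, design) {
  stopifnot(inherits(net, "causal_network"))
  cues <- unique(c(design$stimuli, unname(design$inhibitors)))
  sentinels <- design$sentinels$analyte
  missing <- setdiff(c(cues, sentinels), net$nodes$name)
  if (length(missing)) {
    stop("design names absent from network: ", paste(missing, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target")], directed = TRUE,
    vertices = net$nodes$name)
  reach <- function(from) {
    names(igraph::subcomponent(g, from, mode = "out"))
  }
  # a measured cue reports itself; a sentinel that is a cue is directly
  # controlled — neither counts as a transmission failure
  dead <- cues[vapply(cues, function(cu) {
    !(cu %in% sentinels) && !any(sentinels %in% setdiff(reach(cu), cu))
  }, logical(1))]
  reached <- unique(unlist(lapply(cues, function(cu) setdiff(reach(cu), cu))))
  unreachable <- setdiff(sentinels, c(reached, cues))
  iso <- net$nodes$name[igraph::degree(g, mode = "all") == 0]
  rep <- list(dead_inputs = dead, unreachable_readouts = unreachable,
              isolated = iso,
              ok = !length(dead) && !length(unreachable))
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("network validation: OK\n")
  if (length(x$dead_inputs))
    cat("dead inputs (no path to any sentinel):",
        paste(x$dead_inputs, collapse = ", "), "\n")
  if (length(x$unreachable_readouts))
    cat("unreachable readouts:",
        paste(x$unreachable_readouts, collapse = ", "), "\n")
  if (length(x$isolated))
    cat("isolated nodes:", paste(x$isolated, collapse = ", "), "\n")
  invisible(x)
}
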