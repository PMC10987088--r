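#' Classify FLT3-ITD insertion sites into receptor domains
#'
#' Internal tandem duplications inserted in the juxtamembrane domain (JMD)
#' define the TKI-sensitive genotype; insertions in the first tyrosine
#' kinase domain (TKD1) define the resistant one. A patient carrying
#' insertions on both sides of the domain boundary is classified JMD+TKD.
#'
#' @param itd_sites integer vector of insertion amino-acid positions
#'   (nonempty, positive).
#' @param jmd_tkd_boundary first TKD1 residue; sites strictly below it are
#'   JMD.
#' @return `"JMD"`, `"TKD"`, or `"JMD+TKD"`.
#' @export
classify_itd <- function(itd_sites, jmd_tkd_boundary = 610) {
  if (!length(itd_sites)) stop("no insertion sites")
  if (any(is.na(itd_sites)) || any(itd_sites <= 0))
    stop("insertion sites must be positive integers")
  jmd <- any(itd_sites < jmd_tkd_boundary)
  tkd <- any(itd_sites >= jmd_tkd_boundary)
  if (jmd && tkd) "JMD+TKD" else if (jmd) "JMD" else "TKD"
}

.gof_effects <- c("gain-of-function", "likely gain-of-function")
.lof_effects <- c("loss-of-function", "likely loss-of-function")
.dropped_effects <- c("unknown", "inconclusive", "likely neutral",
                      "switch-of-function")

#' Binarize a patient mutational profile into node clamps
#'
#' Gain-of-function (and likely gain-of-function) variants clamp their gene
#' to 1, loss-of-function (and likely) to 0. Variants annotated Unknown,
#' Inconclusive, Likely Neutral or Switch-of-function are filtered out.
#' Genes that do not map to a model node are reported via `message()` and
#' ignored.
#'
#' @param variants data.frame with columns `gene` and `MUTATION_EFFECT`
#'   (OncoKB-style vocabulary; matching is case-insensitive).
#' @param model optional `logic_model`; when given, clamps are restricted
#'   to model species.
#' @param node_map optional named character vector mapping gene symbols to
#'   model node names (explicit aliasing only; no fuzzy matching).
#' @return named integer vector of clamps (gene/node -> 0 or 1).
#' @export
binarize_mutations <- function(variants, model = NULL, node_map = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "MUTATION_EFFECT") %in% names(variants)))
  eff <- tolower(trimws(variants$MUTATION_EFFECT))
  known <- c(.gof_effects, .lof_effects, .dropped_effects)
  bad <- !(eff %in% known)
  if (any(bad)) {
    stop("unrecognized MUTATION_EFFECT '",
         variants$MUTATION_EFFECT[bad][1], "'; accepted: ",
         paste(known, collapse = ", "))
  }
  keep <- eff %in% c(.gof_effects, .lof_effects)
  variants <- variants[keep, , drop = FALSE]
  eff <- eff[keep]
  clamps <- stats::setNames(as.integer(eff %in% .gof_effects), variants$gene)
  if (!is.null(node_map)) {
    mapped <- names(clamps) %in% names(node_map)
    names(clamps)[mapped] <- unname(node_map[names(clamps)[mapped]])
  }
  if (anyDuplicated(names(clamps))) {
    dup <- unique(names(clamps)[duplicated(names(clamps))])
    agree <- vapply(dup, function(g)
      length(unique(clamps[names(clamps) == g])) == 1, logical(1))
    if (!all(agree)) stop("conflicting clamps for: ",
                          paste(dup[!agree], collapse = ", "))
    clamps <- clamps[!duplicated(names(clamps))]
  }
  if (!is.null(model)) {
    absent <- setdiff(names(clamps), model$scaffold$species)
    if (length(absent))
      message("genes absent from the model ignored: ",
              paste(absent, collapse = ", "))
    clamps <- clamps[setdiff(names(clamps), absent)]
  }
  clamps
}

#' Match a patient's ITD class to a genotype-specific model
#'
#' JMD and JMD+TKD patients are simulated on the JMD-derived model (the
#' JMD insertion is dominant); TKD patients on the TKD-derived model.
#'
#' @param call an ITD class from [classify_itd()].
#' @param models named list with elements `JMD` and `TKD` (logic models).
#' @return the matched `logic_model`.
#' @export
match_model <- function(call, models) {
  key <- if (call %in% c("JMD", "JMD+TKD")) "JMD"
         else if (call == "TKD") "TKD"
         else stop("unknown ITD class: ", call)
  if (is.null(models[[key]])) stop("model missing for class ", key)
  models[[key]]
}

#' Simulate a patient on a genotype-matched model
#'
#' The patient's mutational clamps are applied in every condition of the
#' panel, on top of the condition clamps; condition clamps win on conflict
#' (a drug silences a gain-of-function target), and each override is
#' reported via `message()`.
#'
#' @param model a `logic_model`.
#' @param clamps named 0/1 vector from [binarize_mutations()].
#' @param endpoints list from [endpoint_regulators()].
#' @param panel condition names (subset of `untreated`, `FLT3i`,
#'   `FLT3i+<target>KO`).
#' @param receptors,anchor,complexes,max_iter see [run_condition()].
#' @return data.frame with one row per condition: `condition`,
#'   `proliferation_activation`, `apoptosis_inhibition`.
#' @export
simulate_patient <- function(model, clamps, endpoints,
                             panel = c("untreated", "FLT3i"),
                             receptors = c("FLT3", "IGF1R", "TNFR"),
                             anchor = "FLT3", complexes = NULL,
                             max_iter = 100) {
  unknown <- setdiff(names(clamps), model$scaffold$species)
  if (length(unknown)) stop("clamp on unknown node: ",
                            paste(unknown, collapse = ", "))
  rows <- lapply(panel, function(cn) {
    # rebuild the condition clamps, then overlay the patient profile
    base <- if (cn == "untreated") {
      list(on = intersect(receptors, model$scaffold$species),
           off = character())
    } else if (cn == "FLT3i") {
      list(on = setdiff(intersect(receptors, model$scaffold$species), anchor),
           off = anchor)
    } else {
      target <- sub("^FLT3i\\+(.+)KO$", "\\1", cn)
      members <- resolve_target(model, target, complexes)
      if (is.null(members)) stop("unknown knockout target: ", target)
      off <- unique(c(anchor, members))
      list(on = setdiff(intersect(receptors, model$scaffold$species), off),
           off = off)
    }
    pat_on <- names(clamps)[clamps == 1L]
    pat_off <- names(clamps)[clamps == 0L]
    overridden <- c(intersect(pat_on, base$off), intersect(pat_off, base$on))
    if (length(overridden))
      message(cn, ": condition clamps override patient clamps on ",
              paste(unique(overridden), collapse = ", "))
    cond <- list(on = unique(c(base$on, setdiff(pat_on, base$off))),
                 off = unique(c(base$off, setdiff(pat_off, base$on))))
    st <- simulate_synchronous(model, cond, max_iter = max_iter)
    sc <- phenotype_scores(st, endpoints)
    data.frame(condition = cn,
               proliferation_activation = sc$proliferation_activation,
               apoptosis_inhibition = sc$apoptosis_inhibition,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-patient expression z-scores
#'
#' Standardizes each patient's expression distribution: per column,
#' `z = (x - mean) / sd` with the sample standard deviation of that
#' patient's values.
#'
#' @param expression numeric matrix, genes x patients (>= 2 genes).
#' @return z-score matrix of the same shape; each column has mean 0.
#' @export
expression_zscores <- function(expression) {
  expression <- as.matrix(expression)
  if (nrow(expression) < 2) stop("need >= 2 genes per patient")
  sds <- apply(expression, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression column(s): ",
         paste(colnames(expression)[sds == 0], collapse = ", "))
  }
  scale(expression, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Read a patient variant table
#'
#' TSV with columns `patient`, `gene`, `MUTATION_EFFECT`.
#'
#' @param path file path.
#' @return data.frame split-ready by patient.
#' @export
read_patient_variants <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient", "gene", "MUTATION_EFFECT") %in% names(tab)))
  tab
}

#' Read a table of ITD insertion sites
#'
#' TSV with columns `patient`, `insertion_aa`.
#'
#' @param path file path.
#' @return data.frame with one row per insertion.
#' @export
read_itd_sites <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient", "insertion_aa") %in% names(tab)))
  tab$insertion_aa <- as.integer(tab$insertion_aa)
  tab
}
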