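#' Endpoint phenotype regulators of a high-confidence model
#'
#' The effector proteins used for phenotype inference are the nodes that
#' (i) are annotated as regulators of the phenotype and (ii) are terminal
#' in the retained network — they feed no selected gate, so their state is
#' not relayed further. Restricting scoring to endpoints avoids counting
#' the same signaling axis more than once.
#'
#' @param model_hc a `logic_model`, typically from
#'   [high_confidence_submodel()].
#' @param regtable a `regulator_table` (node, phenotype, effect).
#' @return list with data.frames `apoptosis` and `proliferation`
#'   (columns `node`, `effect`); a warning is emitted for a phenotype with
#'   no endpoint (its score is undefined).
#' @export
endpoint_regulators <- function(model_hc, regtable) {
  stopifnot(inherits(model_hc, "logic_model"))
  sel <- which(model_hc$selection == 1L)
  relayed <- unique(unlist(lapply(model_hc$scaffold$gates[sel],
                                  function(g) g$inputs)))
  terminal <- setdiff(model_hc$scaffold$species, relayed)
  out <- lapply(c(apoptosis = "apoptosis", proliferation = "proliferation"),
                function(ph) {
    t <- regtable[regtable$phenotype == ph & regtable$node %in% terminal,
                  c("node", "effect"), drop = FALSE]
    rownames(t) <- NULL
    if (!nrow(t)) warning("no endpoint regulator for ", ph,
                          "; its score is undefined")
    t
  })
  out
}

#' Phenotype scores from a steady state
#'
#' For each phenotype the raw score is the sum of the states of its
#' activator endpoints minus the sum of its inhibitor endpoints (equal
#' weight, OR logic), normalized by the endpoint count to `[-1, 1]`.
#' `proliferation_activation` is the normalized proliferation score;
#' `apoptosis_inhibition` is the *negative* of the normalized apoptosis
#' score, so that a high value means apoptosis is suppressed (tumor-like).
#' Unresolved endpoint states enter as 0.5.
#'
#' @param state a `steady_state` or a named numeric state vector.
#' @param endpoints list from [endpoint_regulators()].
#' @return list of class `phenotype_scores`: `proliferation_activation`,
#'   `apoptosis_inhibition` (NA when a phenotype has no endpoint), and
#'   `endpoint_states` (data.frame node, phenotype, effect, state).
#' @export
phenotype_scores <- function(state, endpoints) {
  if (inherits(state, "steady_state")) state <- state$state
  score <- function(tab) {
    if (!nrow(tab)) return(NA_real_)
    s <- state[tab$node]
    if (anyNA(match(tab$node, names(state))))
      stop("endpoint not in state: ",
           paste(setdiff(tab$node, names(state)), collapse = ", "))
    s <- ifelse(is.na(s), 0.5, s)
    sum(s * tab$effect) / nrow(tab)
  }
  ep <- do.call(rbind, lapply(names(endpoints), function(ph) {
    t <- endpoints[[ph]]
    if (!nrow(t)) return(NULL)
    data.frame(node = t$node, phenotype = ph, effect = t$effect,
               state = ifelse(is.na(state[t$node]), 0.5, state[t$node]),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    proliferation_activation = score(endpoints$proliferation),
    apoptosis_inhibition = -score(endpoints$apoptosis),
    endpoint_states = ep),
    class = "phenotype_scores")
}

#' @export
print.phenotype_scores <- function(x, ...) {
  cat(sprintf("phenotype_scores: proliferation_activation %.3f, apoptosis_inhibition %.3f\n",
              x$proliferation_activation, x$apoptosis_inhibition))
  invisible(x)
}

# "ERK1/2" -> c("ERK1","ERK2"): later parts replace the tail of the first
split_complex_name <- function(name) {
  parts <- strsplit(name, "/", fixed = TRUE)[[1]]
  if (length(parts) < 2) return(name)
  base <- parts[1]
  c(base, vapply(parts[-1], function(p) {
    paste0(substr(base, 1, nchar(base) - nchar(p)), p)
  }, character(1)))
}

# target label -> member node(s), or NULL if unresolvable
resolve_target <- function(model, target, complexes = NULL) {
  species <- model$scaffold$species
  if (target %in% species) return(target)
  if (!is.null(complexes) && target %in% names(complexes)) {
    members <- complexes[[target]]
    if (all(members %in% species)) return(members)
    return(NULL)
  }
  members <- split_complex_name(target)
  if (length(members) > 1 && all(members %in% species)) return(members)
  NULL
}

#' Simulate one treatment condition of the screen panel
#'
#' The three condition shapes mirror the malignant baseline and its
#' treatments: `untreated` clamps all receptors ON; `FLT3i` moves the
#' anchor receptor to OFF; `FLT3i+<target>KO` additionally clamps the
#' knocked-out target (complex names expand to their member nodes, all
#' clamped) to OFF.
#'
#' @param model a `logic_model` (typically the high-confidence model).
#' @param name `"untreated"`, `"FLT3i"`, or `"FLT3i+<target>KO"`.
#' @param endpoints list from [endpoint_regulators()].
#' @param receptors receptor nodes clamped ON in the untreated state.
#' @param anchor the receptor inhibited by the anchor drug.
#' @param complexes optional named list mapping complex labels to member
#'   nodes.
#' @param max_iter simulation iteration cap.
#' @return list with `state` (a `steady_state`) and `scores`
#'   (a `phenotype_scores`).
#' @export
run_condition <- function(model, name, endpoints,
                          receptors = c("FLT3", "IGF1R", "TNFR"),
                          anchor = "FLT3", complexes = NULL, max_iter = 100) {
  receptors <- intersect(receptors, model$scaffold$species)
  if (name == "untreated") {
    off <- character()
  } else if (name == "FLT3i") {
    off <- anchor
  } else if (grepl("^FLT3i\\+.+KO$", name)) {
    target <- sub("^FLT3i\\+(.+)KO$", "\\1", name)
    members <- resolve_target(model, target, complexes)
    if (is.null(members)) stop("unknown knockout target: ", target)
    off <- unique(c(anchor, members))
  } else stop("unrecognized condition name: ", name)
  cond <- list(on = setdiff(receptors, off), off = off)
  st <- simulate_synchronous(model, cond, max_iter = max_iter)
  list(state = st, scores = phenotype_scores(st, endpoints))
}

#' In silico combinatorial knockout screen
#'
#' Simulates the untreated model, the anchor inhibition alone, and the
#' anchor inhibition combined with each knockout target, and scores the
#' apoptosis-inhibition and proliferation-activation phenotypes per
#' condition. Targets that resolve to no model node are skipped and listed
#' in the `unresolved` attribute.
#'
#' @param model a `logic_model`.
#' @param endpoints list from [endpoint_regulators()].
#' @param targets knockout target labels; the default is the panel of key
#'   signaling kinases downstream of FLT3.
#' @param receptors,anchor,complexes,max_iter see [run_condition()].
#' @return data.frame of class `screen_result` with columns `condition`,
#'   `target` (NA for the two reference rows), `proliferation_activation`,
#'   `apoptosis_inhibition`, in deterministic order.
#' @export
ko_screen <- function(model, endpoints,
                      targets = c("ERK1/2", "MEK1/2", "GSK3A/B", "IGF1R",
                                  "JNK", "KRAS", "MTOR", "PDPK1", "PI3K",
                                  "p38"),
                      receptors = c("FLT3", "IGF1R", "TNFR"),
                      anchor = "FLT3", complexes = NULL, max_iter = 100) {
  resolved <- !vapply(targets, function(t)
    is.null(resolve_target(model, t, complexes)), logical(1))
  combos <- if (any(resolved))
    paste0("FLT3i+", targets[resolved], "KO") else character()
  conditions <- c("untreated", "FLT3i", combos)
  rows <- lapply(conditions, function(cn) {
    sc <- run_condition(model, cn, endpoints, receptors, anchor, complexes,
                        max_iter)$scores
    data.frame(condition = cn,
               target = if (grepl("KO$", cn))
                 sub("^FLT3i\\+(.+)KO$", "\\1", cn) else NA_character_,
               proliferation_activation = sc$proliferation_activation,
               apoptosis_inhibition = sc$apoptosis_inhibition,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unresolved") <- targets[!resolved]
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Call rescue hits from a screen of the resistant model
#'
#' A knockout is a rescue hit when, combined with the anchor inhibition, it
#' brings the resistant model's phenotypes down to the treated sensitive
#' reference on both axes: `apoptosis_inhibition <= ref + epsilon` AND
#' `proliferation_activation <= ref + epsilon`.
#'
#' @param resistant_screen a `screen_result` from the resistant model.
#' @param sensitive_reference a `phenotype_scores` (the sensitive model
#'   under the anchor inhibition) or a list with the two score fields.
#' @param epsilon slack on both axes.
#' @return character vector of hit targets; combos with undefined scores
#'   are excluded with a warning.
#' @export
rescue_hits <- function(resistant_screen, sensitive_reference, epsilon = 0) {
  ref_a <- sensitive_reference$apoptosis_inhibition
  ref_p <- sensitive_reference$proliferation_activation
  combos <- resistant_screen[!is.na(resistant_screen$target), , drop = FALSE]
  undef <- is.na(combos$apoptosis_inhibition) |
    is.na(combos$proliferation_activation)
  if (any(undef)) {
    warning("targets with undefined scores excluded: ",
            paste(combos$target[undef], collapse = ", "))
    combos <- combos[!undef, , drop = FALSE]
  }
  hit <- combos$apoptosis_inhibition <= ref_a + epsilon &
    combos$proliferation_activation <= ref_p + epsilon
  combos$target[hit]
}

#' Write a screen result as TSV
#'
#' @param screen a `screen_result`.
#' @param path output path.
#' @param hits optional character vector from [rescue_hits()] used to fill
#'   a `rescue_flag` column.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, path, hits = NULL) {
  out <- as.data.frame(screen)
  out$rescue_flag <- if (is.null(hits)) NA else
    !is.na(out$target) & out$target %in% hits
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
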