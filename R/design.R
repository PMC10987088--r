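# deterministic condition label: drugs then stimuli, "+"-joined
condition_name <- function(drugs, stimuli) {
  paste(c(drugs, stimuli), collapse = "+")
}

#' Construct an experimental design
#'
#' The design ties together the perturbation layout (conditions), the cue
#' vocabulary (stimuli and inhibitor-to-target map), the measured sentinel
#' analytes with their activity annotation, and any constitutively active
#' receptors (clamped ON in every condition unless drug-inhibited).
#'
#' @param conditions data.frame with columns `name`, `stimuli_on`,
#'   `inhibitors_on` (the latter two are list-columns or `+`-separated
#'   strings of drug/stimulus labels).
#' @param stimuli character vector of stimulus node names.
#' @param inhibitors named character vector: names are drug labels (by
#'   convention suffixed `i`), values are the target node names.
#' @param sentinels data.frame with columns `analyte` and `activity`
#'   (+1 if the measured phosphosite reports activation, -1 if inhibition).
#' @param constitutive character vector of receptor nodes that are active
#'   without stimulation (e.g. a ligand-independent mutant receptor).
#' @return object of class `experimental_design`.
#' @export
experimental_design <- function(conditions, stimuli, inhibitors, sentinels,
                                constitutive = character()) {
  stopifnot(is.data.frame(conditions),
            all(c("name", "stimuli_on", "inhibitors_on") %in% names(conditions)))
  if (anyDuplicated(conditions$name)) stop("condition names must be unique")
  tolist <- function(x) {
    if (is.list(x)) lapply(x, as.character)
    else lapply(strsplit(as.character(x), "+", fixed = TRUE),
                function(v) v[nzchar(v)])
  }
  conditions$stimuli_on <- tolist(conditions$stimuli_on)
  conditions$inhibitors_on <- tolist(conditions$inhibitors_on)
  unknown <- setdiff(unlist(conditions$inhibitors_on), names(inhibitors))
  if (length(unknown)) stop("unknown drug in conditions: ",
                            paste(unknown, collapse = ", "))
  unknown <- setdiff(unlist(conditions$stimuli_on), stimuli)
  if (length(unknown)) stop("unknown stimulus in conditions: ",
                            paste(unknown, collapse = ", "))
  sentinels <- as.data.frame(sentinels, stringsAsFactors = FALSE)
  stopifnot(all(c("analyte", "activity") %in% names(sentinels)),
            all(sentinels$activity %in% c(-1L, 1L)))
  structure(list(conditions = conditions, stimuli = stimuli,
                 inhibitors = inhibitors, sentinels = sentinels,
                 constitutive = constitutive),
            class = "experimental_design")
}

#' @export
print.experimental_design <- function(x, ...) {
  cat(sprintf("experimental_design: %d conditions, %d stimuli, %d inhibitors, %d sentinels\n",
              nrow(x$conditions), length(x$stimuli), length(x$inhibitors),
              nrow(x$sentinels)))
  invisible(x)
}

#' Enumerate the condition panel from stimulus-inhibitor pairings
#'
#' Builds the full condition list from a compact specification: each
#' inhibitor is paired with the stimulus of the pathway it acts on, and a
#' flag says whether the pairing is additionally run on top of the anchor
#' drug (the FLT3 inhibitor). The enumeration order is deterministic:
#' first the anchor drug alone, then anchor+stimulus for each stimulus,
#' then anchor+inhibitor+stimulus for the flagged pairings, then each
#' stimulus alone, then inhibitor+stimulus for every pairing.
#'
#' @param pairings data.frame with columns `drug`, `stimulus`,
#'   `with_anchor` (logical: also run combined with the anchor drug).
#' @param stimuli character vector of stimulus nodes, in panel order.
#' @param inhibitors named character vector drug -> target node; must
#'   include `anchor`.
#' @param anchor drug label of the anchor inhibitor (default `"FLT3i"`).
#' @param sentinels data.frame `analyte`/`activity` passed through.
#' @param constitutive passed through to [experimental_design()].
#' @return an `experimental_design` whose conditions are the enumerated
#'   panel. An empty `pairings` with no stimuli yields zero conditions.
#' @export
enumerate_design <- function(pairings, stimuli, inhibitors, anchor = "FLT3i",
                             sentinels = data.frame(analyte = character(),
                                                    activity = integer()),
                             constitutive = character()) {
  pairings <- as.data.frame(pairings, stringsAsFactors = FALSE)
  if (nrow(pairings) > 0) {
    stopifnot(all(c("drug", "stimulus", "with_anchor") %in% names(pairings)))
    unknown <- setdiff(pairings$drug, names(inhibitors))
    if (length(unknown)) stop("pairing references unknown drug: ",
                              paste(unknown, collapse = ", "))
  }
  rows <- list()
  add <- function(drugs, stims) {
    rows[[length(rows) + 1L]] <<- list(
      name = condition_name(drugs, stims),
      stimuli_on = list(stims), inhibitors_on = list(drugs))
  }
  if (length(stimuli) || nrow(pairings)) {
    stopifnot(anchor %in% names(inhibitors))
    add(anchor, character())
    for (s in stimuli) add(anchor, s)
    if (nrow(pairings)) {
      anchored <- pairings[pairings$with_anchor, , drop = FALSE]
      for (i in seq_len(nrow(anchored)))
        add(c(anchor, anchored$drug[i]), anchored$stimulus[i])
    }
    for (s in stimuli) add(character(), s)
    for (i in seq_len(nrow(pairings)))
      add(pairings$drug[i], pairings$stimulus[i])
  }
  conditions <- data.frame(
    name = vapply(rows, `[[`, "", "name"),
    stringsAsFactors = FALSE)
  conditions$stimuli_on <- lapply(rows, function(r) r$stimuli_on[[1]])
  conditions$inhibitors_on <- lapply(rows, function(r) r$inhibitors_on[[1]])
  if (!nrow(conditions)) {
    conditions <- data.frame(name = character(), stringsAsFactors = FALSE)
    conditions$stimuli_on <- list()
    conditions$inhibitors_on <- list()
  }
  experimental_design(conditions, stimuli, inhibitors, sentinels, constitutive)
}

#' The FLT3-ITD multiparametric perturbation design
#'
#' The 16-condition cue panel used to perturb FLT3-ITD cells: seven small
#' molecule inhibitors (Midostaurin anchoring FLT3, plus p38, JNK, PI3K,
#' mTOR, MEK1/2 and GSK3 inhibitors) and two stimuli (IGF1 driving the
#' AKT-MAPK branch, TNFa driving the p38-JNK branch), with 14 phospho
#' sentinel analytes. The GSK3 inhibitor pairing is not run on top of FLT3
#' inhibition, giving 16 conditions in total. FLT3 is constitutively
#' active (ITD receptor), so it is ON in every condition that does not
#' inhibit it.
#'
#' @return an `experimental_design` with 16 conditions.
#' @export
flt3_design <- function() {
  inhibitors <- c(FLT3i = "FLT3", p38i = "p38", JNKi = "JNK", PI3Ki = "PI3K",
                  mTORi = "mTOR", MEKi = "MEK1/2", GSK3i = "GSK3")
  pairings <- data.frame(
    drug = c("p38i", "JNKi", "PI3Ki", "mTORi", "MEKi", "GSK3i"),
    stimulus = c("TNFa", "TNFa", "IGF1", "IGF1", "IGF1", "IGF1"),
    with_anchor = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  sentinels <- data.frame(
    analyte = c("CREB1", "ERK1/2", "JNK", "p38", "STAT3", "STAT5", "p70S6K",
                "RPS6", "MTOR", "IGF1R", "PTEN", "TSC2", "GSK3A", "GSK3B"),
    activity = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, -1L, -1L, -1L, -1L),
    stringsAsFactors = FALSE)
  enumerate_design(pairings, stimuli = c("IGF1", "TNFa"),
                   inhibitors = inhibitors, anchor = "FLT3i",
                   sentinels = sentinels, constitutive = "FLT3")
}

#' Clamp vectors for one named condition of a design
#'
#' Stimuli present in the condition are clamped ON; drug-inhibited targets
#' are clamped OFF; constitutive receptors are clamped ON unless inhibited.
#' Unstimulated stimuli are left unclamped (they stay at the inactive
#' initial state).
#'
#' @param design an `experimental_design`.
#' @param condition condition name.
#' @return list with character vectors `on` and `off`.
#' @export
condition_clamps <- function(design, condition) {
  i <- match(condition, design$conditions$name)
  if (is.na(i)) stop("unknown condition: ", condition)
  stims <- design$conditions$stimuli_on[[i]]
  drugs <- design$conditions$inhibitors_on[[i]]
  off <- unname(design$inhibitors[drugs])
  on <- unique(c(stims, setdiff(design$constitutive, off)))
  list(on = on, off = unique(off))
}
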