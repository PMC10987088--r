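#' Filter bead-array measurements on detected bead count
#'
#' A median fluorescence intensity is technically reliable only when enough
#' beads were detected in the well; measurements with fewer than `min_beads`
#' beads are excluded.
#'
#' @param raw data.frame with at least a `beads` column (long format:
#'   `condition`, `analyte`, `replicate`, `timepoint`, `mfi`, `beads`).
#' @param min_beads exclusion threshold; a count equal to the threshold is
#'   kept (exclusion is strictly below).
#' @return list with data.frames `kept` and `excluded`; `excluded` gains a
#'   `reason` column (`"low-beads"`).
#' @export
filter_bead_counts <- function(raw, min_beads = 50) {
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  if (!nrow(raw)) return(list(kept = raw, excluded = raw))
  stopifnot("beads" %in% names(raw))
  if (any(raw$beads < 0)) stop("negative bead count")
  drop <- raw$beads < min_beads
  excluded <- raw[drop, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "low-beads"
  list(kept = raw[!drop, , drop = FALSE], excluded = excluded)
}

#' Normalize analyte MFI on a loading-control channel
#'
#' Divides each analyte's MFI by the loading-control MFI of the same
#' (condition, replicate, timepoint) well, then removes the control channel
#' from the analytes. Wells whose control measurement is missing (e.g.
#' excluded by the bead filter) have all their analyte values masked.
#'
#' @param raw long-format data.frame (`condition`, `analyte`, `replicate`,
#'   `timepoint`, `mfi`), already bead-filtered.
#' @param control_analyte name of the loading-control channel.
#' @return the data.frame with `value = mfi / control mfi` (NA and
#'   `reason = "missing"` where the control is absent), control rows removed.
#' @export
normalize_loading <- function(raw, control_analyte = "b-Tubulin") {
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  need <- c("condition", "analyte", "replicate", "timepoint", "mfi")
  stopifnot(all(need %in% names(raw)))
  well <- function(d) paste(d$condition, d$replicate, d$timepoint, sep = "\r")
  ctrl <- raw[raw$analyte == control_analyte, , drop = FALSE]
  out <- raw[raw$analyte != control_analyte, , drop = FALSE]
  ctrl_mfi <- ctrl$mfi[match(well(out), well(ctrl))]
  out$value <- out$mfi / ctrl_mfi
  out$reason <- ifelse(is.na(ctrl_mfi), "missing", NA_character_)
  out
}

#' Aggregate biological replicates
#'
#' Median and sample standard deviation (n-1) over unmasked replicates per
#' (condition, analyte, timepoint). Cells with a single replicate get a
#' masked SD; cells with no unmasked replicate are masked entirely.
#'
#' @param values output of [normalize_loading()].
#' @return data.frame `condition`, `analyte`, `timepoint`, `value` (median),
#'   `sd`, `n_reps`, `reason` (NA, or `"missing"` for fully masked cells).
#' @export
aggregate_replicates <- function(values) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  key <- interaction(values$condition, values$analyte, values$timepoint,
                     drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(values, key), function(d) {
    v <- d$value[!is.na(d$value)]
    data.frame(condition = d$condition[1], analyte = d$analyte[1],
               timepoint = d$timepoint[1],
               value = if (length(v)) stats::median(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_reps = length(v),
               reason = if (length(v)) NA_character_ else "missing",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Fit per-analyte Hill normalization parameters
#'
#' Maps an analyte's observed dynamic range onto (0, 1) with a Hill curve
#' `y = x^n / (K + x^n)` anchored so that the observed minimum maps to
#' `minT = 0.001` and the observed maximum to `maxT = 0.999`. Writing
#' `b = maxS / minS`, the boundary conditions give
#' `n = log(((1 - minT) * maxT) / ((1 - maxT) * minT)) / log(b)` and
#' `K = ((1 - maxT) / maxT) * maxS^n`.
#'
#' @param values positive numeric vector of loading-normalized values of
#'   one analyte across all conditions (and timepoints).
#' @param minT,maxT target images of the observed extremes.
#' @return list of class `hill_params`: `n`, `K`, `minS`, `maxS`, `b`,
#'   `minT`, `maxT`.
#' @export
fit_hill_params <- function(values, minT = 0.001, maxT = 0.999) {
  values <- values[!is.na(values)]
  if (any(values <= 0)) stop("Hill fit requires positive values")
  if (length(values) < 2) stop("Hill fit requires at least two values")
  minS <- min(values)
  maxS <- max(values)
  if (maxS == minS) stop("degenerate analyte: constant values, no dynamic range")
  b <- maxS / minS
  n <- log(((1 - minT) * maxT) / ((1 - maxT) * minT)) / log(b)
  K <- ((1 - maxT) / maxT) * maxS^n
  structure(list(n = n, K = K, minS = minS, maxS = maxS, b = b,
                 minT = minT, maxT = maxT), class = "hill_params")
}

#' Evaluate a fitted Hill normalization
#'
#' @param params a `hill_params` object.
#' @param x positive value(s) on the loading-normalized scale.
#' @return `x^n / (K + x^n)`, strictly increasing in `x`, in (0, 1).
#' @export
apply_hill <- function(params, x) {
  if (any(x <= 0, na.rm = TRUE)) stop("Hill function is defined for x > 0")
  x^params$n / (params$K + x^params$n)
}

#' Run the full normalization pipeline
#'
#' Bead filter, loading-control normalization, replicate aggregation, and
#' per-analyte Hill scaling (fitted on the pooled T0 and T1 condition
#' medians of each analyte, so the observed extremes across the whole
#' experiment anchor 0.001 and 0.999).
#'
#' @param raw long-format data.frame with columns `condition`, `analyte`,
#'   `replicate`, `timepoint` (`"T0"`/`"T1"`), `mfi`, `beads`.
#' @param design an `experimental_design`; conditions and analytes are laid
#'   out in design order.
#' @param control_analyte loading-control channel name.
#' @param min_beads bead-count exclusion threshold.
#' @return object of class `normalized_dataset`: matrices `t1`, `t0`, `sd_t1`,
#'   `sd_t0` (conditions x analytes, NA = masked), character matrix
#'   `mask_reason`, list `hill` of per-analyte parameters, and the `design`.
#' @export
normalize_dataset <- function(raw, design, control_analyte = "b-Tubulin",
                              min_beads = 50) {
  flt <- filter_bead_counts(raw, min_beads)
  ln <- normalize_loading(flt$kept, control_analyte)
  agg <- aggregate_replicates(ln)

  conditions <- design$conditions$name
  analytes <- design$sentinels$analyte
  hill <- lapply(analytes, function(a) {
    v <- agg$value[agg$analyte == a & !is.na(agg$value)]
    fit_hill_params(v)
  })
  names(hill) <- analytes

  grab <- function(tp, col) {
    m <- matrix(NA_real_, length(conditions), length(analytes),
                dimnames = list(conditions, analytes))
    d <- agg[agg$timepoint == tp, , drop = FALSE]
    idx <- cbind(match(d$condition, conditions), match(d$analyte, analytes))
    keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
    m[idx[keep, , drop = FALSE]] <- d[[col]][keep]
    m
  }
  t1_raw <- grab("T1", "value"); t0_raw <- grab("T0", "value")
  sc <- function(m) {
    for (a in analytes) m[, a] <- ifelse(is.na(m[, a]), NA,
                                         apply_hill(hill[[a]], m[, a]))
    m
  }
  mask_reason <- matrix(NA_character_, length(conditions), length(analytes),
                        dimnames = list(conditions, analytes))
  # reasons: low-beads wells surface as missing cells after aggregation
  excl <- flt$excluded[flt$excluded$analyte %in% analytes, , drop = FALSE]
  if (nrow(excl)) {
    idx <- unique(cbind(match(excl$condition, conditions),
                        match(excl$analyte, analytes)))
    idx <- idx[!is.na(idx[, 1]) & !is.na(idx[, 2]), , drop = FALSE]
    idx <- idx[is.na(t1_raw[idx]), , drop = FALSE]
    if (nrow(idx)) mask_reason[idx] <- "low-beads"
  }
  mask_reason[is.na(t1_raw) & is.na(mask_reason)] <- "missing"
  mask_reason[!is.na(t1_raw)] <- NA_character_

  structure(list(t1 = sc(t1_raw), t0 = sc(t0_raw),
                 sd_t1 = grab("T1", "sd"), sd_t0 = grab("T0", "sd"),
                 mask_reason = mask_reason, hill = hill, design = design),
            class = "normalized_dataset")
}

#' @export
print.normalized_dataset <- function(x, ...) {
  cat(sprintf("normalized_dataset: %d conditions x %d analytes, %d masked cell(s)\n",
              nrow(x$t1), ncol(x$t1), sum(is.na(x$t1))))
  invisible(x)
}

#' Serialize a normalized dataset as a MIDAS file
#'
#' MIDAS is the standard CSV dialect for perturbation datasets: `TR:` columns
#' encode the treatments (stimuli and inhibitors, 0/1), `DA:` columns the
#' data-acquisition time per analyte, `DV:` columns the measured values.
#' One row is written per condition and timepoint (times 0 and 90); masked
#' values are written as NA.
#'
#' @param dataset a `normalized_dataset`.
#' @param path output path.
#' @param t1_time acquisition time of the endpoint measurement, minutes.
#' @return `path`, invisibly.
#' @export
to_midas <- function(dataset, path, t1_time = 90) {
  design <- dataset$design
  analytes <- colnames(dataset$t1)
  stopifnot(all(!is.na(dataset$t1) | !is.na(dataset$mask_reason)))
  rng <- range(c(dataset$t1, dataset$t0), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("values outside [0,1]")
  cues <- c(design$stimuli, names(design$inhibitors))
  rows <- list()
  for (i in seq_len(nrow(design$conditions))) {
    tr <- as.integer(cues %in% c(design$conditions$stimuli_on[[i]],
                                 design$conditions$inhibitors_on[[i]]))
    for (tp in c("t0", "t1")) {
      tm <- if (tp == "t0") 0 else t1_time
      rows[[length(rows) + 1L]] <- c(
        tr, rep(tm, length(analytes)), unname(dataset[[tp]][i, ]))
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c(paste0("TR:", cues), paste0("DA:", analytes),
                   paste0("DV:", analytes))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a MIDAS file back into matrices
#'
#' Inverse of [to_midas()] for the dialect this package writes: returns the
#' T1 and T0 value matrices plus the treatment matrix.
#'
#' @param path MIDAS CSV path.
#' @return list with matrices `t1`, `t0` (rows = condition index) and `tr`
#'   (treatments), plus `analytes` and `cues`.
#' @export
read_midas <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  cues <- sub("^TR:", "", grep("^TR:", names(tab), value = TRUE))
  analytes <- sub("^DV:", "", grep("^DV:", names(tab), value = TRUE))
  da <- as.matrix(tab[, grep("^DA:", names(tab)), drop = FALSE])
  dv <- as.matrix(tab[, grep("^DV:", names(tab)), drop = FALSE])
  tr <- as.matrix(tab[, grep("^TR:", names(tab)), drop = FALSE])
  is_t0 <- da[, 1] == 0
  t0 <- dv[is_t0, , drop = FALSE]; t1 <- dv[!is_t0, , drop = FALSE]
  colnames(t0) <- colnames(t1) <- analytes
  colnames(tr) <- cues
  list(t1 = t1, t0 = t0, tr = tr[!is_t0, , drop = FALSE],
       analytes = analytes, cues = cues)
}
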