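#' Apply melt-curve and QC exclusion filters to a Ct table
#'
#' A biological replicate (species x virus x bio_rep) is excluded entirely
#' when any of its day-0 or day-2 samples shows repeated amplification
#' failure, a flagged contaminant, or a melt-curve peak departing from the
#' reference peak of positive samples by more than 1.5 degrees C for the viral
#' amplicon or 3 degrees C for the housekeeping amplicon.
#'
#' Exclusion at the replicate level: a failed measurement on either day makes
#' the day-0 vs day-2 contrast for that replicate uninterpretable.
#'
#' @param ct Ct table (see [read_ct_tsv()] for columns). `qc_flag` values
#'   `"amplification_failure"` and `"contaminant"` trigger exclusion.
#' @param reference_peaks Named numeric vector of reference melt temperatures,
#'   one entry per amplicon present (names `"viral"`, `"housekeeping"`).
#' @param viral_tol,housekeeping_tol Melt-peak tolerances in degrees C.
#' @return List with `kept` (filtered Ct table) and `log` (one row per
#'   excluded biological replicate: species, virus, bio_rep, rule, detail).
#' @export
apply_exclusion_filters <- function(ct, reference_peaks,
                                    viral_tol = 1.5, housekeeping_tol = 3.0) {
  stopifnot(is.data.frame(ct))
  amps <- unique(ct$amplicon)
  if (!all(amps %in% names(reference_peaks))) {
    stop("missing reference melt peak for amplicon(s): ",
         paste(setdiff(amps, names(reference_peaks)), collapse = ", "))
  }
  tol <- ifelse(ct$amplicon == "viral", viral_tol, housekeeping_tol)
  ref <- reference_peaks[ct$amplicon]
  qc <- if (is.null(ct$qc_flag)) rep("", nrow(ct)) else ct$qc_flag
  melt_dev <- if (is.null(ct$melt_peak)) rep(0, nrow(ct)) else {
    ifelse(is.na(ct$melt_peak), 0, abs(ct$melt_peak - ref))
  }
  rule <- rep(NA_character_, nrow(ct))
  rule[melt_dev > tol] <- "melt_peak_departure"
  rule[qc == "contaminant"] <- "contaminant"
  rule[qc == "amplification_failure"] <- "amplification_failure"

  key <- paste(ct$species, ct$virus, ct$bio_rep, sep = "|")
  bad <- !is.na(rule)
  excluded_keys <- unique(key[bad])
  log <- if (any(bad)) {
    first <- !duplicated(key[bad])
    data.frame(species = ct$species[bad][first], virus = ct$virus[bad][first],
               bio_rep = ct$bio_rep[bad][first], rule = rule[bad][first],
               detail = sprintf("day %d %s (melt deviation %.2f)",
                                ct$day[bad][first], ct$amplicon[bad][first],
                                melt_dev[bad][first]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(species = character(), virus = character(),
               bio_rep = character(), rule = character(),
               detail = character(), stringsAsFactors = FALSE)
  }
  list(kept = ct[!(key %in% excluded_keys), , drop = FALSE], log = log)
}

#' Correct between-plate variation in Ct values
#'
#' Fits, separately for each amplicon, an additive two-factor linear model of
#' Ct on plate and biological-replicate block, with sum-to-zero contrasts on
#' the plate factor, and subtracts the estimated plate effects from every Ct
#' measurement. With a single plate the input is returned unchanged. When
#' plate and biological replicate are completely confounded (each block on
#' exactly one plate and vice versa) the effects are inseparable: a warning is
#' issued and the identity correction applied.
#'
#' @param ct Ct table with `plate` and `bio_rep` columns and technical
#'   replicate columns `ct1` (and optionally `ct2`).
#' @return Ct table with corrected `ct1`/`ct2` and an attribute
#'   `"plate_effects"` (per-amplicon named vectors, summing to zero).
#' @export
correct_plate_effects <- function(ct) {
  stopifnot(all(c("plate", "bio_rep", "amplicon", "ct1") %in% names(ct)))
  plates <- unique(ct$plate)
  if (length(plates) < 2) return(ct)

  # confounding check: plate <-> block is a bijection
  tab <- table(ct$plate, ct$bio_rep) > 0
  if (all(rowSums(tab) == 1) && all(colSums(tab) == 1)) {
    warning("plate completely confounded with biological replicate; ",
            "plate effects inseparable, returning Ct values unchanged")
    return(ct)
  }

  has_ct2 <- "ct2" %in% names(ct) && any(!is.na(ct$ct2))
  effects <- list()
  for (amp in unique(ct$amplicon)) {
    i <- which(ct$amplicon == amp)
    # long over technical replicates so both measurements inform the fit
    ctv <- c(ct$ct1[i], if (has_ct2) ct$ct2[i])
    pl <- factor(rep(ct$plate[i], if (has_ct2) 2 else 1))
    br <- factor(rep(ct$bio_rep[i], if (has_ct2) 2 else 1))
    keep <- is.finite(ctv)
    fit <- if (nlevels(droplevels(br[keep])) > 1) {
      stats::lm(ctv ~ pl + br, subset = keep,
                contrasts = list(pl = "contr.sum"))
    } else {
      stats::lm(ctv ~ pl, subset = keep, contrasts = list(pl = "contr.sum"))
    }
    co <- stats::coef(fit)
    k <- nlevels(pl)
    pe <- co[grep("^pl", names(co))]
    pe[is.na(pe)] <- 0
    pe <- c(pe, -sum(pe))                    # sum-to-zero completion
    names(pe) <- levels(pl)
    ct$ct1[i] <- ct$ct1[i] - pe[ct$plate[i]]
    if (has_ct2) ct$ct2[i] <- ct$ct2[i] - pe[ct$plate[i]]
    effects[[amp]] <- pe
  }
  attr(ct, "plate_effects") <- effects
  ct
}

#' Compute log2 fold change in viral load from a Ct table
#'
#' Per biological replicate: technical-replicate Ct values are averaged, the
#' viral Ct is normalized to the housekeeping gene (`dCt = Ct_viral -
#' Ct_housekeeping` per day), and the day contrast `y = dCt_day0 - dCt_day2`
#' gives the log2 fold change; fold change in viral load is `2^y`, so viral
#' growth gives y > 0. Replicates missing any of the four required
#' measurements (2 days x 2 amplicons) are dropped with a logged reason.
#'
#' @param ct Ct table (ideally after [apply_exclusion_filters()] and
#'   [correct_plate_effects()]).
#' @return List with `obs` (data.frame species, virus, bio_rep, y) and
#'   `dropped` (replicates lacking a complete day-0/day-2 amplicon set).
#' @export
compute_fold_change <- function(ct) {
  stopifnot(all(c("species", "virus", "day", "bio_rep", "amplicon", "ct1")
                %in% names(ct)))
  if (!all(ct$day %in% c(0L, 2L))) stop("day must be 0 or 2")
  ctbar <- if ("ct2" %in% names(ct)) {
    rowMeans(cbind(ct$ct1, ct$ct2), na.rm = TRUE)
  } else ct$ct1

  key <- interaction(ct$species, ct$virus, ct$bio_rep, drop = TRUE, sep = "|")
  cell <- paste(ct$day, ct$amplicon, sep = "|")
  need <- c("0|viral", "0|housekeeping", "2|viral", "2|housekeeping")
  agg <- tapply(ctbar, list(key, factor(cell, levels = need)), mean)

  complete <- rowSums(is.na(agg)) == 0
  ids <- do.call(rbind, strsplit(rownames(agg), "|", fixed = TRUE))
  y <- (agg[, 1] - agg[, 2]) - (agg[, 3] - agg[, 4])
  obs <- data.frame(species = ids[complete, 1], virus = ids[complete, 2],
                    bio_rep = ids[complete, 3], y = unname(y[complete]),
                    stringsAsFactors = FALSE)
  obs <- obs[order(obs$species, obs$virus, obs$bio_rep), , drop = FALSE]
  rownames(obs) <- NULL
  dropped <- if (any(!complete)) {
    data.frame(species = ids[!complete, 1], virus = ids[!complete, 2],
               bio_rep = ids[!complete, 3],
               reason = apply(is.na(agg[!complete, , drop = FALSE]), 1,
                              function(m) paste("missing", paste(need[m], collapse = ", "))),
               stringsAsFactors = FALSE)
  } else {
    data.frame(species = character(), virus = character(),
               bio_rep = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  rownames(dropped) <- NULL
  list(obs = obs, dropped = dropped)
}

#' Full qPCR preprocessing pipeline
#'
#' Exclusion filters, plate correction, and fold-change computation in one
#' call.
#'
#' @param ct Raw Ct table.
#' @param reference_peaks Passed to [apply_exclusion_filters()]; `NULL` skips
#'   filtering (e.g. for synthetic data known to be clean).
#' @inheritParams apply_exclusion_filters
#' @return List with `obs`, `exclusions`, `dropped`.
#' @export
qpcr_pipeline <- function(ct, reference_peaks = NULL,
                          viral_tol = 1.5, housekeeping_tol = 3.0) {
  exclusions <- NULL
  if (!is.null(reference_peaks)) {
    f <- apply_exclusion_filters(ct, reference_peaks, viral_tol, housekeeping_tol)
    ct <- f$kept
    exclusions <- f$log
  }
  ct <- correct_plate_effects(ct)
  fc <- compute_fold_change(ct)
  list(obs = fc$obs, exclusions = exclusions, dropped = fc$dropped)
}
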