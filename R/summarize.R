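.CLASS_SYMBOLS <- c(High = "\u2714", Moderate = "\u25b2", Poor = "\u2a2f")

#' Build paired records from two feature tables
#'
#' Joins the per-(subject, structure) feature rows of the two methods and
#' attaches the per-feature signed and symmetric relative differences and,
#' when masks are supplied, the Dice coefficient and Hausdorff distance.
#'
#' @param featuresA,featuresB feature tables as produced by
#'   [extractAllFeatures()] (one method each).
#' @param overlaps optional data.frame with columns subject_id, structure,
#'   dsc, hausdorff_mm to merge in.
#' @return Paired-record data.frame: one row per (subject, structure) with
#'   `<feature>_A`, `<feature>_B`, `delta_<feature>`,
#'   `delta_rel_<feature>`, `n_voxels_A/B`, `dsc`, `hausdorff_mm`.
#' @export
buildPairedRecords <- function(featuresA, featuresB, overlaps = NULL) {
  keyCols <- c("subject_id", "structure")
  fa <- featuresA[c(keyCols, .FEATURES, "n_voxels")]
  fb <- featuresB[c(keyCols, .FEATURES, "n_voxels")]
  names(fa)[-(1:2)] <- paste0(names(fa)[-(1:2)], "_A")
  names(fb)[-(1:2)] <- paste0(names(fb)[-(1:2)], "_B")
  rec <- merge(fa, fb, by = keyCols, sort = TRUE)
  for (f in .FEATURES) {
    a <- rec[[paste0(f, "_A")]]
    b <- rec[[paste0(f, "_B")]]
    d <- a - b
    dr <- ifelse(a + b == 0, 0, 2 * abs(a - b) / (a + b) * 100)
    dr[is.na(a) | is.na(b)] <- NA_real_
    d[is.na(a) | is.na(b)] <- NA_real_
    rec[[paste0("delta_", f)]] <- d
    rec[[paste0("delta_rel_", f)]] <- dr
  }
  if (!is.null(overlaps))
    rec <- merge(rec, overlaps[c(keyCols, "dsc", "hausdorff_mm")],
                 by = keyCols, all.x = TRUE, sort = TRUE)
  rec[order(rec$structure, rec$subject_id), , drop = FALSE]
}

#' Summarise between-method agreement across a cohort
#'
#' For every (structure, feature) computes: the number of evaluable
#' subjects (feature defined under both methods), the proportions of
#' subjects with symmetric relative difference within 10% and 20%, the
#' reproducibility class, the paired Wilcoxon p-value on the raw feature
#' values, the Spearman rank correlation, the mean and SD of the absolute
#' difference and the range of the signed difference. SUVpeak is classed
#' `NA` (and its tests are not run) for structures failing the strict
#' more-than-50%-of-subjects evaluability rule under either method.
#' Records should already be filtered with [excludeMissing()].
#'
#' @param records paired-record data.frame from [buildPairedRecords()].
#' @param rule a [classificationRule()].
#' @return A [CohortSummary-class].
#' @export
summarizeCohort <- function(records, rule = classificationRule()) {
  structures <- sort(unique(records$structure))
  rows <- list()
  for (s in structures) {
    rs <- records[records$structure == s, , drop = FALSE]
    for (f in .FEATURES) {
      a <- rs[[paste0(f, "_A")]]
      b <- rs[[paste0(f, "_B")]]
      dr <- rs[[paste0("delta_rel_", f)]]
      dd <- rs[[paste0("delta_", f)]]
      ok <- !(is.na(a) | is.na(b))
      nEval <- sum(ok)
      evaluable <- f != "suv_peak" || suvPeakEvaluable(rs)
      if (!evaluable || nEval == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          structure = s, feature = f, n_evaluable = nEval,
          prop_within_10 = NA_real_, prop_within_20 = NA_real_,
          class = NA_character_, wilcoxon_p = NA_real_,
          significant = NA, spearman_rs = NA_real_,
          mean_abs_delta = NA_real_, sd_abs_delta = NA_real_,
          min_delta = NA_real_, max_delta = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      wt <- pairedWilcoxon(a[ok], b[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        structure = s, feature = f, n_evaluable = nEval,
        prop_within_10 = mean(dr[ok] <= rule$high_threshold),
        prop_within_20 = mean(dr[ok] <= rule$moderate_threshold),
        class = classifyStructure(dr[ok], rule),
        wilcoxon_p = wt$p, significant = wt$significant,
        spearman_rs = spearmanRank(a[ok], b[ok]),
        mean_abs_delta = mean(abs(dd[ok])),
        sd_abs_delta = stats::sd(abs(dd[ok])),
        min_delta = min(dd[ok]), max_delta = max(dd[ok]),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  globals <- do.call(rbind, lapply(.FEATURES, function(f) {
    tf <- tab[tab$feature == f & !is.na(tab$class), , drop = FALSE]
    data.frame(feature = f,
               n_structures = nrow(tf),
               n_significant = sum(tf$significant, na.rm = TRUE),
               min_rs = if (all(is.na(tf$spearman_rs))) NA_real_
                        else min(tf$spearman_rs, na.rm = TRUE),
               max_rs = if (all(is.na(tf$spearman_rs))) NA_real_
                        else max(tf$spearman_rs, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  new("CohortSummary", table = tab, globals = globals, rule = rule)
}

#' Render the per-structure class grid
#'
#' One row per structure, one column per feature, each cell the class
#' symbol: High (check mark), Moderate (triangle), Poor (cross), NA for structures
#' where SUVpeak was not evaluable (or no subject survived exclusion).
#'
#' @param summary a [CohortSummary-class].
#' @param markdown render as a markdown table (default) or aligned text.
#' @return Character vector of lines, invisibly printable via `cat`.
#' @export
formatSummaryGrid <- function(summary, markdown = TRUE) {
  tab <- summaryTable(summary)
  structures <- sort(unique(tab$structure))
  featLabels <- c(volume_ml = "Volume", suv_max = "SUVmax",
                  suv_peak = "SUVpeak", suv_mean = "SUVmean",
                  suv_median = "SUVmedian")
  cell <- function(s, f) {
    cls <- tab$class[tab$structure == s & tab$feature == f]
    if (length(cls) != 1L || is.na(cls)) "NA" else .CLASS_SYMBOLS[[cls]]
  }
  body <- vapply(structures, function(s)
    paste(c(s, vapply(.FEATURES, cell, character(1), s = s)),
          collapse = " | "), character(1))
  header <- paste(c("Structure", unname(featLabels[.FEATURES])),
                  collapse = " | ")
  if (markdown) {
    sep <- paste(rep("---", length(.FEATURES) + 1L), collapse = " | ")
    c(paste("|", header, "|"), paste("|", sep, "|"),
      paste("|", body, "|"))
  } else {
    c(header, body)
  }
}
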