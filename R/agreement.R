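.FEATURES <- c("volume_ml", "suv_max", "suv_peak", "suv_mean", "suv_median")

#' Per-feature differences between two methods
#'
#' For each feature f of one (subject, structure):
#' delta(f) = f_A - f_B (signed), and the symmetric relative difference
#' delta_rel(f) = 2 |f_A - f_B| / (f_A + f_B) x 100 (%), bounded by 200%
#' for non-negative features. When either side is UNDEFINED (`NA`) both
#' outputs are `NA`; when both sides are exactly 0 the relative difference
#' is defined as 0% (perfect agreement on absence).
#'
#' @param featuresA,featuresB one-row data.frames (or named lists) holding
#'   the five features for the same (subject, structure) under each method.
#' @return A data.frame with columns feature, value_A, value_B, delta,
#'   delta_rel.
#' @export
computeDeltas <- function(featuresA, featuresB) {
  out <- lapply(.FEATURES, function(f) {
    a <- as.numeric(featuresA[[f]])
    b <- as.numeric(featuresB[[f]])
    if (length(a) != 1L || length(b) != 1L)
      stop("expected exactly one value per feature, got feature ", f)
    if (is.na(a) || is.na(b)) {
      d <- NA_real_; dr <- NA_real_
    } else {
      d <- a - b
      dr <- if (a + b == 0) 0 else 2 * abs(a - b) / (a + b) * 100
    }
    data.frame(feature = f, value_A = a, value_B = b, delta = d,
               delta_rel = dr, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' The default reproducibility classification rule
#'
#' High: delta_rel <= 10% in at least 80% of subjects; Moderate:
#' delta_rel <= 20% in at least 80%; otherwise Poor (equivalently, more
#' than 20% of subjects above 20%). Tiers are evaluated strictly in that
#' precedence order, which makes them exhaustive and disjoint at the exact
#' 80% boundary.
#'
#' @param highThreshold,moderateThreshold delta_rel thresholds in %.
#' @param highProportion,moderateProportion required proportions in (0, 1].
#' @return A classification rule (list).
#' @export
classificationRule <- function(highThreshold = 10, moderateThreshold = 20,
                               highProportion = 0.8,
                               moderateProportion = 0.8) {
  stopifnot(highThreshold > 0, moderateThreshold > 0,
            highProportion > 0, highProportion <= 1,
            moderateProportion > 0, moderateProportion <= 1)
  list(high_threshold = highThreshold,
       moderate_threshold = moderateThreshold,
       high_proportion = highProportion,
       moderate_proportion = moderateProportion)
}

#' Classify one structure's reproducibility
#'
#' Applies the tiered rule to the defined delta_rel values of one
#' (structure, feature) across the cohort. UNDEFINED entries must be
#' removed upstream. The rule is monotone: decreasing any delta_rel value
#' never demotes the class.
#'
#' @param deltaRel numeric vector of defined delta_rel values (%).
#' @param rule a [classificationRule()].
#' @return "High", "Moderate" or "Poor"; `NA` for empty input.
#' @export
classifyStructure <- function(deltaRel, rule = classificationRule()) {
  deltaRel <- deltaRel[!is.na(deltaRel)]
  if (length(deltaRel) == 0L) return(NA_character_)
  if (mean(deltaRel <= rule$high_threshold) >= rule$high_proportion)
    return("High")
  if (mean(deltaRel <= rule$moderate_threshold) >= rule$moderate_proportion)
    return("Moderate")
  "Poor"
}

#' SUVpeak evaluability rule
#'
#' SUVpeak reproducibility is assessed for a structure only when SUVpeak
#' was successfully computed in strictly more than 50% of subjects under
#' each method separately (the 1 cm3 sphere does not fit small or thin
#' structures).
#'
#' @param records paired-record data.frame rows of one structure (columns
#'   `suv_peak_A`, `suv_peak_B`).
#' @return TRUE when the structure is evaluable for SUVpeak.
#' @export
suvPeakEvaluable <- function(records) {
  n <- nrow(records)
  if (n == 0L) return(FALSE)
  mean(!is.na(records$suv_peak_A)) > 0.5 &&
    mean(!is.na(records$suv_peak_B)) > 0.5
}

#' Exclude subjects with a missing segmentation
#'
#' For each structure, drops subjects for whom at least one method produced
#' no segmentation (empty or missing mask). Every exclusion is logged
#' (subject, structure, offending method) and returned in the
#' `"exclusions"` attribute so per-structure subject counts stay auditable.
#'
#' @param records paired-record data.frame (columns `n_voxels_A`,
#'   `n_voxels_B`).
#' @param quiet suppress per-exclusion messages.
#' @return The surviving records, with attribute `exclusions`.
#' @export
excludeMissing <- function(records, quiet = FALSE) {
  emptyA <- is.na(records$n_voxels_A) | records$n_voxels_A == 0L
  emptyB <- is.na(records$n_voxels_B) | records$n_voxels_B == 0L
  drop <- emptyA | emptyB
  excl <- data.frame(
    subject_id = records$subject_id[drop],
    structure = records$structure[drop],
    method = ifelse(emptyA[drop] & emptyB[drop], "both",
                    ifelse(emptyA[drop], "A", "B")),
    stringsAsFactors = FALSE)
  if (!quiet && nrow(excl))
    for (r in seq_len(nrow(excl)))
      message(sprintf("excluding subject %s, structure %s: no segmentation from method %s",
                      excl$subject_id[r], excl$structure[r], excl$method[r]))
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided paired Wilcoxon test on the differences A - B: zero
#' differences are dropped, ties get mid-ranks, and the null distribution
#' of the signed-rank statistic is computed exactly (by the shift algorithm
#' over the 2^n sign assignments) for n <= `exactMax`, with the normal
#' approximation with continuity correction above. The two-sided p-value is
#' min(1, 2 min(P(W <= w), P(W >= w))). All differences zero is a
#' degenerate case reported as p = 1 and flagged.
#'
#' @param valuesA,valuesB equal-length paired numeric vectors.
#' @param exactMax largest n (after dropping zeros) for the exact null.
#' @return list(p = p-value, statistic = signed-rank sum W, n = pairs used,
#'   significant = p < 0.05, degenerate = logical, exact = logical).
#' @export
pairedWilcoxon <- function(valuesA, valuesB, exactMax = 25L) {
  if (length(valuesA) != length(valuesB))
    stop("paired samples must have equal length")
  keep <- !(is.na(valuesA) | is.na(valuesB))
  d <- valuesA[keep] - valuesB[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p = 1, statistic = 0, n = 0L, significant = FALSE,
                degenerate = TRUE, exact = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactMax) {
    # exact null over all 2^n sign assignments: distribution of the sum of
    # a random subset of the (doubled, hence integer) ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1L)  # dist[s+1] = #assignments with 2W == s
    dist[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), dist[seq_len(total + 1L - rr)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * W))
    lower <- sum(dist[seq_len(w2 + 1L)])
    upper <- sum(dist[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(lower, upper))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(p = p, statistic = W, n = n, significant = p < 0.05,
       degenerate = FALSE, exact = exact)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged). `NA` when either
#' vector is constant (undefined ranks correlation) or n < 3.
#'
#' @param valuesA,valuesB equal-length numeric vectors.
#' @return rS in [-1, 1], or `NA`.
#' @export
spearmanRank <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB))
    stop("samples must have equal length")
  keep <- !(is.na(valuesA) | is.na(valuesB))
  a <- valuesA[keep]; b <- valuesB[keep]
  if (length(a) < 3L) return(NA_real_)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = "spearman")
}
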