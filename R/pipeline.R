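# Pipeline stages over an on-disk cohort: phantom generation -> feature
# extraction -> agreement analysis -> report. CSV is the interchange format
# between stages so each stage is independently testable; exclusions and
# undefined features are logged one line each, keeping per-structure
# subject counts auditable.

#' Resample a scalar image onto an explicit grid
#'
#' Trilinear resampling of a [ScalarImage-class] onto the given
#' [ImageGrid-class] (used to bring a PET volume onto the masks' resampled
#' grid when the two were resampled from different native grids).
#'
#' @param image a [ScalarImage-class].
#' @param grid target [ImageGrid-class].
#' @return A [ScalarImage-class] on `grid`.
#' @export
resampleImageToGrid <- function(image, grid) {
  if (.isIdentityResample(image@grid, grid)) return(image)
  scalarImage(.resampleTrilinear(image@values, image@grid, grid), grid,
              unit = image@unit)
}

.readManifest <- function(cohortDir) {
  path <- file.path(cohortDir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv in ", cohortDir)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Load one subject's resampled masks for one method.
.loadMethodMasks <- function(segPath, smap, method, targetSpacing) {
  vol <- readVolume(segPath)
  if (!vol$isLabel)
    stop("expected an integer label volume: ", segPath)
  rs <- resampleLabels(vol$labels, vol$grid, targetSpacing)
  masks <- lapply(names(smap), function(s)
    extractStructureMask(rs$labels, s, smap[[s]][[method]], rs$grid))
  names(masks) <- names(smap)
  masks
}

#' Stage 1: generate a phantom cohort on disk
#'
#' Thin wrapper over [generateCohort()].
#'
#' @param spec a [phantomCohortSpec()]; default [defaultCohortSpec()].
#' @param outDir cohort directory to create.
#' @return The manifest data.frame, invisibly.
#' @export
runPhantom <- function(spec = defaultCohortSpec(), outDir) {
  generateCohort(spec, outDir)
}

#' Stage 2: extract per-structure features for a cohort
#'
#' Reads each subject's PET and both label volumes, resamples everything
#' onto the fixed isotropic grid (masks nearest-neighbour, PET trilinear,
#' onto the masks' grid), extracts the five features per structure and
#' method, and writes one CSV row per (subject, structure, method). A
#' missing volume file is reported and the run continues with the
#' remaining subjects.
#'
#' @param cohortDir cohort directory (as laid out by [runPhantom()]).
#' @param outPath output CSV path (default `features.csv` in `cohortDir`).
#' @param targetSpacing isotropic analysis voxel size in mm (default 2).
#' @param structureMap optional structure map (list or path); default
#'   `structure_map.yaml` in the cohort directory.
#' @return The feature table, invisibly; written to `outPath`.
#' @export
runExtract <- function(cohortDir, outPath = file.path(cohortDir, "features.csv"),
                       targetSpacing = 2, structureMap = NULL) {
  manifest <- .readManifest(cohortDir)
  smap <- if (is.null(structureMap))
    readStructureMap(file.path(cohortDir, "structure_map.yaml"))
  else if (is.character(structureMap)) readStructureMap(structureMap)
  else structureMap
  kernel <- buildSphereKernel(targetSpacing)
  rows <- list()
  for (r in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[r]
    paths <- c(manifest$pet[r], manifest$seg_A[r], manifest$seg_B[r])
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      message("skipping subject ", sid, ": missing file(s) ",
              paste(missing, collapse = ", "))
      next
    }
    pet <- readVolume(manifest$pet[r], unit = "SUV_bw")$image
    pet <- resampleToIsotropic(pet, targetSpacing)
    for (method in c("A", "B")) {
      segPath <- manifest[[paste0("seg_", method)]][r]
      masks <- .loadMethodMasks(segPath, smap, method, targetSpacing)
      petOnGrid <- resampleImageToGrid(pet, gridOf(masks[[1]]))
      rows[[length(rows) + 1L]] <-
        extractAllFeatures(petOnGrid, masks, names(smap),
                           subjectId = sid, method = method,
                           kernel = kernel)
    }
  }
  if (!length(rows)) stop("no subjects could be extracted from ", cohortDir)
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  utils::write.csv(features, outPath, row.names = FALSE)
  invisible(features)
}

#' Stage 3: paired agreement analysis and cohort summary
#'
#' Joins the two methods' features per (subject, structure), computes Dice
#' and Hausdorff from the mask volumes, applies the exclusion rule
#' (subjects with a missing segmentation are dropped per structure, with a
#' log line each), the SUVpeak evaluability rule, the reproducibility
#' classification, paired Wilcoxon tests and Spearman correlations, and
#' writes `paired_records.csv`, `cohort_summary.csv`,
#' `cohort_globals.csv`, `exclusions.csv` and the class-symbol grid
#' `summary_grid.md`.
#'
#' @param cohortDir cohort directory (for the mask volumes).
#' @param featuresPath features CSV from [runExtract()].
#' @param outDir output directory (default `cohortDir`).
#' @param targetSpacing isotropic analysis voxel size in mm.
#' @param rule a [classificationRule()].
#' @param quiet suppress exclusion log lines.
#' @return list(records, summary, exclusions), invisibly.
#' @export
runCompare <- function(cohortDir,
                       featuresPath = file.path(cohortDir, "features.csv"),
                       outDir = cohortDir, targetSpacing = 2,
                       rule = classificationRule(), quiet = FALSE) {
  features <- utils::read.csv(featuresPath, stringsAsFactors = FALSE)
  manifest <- .readManifest(cohortDir)
  smap <- readStructureMap(file.path(cohortDir, "structure_map.yaml"))
  featA <- features[features$method == "A", , drop = FALSE]
  featB <- features[features$method == "B", , drop = FALSE]
  # overlap metrics from the mask volumes
  overlapRows <- list()
  for (r in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[r]
    if (!sid %in% featA$subject_id) next
    if (!file.exists(manifest$seg_A[r]) || !file.exists(manifest$seg_B[r]))
      next
    masksA <- .loadMethodMasks(manifest$seg_A[r], smap, "A", targetSpacing)
    masksB <- .loadMethodMasks(manifest$seg_B[r], smap, "B", targetSpacing)
    for (s in names(smap)) {
      bothEmpty <- !any(masksA[[s]]@membership) && !any(masksB[[s]]@membership)
      overlapRows[[length(overlapRows) + 1L]] <- data.frame(
        subject_id = sid, structure = s,
        dsc = if (bothEmpty) NA_real_
              else diceCoefficient(masksA[[s]], masksB[[s]]),
        hausdorff_mm = hausdorffDistance(masksA[[s]], masksB[[s]]),
        stringsAsFactors = FALSE)
    }
  }
  overlaps <- do.call(rbind, overlapRows)
  records <- buildPairedRecords(featA, featB, overlaps)
  records <- excludeMissing(records, quiet = quiet)
  exclusions <- attr(records, "exclusions")
  if (nrow(records) == 0L)
    stop("no paired records left after exclusion (",
         nrow(exclusions), " excluded)")
  summary <- summarizeCohort(records, rule)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(records, file.path(outDir, "paired_records.csv"),
                   row.names = FALSE)
  utils::write.csv(summaryTable(summary),
                   file.path(outDir, "cohort_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(summaryGlobals(summary),
                   file.path(outDir, "cohort_globals.csv"),
                   row.names = FALSE)
  utils::write.csv(exclusions, file.path(outDir, "exclusions.csv"),
                   row.names = FALSE)
  writeLines(formatSummaryGrid(summary),
             file.path(outDir, "summary_grid.md"))
  invisible(list(records = records, summary = summary,
                 exclusions = exclusions))
}

#' Stage 4: re-render the class grid from a cohort summary CSV
#'
#' @param summaryPath `cohort_summary.csv` from [runCompare()].
#' @param outPath output markdown path (default `summary_grid.md` next to
#'   the summary).
#' @param rule a [classificationRule()] (recorded in the object only).
#' @return The grid lines, invisibly.
#' @export
runReport <- function(summaryPath,
                      outPath = file.path(dirname(summaryPath),
                                          "summary_grid.md"),
                      rule = classificationRule()) {
  tab <- utils::read.csv(summaryPath, stringsAsFactors = FALSE)
  summary <- new("CohortSummary", table = tab,
                 globals = data.frame(), rule = rule)
  lines <- formatSummaryGrid(summary)
  writeLines(lines, outPath)
  invisible(lines)
}
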