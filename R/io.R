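#' Read a NIfTI volume
#'
#' Reads a 3-D NIfTI volume (.nii or .nii.gz), reorients it to the package's
#' fixed RAS convention and populates grid metadata (spacing, origin) from
#' the header. Integer-typed volumes are flagged as label volumes and keep
#' their integer values; floating-point volumes become [ScalarImage-class]
#' objects.
#'
#' @param path path to a readable NIfTI file.
#' @param unit unit tag to attach to scalar volumes (NIfTI headers do not
#'   carry SUV semantics); one of "SUV_bw", "Bq_per_mL", "unitless".
#' @return A list with elements `image` (a [ScalarImage-class], or `NULL`
#'   for label volumes), `labels` (integer array, or `NULL` for scalar
#'   volumes), `grid` (the [ImageGrid-class]) and `isLabel` (logical).
#' @export
readVolume <- function(path, unit = "unitless") {
  if (!file.exists(path))
    stop("cannot read volume: no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]   # degenerate 4th dimension
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected 3-D volume in '", path, "', got ", length(d), "-D data")
  if (!identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (any(abs(rot - diag(diag(rot))) > 1e-4 * max(abs(diag(rot)))))
    stop("oblique volumes are not supported: ", path)
  grid <- imageGrid(dim(img), spacing = abs(diag(rot)), origin = xf[1:3, 4])
  isLabel <- is.integer(img[1])
  vals <- array(as.vector(img), dim(img))
  if (any(!is.finite(vals)))
    stop("non-finite voxel values in '", path, "'")
  if (isLabel) {
    storage.mode(vals) <- "integer"
    list(image = NULL, labels = vals, grid = grid, isLabel = TRUE)
  } else {
    list(image = scalarImage(vals, grid, unit = unit), labels = NULL,
         grid = grid, isLabel = FALSE)
  }
}

#' Write a volume to NIfTI
#'
#' Writes a [ScalarImage-class], [LabelMask-class] or integer label array to
#' a NIfTI-1 file with full grid metadata (spacing and origin in the sform).
#' Scalar images are stored as float64 by default so that write/read
#' round-trips preserve values bit-wise; label volumes as int32; masks as
#' int16 0/1.
#'
#' @param x a [ScalarImage-class], [LabelMask-class], or integer 3-D array.
#' @param path output path (.nii or .nii.gz).
#' @param grid required [ImageGrid-class] when `x` is a bare array.
#' @param datatype on-disk type for scalar images: "double" (default;
#'   bit-wise round trips) or "float" (float32, halves cohort size on
#'   disk).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path, grid = NULL, datatype = "double") {
  if (is(x, "ScalarImage")) {
    arr <- x@values; grid <- x@grid
    dtype <- match.arg(datatype, c("double", "float"))
  } else if (is(x, "LabelMask")) {
    arr <- array(as.integer(x@membership), dim(x@membership))
    grid <- x@grid; dtype <- "int16"
  } else if (is.array(x) && is.integer(x)) {
    if (is.null(grid)) stop("grid is required when writing a bare array")
    arr <- x; dtype <- "int32"
  } else stop("cannot write object of class ", class(x)[1])
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid@spacing
  m <- diag(c(grid@spacing, 1))
  m[1:3, 4] <- grid@origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Extract one structure mask from a multi-label volume
#'
#' Membership is the union over the given label ids (e.g. left and right
#' organ halves merged into one volume of interest). An empty result is a
#' valid empty mask.
#'
#' @param labels integer 3-D array of segmentation labels.
#' @param name structure name for the resulting mask.
#' @param labelIds non-empty integer vector of label ids.
#' @param grid the [ImageGrid-class] of the label volume.
#' @return A [LabelMask-class].
#' @export
extractStructureMask <- function(labels, name, labelIds, grid = NULL) {
  if (length(labelIds) == 0L)
    stop("labelIds must be a non-empty set of integer labels")
  if (is.null(grid)) grid <- imageGrid(dim(labels))
  member <- array(labels %in% as.integer(labelIds), dim(labels))
  labelMask(member, grid, structure = name)
}

#' Read a structure map
#'
#' A structure map names the anatomical structures to analyse and, per
#' segmentation method, the integer label ids whose union forms each
#' structure's volume of interest. Format (YAML or JSON):
#' \preformatted{
#' structures:
#'   liver:    {A: [3], B: [3]}
#'   kidneys:  {A: [5, 6], B: [7, 8]}
#' }
#' A bare list of ids is taken to apply to both methods.
#'
#' @param path YAML (or JSON) file path.
#' @return Named list: structure -> list(A = ids, B = ids).
#' @export
readStructureMap <- function(path) {
  if (!file.exists(path)) stop("no such structure map: ", path)
  raw <- yaml::read_yaml(path)
  entries <- if (!is.null(raw$structures)) raw$structures else raw
  if (length(entries) == 0L) stop("structure map is empty: ", path)
  out <- lapply(entries, function(e) {
    if (is.list(e) && !is.null(e$A))
      list(A = as.integer(unlist(e$A)),
           B = as.integer(unlist(if (is.null(e$B)) e$A else e$B)))
    else
      list(A = as.integer(unlist(e)), B = as.integer(unlist(e)))
  })
  bad <- vapply(out, function(e) length(e$A) == 0L || length(e$B) == 0L,
                logical(1))
  if (any(bad))
    stop("structure map entries without label ids: ",
         paste(names(out)[bad], collapse = ", "))
  out
}

#' Convert an activity-concentration image to body-weight SUV
#'
#' SUV_bw = concentration [Bq/mL] x body weight [g] / injected dose [Bq].
#' The injected dose is assumed decay-corrected to acquisition start.
#' Images already tagged SUV_bw pass through unchanged.
#'
#' @param image a [ScalarImage-class] in Bq_per_mL (or already SUV_bw).
#' @param weightKg body weight in kilograms (> 0).
#' @param doseMBq injected dose in MBq (> 0).
#' @return A [ScalarImage-class] in SUV_bw.
#' @export
activityToSUV <- function(image, weightKg, doseMBq) {
  if (imageUnit(image) == "SUV_bw") return(image)
  if (imageUnit(image) != "Bq_per_mL")
    stop("activityToSUV expects a Bq_per_mL image, got ", imageUnit(image))
  if (missing(weightKg) || missing(doseMBq) ||
      !is.finite(weightKg) || !is.finite(doseMBq) ||
      weightKg <= 0 || doseMBq <= 0)
    stop("valid body weight (kg) and injected dose (MBq) are required")
  scale <- (weightKg * 1000) / (doseMBq * 1e6)
  scalarImage(image@values * scale, image@grid, unit = "SUV_bw")
}
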