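#' Read ROI specifications from a TSV file
#'
#' Expects columns `label`, `x`, `y`, `z` (MNI mm) and optionally `extent`
#' (mm; defaults to 6).
#'
#' @param path TSV file path.
#' @param default_extent extent used when the file has no `extent` column.
#' @return data.frame of ROI specs.
#' @export
read_roi_specs <- function(path, default_extent = 6) {
  specs <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(specs)))
    stop("ROI spec file must have columns label, x, y, z")
  if (is.null(specs$extent)) specs$extent <- default_extent
  if (any(specs$extent <= 0)) stop("extent must be positive")
  specs
}

#' ROI time-series container
#'
#' @param data numeric matrix, time x ROI; column names are ROI labels.
#' @param TR repetition time, s.
#' @param subject,run identifiers.
#' @param normalized whether columns are z-scored.
#' @return object of class `"roi_timeseries"`.
#' @export
roi_timeseries <- function(data, TR = 2, subject = NA, run = NA,
                           normalized = FALSE) {
  stopifnot(is.matrix(data), all(is.finite(data)))
  structure(list(data = data, TR = TR, subject = subject, run = run,
                 normalized = normalized),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: %d volumes x %d ROIs, TR = %g s%s\n",
              nrow(x$data), ncol(x$data), x$TR,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Extract peak-centred ROI time series from a 4D image
#'
#' For each ROI, averages the series of all voxels whose centres fall inside
#' the neighbourhood of the peak coordinate: an axis-aligned cube of side
#' `extent` mm (half-open on the upper face of each axis, so boundary
#' membership is unambiguous), or a sphere of radius `extent` mm. Voxel
#' membership is decided on voxel centres mapped through the image affine.
#'
#' @param image 4D NIfTI image (path or `RNifti` image).
#' @param specs data.frame with `label`, `x`, `y`, `z`, `extent`
#'   (see [read_roi_specs()]).
#' @param shape `"cube"` (extent = side) or `"sphere"` (extent = radius).
#' @param TR repetition time; if `NULL`, taken from the image header.
#' @return an [roi_timeseries()] (not normalized).
#' @export
extract_roi_timeseries <- function(image, specs,
                                   shape = c("cube", "sphere"), TR = NULL) {
  shape <- match.arg(shape)
  if (is.character(image)) image <- RNifti::readNifti(image)
  dm <- dim(image)
  if (length(dm) != 4) stop("a 4D image is required")
  aff <- RNifti::xform(image)
  if (abs(det(aff[1:3, 1:3])) < 1e-12)
    stop("non-invertible image affine")
  if (is.null(TR)) {
    pd <- RNifti::pixdim(image)
    TR <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  arr <- as.array(image)
  n_t <- dm[4]
  out <- matrix(NA_real_, n_t, nrow(specs),
                dimnames = list(NULL, specs$label))
  for (k in seq_len(nrow(specs))) {
    centre <- c(specs$x[k], specs$y[k], specs$z[k])
    extent <- specs$extent[k]
    # bounding box in voxel space around the centre
    cv <- RNifti::worldToVoxel(centre, image)
    vox_size <- sqrt(colSums(aff[1:3, 1:3]^2))
    rad_vox <- ceiling(extent / min(vox_size)) + 1
    ranges <- lapply(1:3, function(d)
      max(1, floor(cv[d] - rad_vox)):min(dm[d], ceiling(cv[d] + rad_vox)))
    grid <- as.matrix(expand.grid(i = ranges[[1]], j = ranges[[2]],
                                  kk = ranges[[3]]))
    if (nrow(grid) == 0)
      stop(sprintf("ROI '%s' does not intersect the image grid",
                   specs$label[k]))
    world <- t(aff %*% rbind(t(grid) - 1, 1))[, 1:3, drop = FALSE]
    member <- if (shape == "cube") {
      apply(world, 1, function(w)
        all(w >= centre - extent / 2 & w < centre + extent / 2))
    } else {
      sqrt(rowSums(sweep(world, 2, centre)^2)) <= extent
    }
    if (!any(member))
      stop(sprintf("ROI '%s' contains no voxel centres", specs$label[k]))
    vox <- grid[member, , drop = FALSE]
    series <- vapply(seq_len(nrow(vox)), function(r)
      arr[vox[r, 1], vox[r, 2], vox[r, 3], ], numeric(n_t))
    out[, k] <- rowMeans(series)
  }
  roi_timeseries(out, TR = TR)
}

#' Z-score ROI columns within a run
#'
#' Normalizes each ROI column to mean 0 and unit (sample) variance within
#' the run. Idempotent within floating tolerance and invariant to affine
#' rescaling of the input.
#'
#' @param ts an [roi_timeseries()] or plain time x ROI matrix.
#' @return the normalized object (flag set).
#' @export
normalize_per_run <- function(ts) {
  is_obj <- inherits(ts, "roi_timeseries")
  m <- if (is_obj) ts$data else ts
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("zero-variance column(s) %s%s",
                 paste(bad, collapse = ", "),
                 if (is_obj && !is.na(ts$run))
                   sprintf(" in run %s", ts$run) else ""))
  }
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z <- matrix(as.numeric(z), nrow(m), ncol(m),
              dimnames = dimnames(m))
  if (is_obj) {
    ts$data <- z
    ts$normalized <- TRUE
    ts
  } else z
}

#' Write / read ROI time series as TSV (time x ROI)
#' @param ts an [roi_timeseries()].
#' @param path file path.
#' @export
write_roi_timeseries <- function(ts, path) {
  utils::write.table(as.data.frame(ts$data), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_timeseries
#' @param TR,subject,run metadata for the returned object.
#' @export
read_roi_timeseries <- function(path, TR = 2, subject = NA, run = NA) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  roi_timeseries(m, TR = TR, subject = subject, run = run)
}

#' Embed ROI series into a synthetic 4D NIfTI volume
#'
#' Builds a small 4D image on a 3 mm isotropic grid in which all voxels of
#' each ROI's cube carry that ROI's series, for exercising
#' [extract_roi_timeseries()] end to end. The ROI centres are snapped onto
#' voxel centres.
#'
#' @param bold time x ROI matrix.
#' @param specs ROI specs (`label`, `x`, `y`, `z`, `extent`).
#' @param path output `.nii` path.
#' @param TR repetition time stored in the header.
#' @param margin empty margin around the ROIs, mm.
#' @return invisibly, `path`.
#' @export
write_bold_nifti <- function(bold, specs, path, TR = 2, margin = 9) {
  vox <- 3
  lo <- vapply(c("x", "y", "z"), function(d) min(specs[[d]]) - margin,
               numeric(1))
  hi <- vapply(c("x", "y", "z"), function(d) max(specs[[d]]) + margin,
               numeric(1))
  dims <- ceiling((hi - lo) / vox) + 1
  arr <- array(0, dim = c(dims, nrow(bold)))
  aff <- diag(c(vox, vox, vox, 1))
  aff[1:3, 4] <- lo
  for (k in seq_len(nrow(specs))) {
    centre_vox <- round((c(specs$x[k], specs$y[k], specs$z[k]) - lo) / vox) + 1
    half <- floor(specs$extent[k] / 2 / vox)
    idx <- lapply(1:3, function(d)
      max(1, centre_vox[d] - half):min(dims[d], centre_vox[d] + half))
    for (i in idx[[1]]) for (j in idx[[2]]) for (kk in idx[[3]])
      arr[i, j, kk, ] <- bold[, k]
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vox, vox, vox, TR)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
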