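#' Voxel-wise pharmacokinetic parameter maps
#'
#' Container for co-registered Ktrans and ve maps with a tumor ROI mask.
#' Within the ROI both parameters must be non-negative where finite;
#' \eqn{v_e > 1} is allowed and is treated downstream as unphysiological
#' (necrosis; the Tofts model assumptions fail in such voxels).
#'
#' @param ktrans Numeric array, Ktrans in min^-1 (NA outside ROI allowed).
#' @param ve Numeric array, fractional distribution volume (same dim).
#' @param roi Logical (or 0/1) array, tumor membership (same dim).
#' @param voxel_size Voxel dimensions in mm (metadata).
#' @return An object of class \code{parameter_maps}.
#' @export
parameter_maps <- function(ktrans, ve, roi, voxel_size = c(1, 1, 1)) {
  ktrans <- as.array(ktrans); ve <- as.array(ve)
  roi <- array(as.logical(roi), dim = dim(as.array(roi)))
  if (!identical(dim(ktrans), dim(ve)) || !identical(dim(ktrans), dim(roi)))
    stop("ktrans, ve and roi must share one grid shape", call. = FALSE)
  kin <- ktrans[roi]; vin <- ve[roi]
  if (any(kin < 0, na.rm = TRUE) || any(vin < 0, na.rm = TRUE))
    stop("within the ROI, ktrans and ve must be >= 0", call. = FALSE)
  structure(list(ktrans = ktrans, ve = ve, roi = roi,
                 voxel_size = as.numeric(voxel_size)),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("Parameter maps %s, %d ROI voxels (%d with ve > 1)\n",
              paste(dim(x$ktrans), collapse = "x"), sum(x$roi),
              sum(x$ve[x$roi] > 1, na.rm = TRUE)))
  invisible(x)
}

# ROI voxels usable for hypoxia classification: finite parameters, ve <= 1.
.viable_values <- function(maps) {
  k <- maps$ktrans[maps$roi]
  v <- maps$ve[maps$roi]
  ok <- is.finite(k) & is.finite(v) & v <= 1
  list(ktrans = k[ok], ve = v[ok], n_roi = length(k), n_viable = sum(ok))
}

#' Write parameter maps as NIfTI-1 volumes
#'
#' Writes one file per parameter (\code{ktrans.nii.gz}, \code{ve.nii.gz})
#' plus a 0/1 ROI mask (\code{roi.nii.gz}) into a directory.
#'
#' @param maps A [parameter_maps()] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_parameter_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- maps$voxel_size
  pix <- c(ps, rep(1, max(0, 3 - length(ps))))[1:3]
  wr <- function(arr, name) {
    a <- arr
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
    img <- RNifti::asNifti(a, reference = list(pixdim = c(-1, pix, rep(1, 4))))
    path <- file.path(dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(img, path)
    path
  }
  paths <- c(wr(maps$ktrans, "ktrans"), wr(maps$ve, "ve"),
             wr(maps$roi * 1, "roi"))
  invisible(paths)
}

#' Read parameter maps from NIfTI-1 volumes
#'
#' Counterpart of [write_parameter_maps()].
#'
#' @param dir Directory containing \code{ktrans.nii.gz}, \code{ve.nii.gz}
#'   and \code{roi.nii.gz}.
#' @return A [parameter_maps()] object.
#' @export
read_parameter_maps <- function(dir) {
  rd <- function(name) {
    path <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(path))
      stop("missing map file: ", path, call. = FALSE)
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 3L && dim(arr)[3L] == 1L)
      dim(arr) <- dim(arr)[1:2]
    arr
  }
  k <- rd("ktrans")
  hdr <- RNifti::niftiHeader(file.path(dir, "ktrans.nii.gz"))
  vs <- hdr$pixdim[2:4]
  parameter_maps(k, rd("ve"), rd("roi") > 0.5, voxel_size = vs)
}

#' Write parameter maps as delimited text
#'
#' Toy-scale alternative to NIfTI: one row per ROI voxel with columns
#' \code{x, y, z, ktrans, ve}.
#'
#' @param maps A [parameter_maps()] object.
#' @param path Output file (tab-separated).
#' @return Invisibly, \code{path}.
#' @export
write_maps_table <- function(maps, path) {
  stopifnot(inherits(maps, "parameter_maps"))
  d <- dim(maps$ktrans)
  if (length(d) == 2L) d <- c(d, 1L)
  idx <- which(array(maps$roi, dim = d), arr.ind = TRUE)
  df <- data.frame(x = idx[, 1L], y = idx[, 2L], z = idx[, 3L],
                   ktrans = maps$ktrans[maps$roi], ve = maps$ve[maps$roi])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read parameter maps from delimited text
#'
#' Counterpart of [write_maps_table()]; the grid shape is the bounding
#' box of the listed voxels unless given.
#'
#' @param path Tab-separated file with columns \code{x, y, z, ktrans, ve}.
#' @param dim Optional grid dimensions.
#' @param voxel_size Voxel dimensions in mm.
#' @return A [parameter_maps()] object.
#' @export
read_maps_table <- function(path, dim = NULL, voxel_size = c(1, 1, 1)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("x", "y", "z", "ktrans", "ve")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(dim)) dim <- c(max(df$x), max(df$y), max(df$z))
  k <- array(NA_real_, dim = dim); v <- array(NA_real_, dim = dim)
  roi <- array(FALSE, dim = dim)
  lin <- df$x + (df$y - 1L) * dim[1L] + (df$z - 1L) * dim[1L] * dim[2L]
  k[lin] <- df$ktrans; v[lin] <- df$ve; roi[lin] <- TRUE
  if (dim[3L] == 1L) { dim(k) <- dim(v) <- dim(roi) <- dim[1:2] }
  parameter_maps(k, v, roi, voxel_size = voxel_size)
}

#' Write concentration curves as delimited text
#'
#' First column is time (s); one column per voxel, named by linear voxel
#' index.
#'
#' @param acq A [dce_acquisition()].
#' @param path Output file (tab-separated).
#' @return Invisibly, \code{path}.
#' @export
write_curves <- function(acq, path) {
  stopifnot(inherits(acq, "dce_acquisition"))
  df <- data.frame(time = acq$times, acq$concentrations)
  names(df) <- c("time", paste0("v", acq$voxel_index))
  attr <- sprintf("# dim: %s", paste(acq$dim, collapse = " "))
  con <- file(path, "w")
  writeLines(attr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Read concentration curves from delimited text
#'
#' Counterpart of [write_curves()].
#'
#' @param path File written by [write_curves()].
#' @return A [dce_acquisition()].
#' @export
read_curves <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# dim:", first))
    stop("curve file lacks its '# dim:' header line", call. = FALSE)
  dims <- as.integer(strsplit(sub("^# dim:\\s*", "", first), "\\s+")[[1L]])
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  idx <- as.integer(sub("^v", "", names(df)[-1L]))
  dce_acquisition(df[[1L]], as.matrix(df[, -1L, drop = FALSE]), idx, dims)
}
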