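#' Read a 4-D NIfTI BOLD series into a `bold_ts`
#'
#' Voxels are vectorized in array order; an optional 3-D mask (or the label
#' volume from [read_labels_nifti()]) restricts the units kept.
#'
#' @param path Path to a 4-D NIfTI file.
#' @param tr Repetition time in seconds; if `NULL`, taken from the NIfTI
#'   header `pixdim[4]`.
#' @param mask Optional 3-D logical/numeric array; voxels where it is 0/`FALSE`
#'   are dropped.
#' @return A [bold_ts()] with one column per retained voxel; voxel linear
#'   indices are kept in attribute `voxel_index`, volume dimensions in `dim3`.
#' @export
read_bold_nifti <- function(path, tr = NULL, mask = NULL) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4L) stop("expected a 4-D NIfTI volume")
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  d3 <- dim(a)[1:3]
  nt <- dim(a)[4]
  m <- matrix(a, prod(d3), nt)
  keep <- seq_len(prod(d3))
  if (!is.null(mask)) {
    mk <- as.logical(as.array(mask) != 0)
    if (length(mk) != prod(d3)) stop("mask dimensions do not match the volume")
    keep <- which(mk)
  }
  out <- bold_ts(t(m[keep, , drop = FALSE]), tr = tr,
                 unit_ids = paste0("v", keep))
  attr(out, "voxel_index") <- keep
  attr(out, "dim3") <- d3
  out
}

#' Read an integer parcel-label NIfTI volume as a `parcel_scheme`
#'
#' @param path Path to a 3-D integer NIfTI label volume (0 = background).
#' @param parcel_names Optional named character vector mapping label values to
#'   parcel names.
#' @param hemisphere_pairs See [parcel_scheme()].
#' @return A [parcel_scheme()] over the vectorized voxels.
#' @export
read_labels_nifti <- function(path, parcel_names = NULL, hemisphere_pairs = NULL) {
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) != 3L) stop("expected a 3-D label volume")
  parcel_scheme(as.integer(a), parcel_names = parcel_names,
                hemisphere_pairs = hemisphere_pairs)
}

#' Write a voxel-level INT map back to NIfTI
#'
#' @param map An `int_map` produced from a series read with
#'   [read_bold_nifti()] (needs the `voxel_index`/`dim3` attributes, passed
#'   here explicitly).
#' @param path Output path.
#' @param dim3 Volume dimensions.
#' @param voxel_index Linear indices of the map's units within the volume.
#' @param reference Optional NIfTI image or path whose header to reuse.
#' @return `path`, invisibly.
#' @export
write_int_nifti <- function(map, path, dim3, voxel_index, reference = NULL) {
  vol <- array(0, dim = dim3)
  vals <- map$values
  vals[!is.finite(vals)] <- 0
  vol[voxel_index] <- vals
  img <- if (is.null(reference)) RNifti::asNifti(vol) else
    RNifti::asNifti(vol, reference = reference)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a TSV confound table
#'
#' Plain wrapper around [utils::read.delim()]; the framewise-displacement
#' column is expected under the name `framewise_displacement`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_confounds_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE)
}

#' Write a long-format parcel INT table
#'
#' @param int_matrix Subjects x parcels numeric matrix (dimnames used for ids).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_int_table <- function(int_matrix, path) {
  m <- as.matrix(int_matrix)
  if (is.null(rownames(m))) rownames(m) <- paste0("sub", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("parcel", seq_len(ncol(m)))
  df <- data.frame(
    subject_id = rep(rownames(m), times = ncol(m)),
    parcel = rep(colnames(m), each = nrow(m)),
    int_seconds = as.vector(m)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format parcel INT table into a subjects x parcels matrix
#'
#' @param path CSV with columns `subject_id`, `parcel`, `int_seconds`.
#' @return Numeric matrix with subject/parcel dimnames.
#' @export
read_int_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::xtabs(int_seconds ~ subject_id + parcel, data = df) |>
    unclass() |> as.matrix()
}
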