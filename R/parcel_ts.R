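#' Parcel-wise voxel time series
#'
#' Container for the BOLD signals of one scanning run: a `time x voxel` matrix
#' together with the repetition time and a voxel-to-parcel map. Columns are
#' named `"<parcel_id>:<voxel_index>"`.
#'
#' @param data Numeric matrix, one row per acquired volume.
#' @param tr_s Repetition time in seconds.
#' @param voxel_map Data frame with one row per column of `data` and columns
#'   `parcel_id` and `voxel`. If `NULL` it is reconstructed from the column
#'   names of `data`.
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, tr_s, voxel_map = NULL) {
  data <- as.matrix(data)
  assert_scalar_number(tr_s, "tr_s", lower = 1e-6)
  if (any(!is.finite(data))) {
    abort_validation("parcel time series must not contain missing values")
  }
  if (is.null(voxel_map)) {
    if (is.null(colnames(data))) {
      abort_argument("`voxel_map` is required when `data` has no column names")
    }
    parts <- strsplit(colnames(data), ":", fixed = TRUE)
    voxel_map <- tibble::tibble(
      parcel_id = as.integer(vapply(parts, `[[`, "", 1L)),
      voxel = as.integer(vapply(parts, `[[`, "", 2L))
    )
  }
  voxel_map <- tibble::as_tibble(voxel_map)
  if (nrow(voxel_map) != ncol(data)) {
    abort_validation("`voxel_map` must have one row per data column")
  }
  colnames(data) <- paste0(voxel_map$parcel_id, ":", voxel_map$voxel)
  structure(
    list(data = data, tr_s = tr_s, n_volumes = nrow(data),
         voxel_map = voxel_map,
         parcel_ids = sort(unique(voxel_map$parcel_id))),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %d volumes x %d voxels (%d parcels), TR = %g s\n",
              x$n_volumes, ncol(x$data), length(x$parcel_ids), x$tr_s))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.parcel_ts <- function(x, ...) {
  tibble::tibble(
    volume = rep(seq_len(x$n_volumes), times = ncol(x$data)),
    time_s = (rep(seq_len(x$n_volumes), times = ncol(x$data)) - 1) * x$tr_s,
    parcel_id = rep(x$voxel_map$parcel_id, each = x$n_volumes),
    voxel = rep(x$voxel_map$voxel, each = x$n_volumes),
    signal = as.vector(x$data)
  )
}

#' Read a parcel-by-time matrix from TSV plus JSON sidecar
#'
#' The TSV holds one row per volume and one column per voxel, named
#' `"<parcel_id>:<voxel_index>"`; the JSON sidecar records `tr_s` and
#' `n_volumes`.
#'
#' @param path Path to the TSV file.
#' @param sidecar Path to the JSON sidecar (default `paste0(path, ".json")`).
#' @return A [parcel_ts()].
#' @export
read_parcel_matrix <- function(path, sidecar = paste0(path, ".json")) {
  x <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_format(paste0("cannot parse parcel matrix: ",
                                            conditionMessage(e)))
  )
  if (nrow(x) == 0L || ncol(x) == 0L) {
    abort_format("parcel matrix file is empty")
  }
  if (!all(vapply(x, is.numeric, logical(1)))) {
    abort_format("parcel matrix contains non-numeric entries")
  }
  if (!file.exists(sidecar)) {
    abort_format(paste0("sidecar file not found: ", sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$tr_s)) abort_format("sidecar must declare `tr_s`")
  if (!is.null(meta$n_volumes) && meta$n_volumes != nrow(x)) {
    abort_validation(sprintf(
      "sidecar declares %d volumes but file has %d rows",
      meta$n_volumes, nrow(x)))
  }
  parcel_ts(as.matrix(x), tr_s = meta$tr_s)
}

#' Write a parcel-by-time matrix as TSV plus JSON sidecar
#'
#' @param ts A [parcel_ts()].
#' @param path Output TSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_parcel_matrix <- function(ts, path) {
  stopifnot(inherits(ts, "parcel_ts"))
  df <- tibble::as_tibble(ts$data, .name_repair = "minimal")
  readr::write_tsv(df, path, progress = FALSE)
  jsonlite::write_json(list(tr_s = ts$tr_s, n_volumes = ts$n_volumes),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 4D NIfTI image grouped by an integer atlas volume
#'
#' Optional adapter for volumetric data: voxel time courses of the 4D image
#' are grouped by the nonzero labels of a 3D parcellation image on the same
#' grid.
#'
#' @param image_path Path to a 4D NIfTI image.
#' @param label_path Path to a 3D integer label NIfTI on the same grid.
#' @param lookup Optional atlas lookup table (see [default_atlas()]); labels
#'   absent from the lookup are kept with a numeric name and a warning.
#' @param tr_s Repetition time override; defaults to the image `pixdim` time
#'   step.
#' @return A [parcel_ts()] with the atlas lookup attached as attribute
#'   `"atlas"`.
#' @export
read_nifti_with_atlas <- function(image_path, label_path, lookup = NULL,
                                  tr_s = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort_argument("reading NIfTI images requires the RNifti package")
  }
  img <- RNifti::readNifti(image_path)
  lab <- RNifti::readNifti(label_path)
  dimg <- dim(img); dlab <- dim(lab)
  if (length(dimg) != 4L) abort_validation("image must be 4-dimensional")
  if (!identical(as.integer(dimg[1:3]), as.integer(dlab[1:3]))) {
    abort_validation("image and label grids do not match")
  }
  if (is.null(tr_s)) {
    pd <- attr(img, "pixdim")
    tr_s <- if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  lab <- as.integer(round(lab))
  keep <- which(lab > 0L)
  n_vol <- dimg[4]
  mat <- matrix(img, nrow = prod(dimg[1:3]), ncol = n_vol)[keep, , drop = FALSE]
  ids <- lab[keep]
  ord <- order(ids)
  mat <- mat[ord, , drop = FALSE]
  ids <- ids[ord]
  voxel <- stats::ave(ids, ids, FUN = seq_along)
  if (!is.null(lookup)) {
    unknown <- setdiff(unique(ids), lookup$parcel_id)
    if (length(unknown)) {
      warning(sprintf("label id(s) %s absent from lookup; kept with numeric names",
                      paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  out <- parcel_ts(t(mat), tr_s = tr_s,
                   voxel_map = tibble::tibble(parcel_id = ids, voxel = voxel))
  attr(out, "atlas") <- lookup
  out
}

#' Parcellation lookup table
#'
#' A synthetic 246-parcel lookup emulating a whole-brain atlas with left and
#' right amygdala seed parcels; it carries the fields consumed by the PPI and
#' reporting stages (`parcel_id`, `name`, `hemisphere`, `is_seed`).
#'
#' @param n_parcels Number of parcels (default 246).
#' @param seed_parcels Integer ids of the connectivity seed parcels, named
#'   with their hemisphere (default left/right amygdala at ids 211 and 212;
#'   for small toy atlases the last two parcels are used).
#' @return A tibble with one row per parcel.
#' @export
default_atlas <- function(n_parcels = 246, seed_parcels = NULL) {
  if (is.null(seed_parcels)) {
    seed_parcels <- if (n_parcels >= 212L) c(L = 211L, R = 212L)
                    else c(L = n_parcels - 1L, R = n_parcels)
  }
  if (any(seed_parcels > n_parcels)) {
    abort_argument("seed parcel ids must not exceed `n_parcels`")
  }
  hemi <- rep(c("L", "R"), length.out = n_parcels)
  name <- sprintf("parcel_%03d_%s", seq_len(n_parcels), hemi)
  is_seed <- seq_len(n_parcels) %in% seed_parcels
  name[seed_parcels] <- paste0("amygdala_", names(seed_parcels))
  hemi[seed_parcels] <- names(seed_parcels)
  tibble::tibble(parcel_id = seq_len(n_parcels), name = name,
                 hemisphere = hemi, is_seed = is_seed)
}
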