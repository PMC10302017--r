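# File-format plumbing: NIfTI images, plain-text b-vector/b-value tables and
# landmark lists, and RDS array archives with JSON sidecar manifests for
# masks, k-space sets and displacement fields.

#' Read/write images as NIfTI
#'
#' @param img Numeric matrix or array.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `write_image_nifti` returns the path invisibly;
#'   `read_image_nifti` returns the array.
#' @export
write_image_nifti <- function(img, path) {
  RNifti::writeNifti(RNifti::asNifti(img), path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path) {
  x <- RNifti::readNifti(path)
  a <- as.array(x)
  # drop trailing singleton dims added by the format
  d <- dim(a)
  while (length(d) > 2 && d[length(d)] == 1) {
    d <- d[-length(d)]
    dim(a) <- d
  }
  a
}

#' Plain-text b-vector / b-value tables
#'
#' b-vectors are written as a 3 x N whitespace table (one gradient axis per
#' row), b-values as a single line of N values - the sidecar convention used
#' alongside DWI NIfTI stacks.
#'
#' @param bvecs 3 x N matrix of unit vectors.
#' @param bvals Numeric vector of b-values (s/mm^2).
#' @param path Output path.
#' @return Path (writers, invisibly) or the parsed object (readers).
#' @export
write_bvecs <- function(bvecs, path) {
  utils::write.table(format(bvecs, digits = 10), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bvecs
#' @export
read_bvecs <- function(path) {
  as.matrix(utils::read.table(path))
}

#' @rdname write_bvecs
#' @export
write_bvals <- function(bvals, path) {
  writeLines(paste(format(bvals, digits = 10), collapse = " "), path)
  invisible(path)
}

#' @rdname write_bvecs
#' @export
read_bvals <- function(path) {
  scan(path, quiet = TRUE)
}

#' Landmark tables
#'
#' Whitespace-delimited text, one `x y [z]` triple per line, 0-based voxel
#' coordinates on disk; converted to the package's 1-based convention on
#' read.
#'
#' @param landmarks N x 2 (or N x 3) matrix of 1-based coordinates.
#' @param path File path.
#' @return Path (writer, invisibly) or N x k matrix of 1-based coordinates.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.table(as.matrix(landmarks) - 1, path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  as.matrix(utils::read.table(path)) + 1
}

#' Array archive with JSON sidecar
#'
#' Stores an R object (mask, k-space set, displacement field) as an RDS
#' archive next to a human-readable JSON manifest describing it.
#'
#' @param obj Object to store.
#' @param path Path of the `.rds` archive (sidecar gets `.json`).
#' @param meta Named list of manifest fields.
#' @return Path (writer, invisibly) or the restored object (reader).
#' @export
write_array_archive <- function(obj, path, meta = list()) {
  saveRDS(obj, path)
  meta$class <- class(obj)[1]
  if (inherits(obj, "sampling_mask")) {
    meta$grid <- dim(obj$mask)
    meta$fraction_sampled <- obj$fraction_sampled
    meta$hermitian_half <- obj$hermitian_half
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_array_archive
#' @export
read_array_archive <- function(path) readRDS(path)

# tiny FNV-1a hash of a serialized object for run manifests
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  p <- 16777619
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h %/% 2^31) * 2^31
    # 32-bit modular multiply in two 16-bit halves (doubles stay exact)
    h <- (((h %/% 65536) * p %% 65536) * 65536 + (h %% 65536) * p) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}
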