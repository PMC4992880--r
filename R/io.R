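#' Write a voxel-vector stack as a NIfTI-1 volume
#'
#' Voxel vectors live on a small 3-D lattice (default 10 x 10 x 20 = 2000
#' voxels); a single vector becomes a 3-D volume and an observation x voxel
#' matrix becomes a 4-D volume with one frame per row.
#'
#' @param x numeric vector or observation x voxel matrix.
#' @param path output file (\code{.nii} or \code{.nii.gz}).
#' @param grid_dim integer length-3 lattice dimensions; their product must
#'   equal the voxel count.
#' @param pixdim voxel size in mm.
#' @return \code{path}, invisibly.
#' @export
write_voxels_nifti <- function(x, path, grid_dim = c(10L, 10L, 20L),
                               pixdim = c(2, 2, 2)) {
  n_vox <- if (is.matrix(x)) ncol(x) else length(x)
  if (prod(grid_dim) != n_vox) {
    stop("write_voxels_nifti: grid ", paste(grid_dim, collapse = "x"),
         " does not hold ", n_vox, " voxels")
  }
  arr <- if (is.matrix(x)) {
    array(t(x), dim = c(grid_dim, nrow(x)))
  } else {
    array(x, dim = grid_dim)
  }
  img <- RNifti::asNifti(arr, pixdim = pixdim)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume back into voxel vectors
#'
#' Inverse of [write_voxels_nifti()]: 3-D volumes give a vector, 4-D volumes
#' give a frame x voxel matrix.
#'
#' @param path NIfTI file.
#' @return numeric vector or matrix, with attribute \code{grid_dim}.
#' @export
read_voxels_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop("read_voxels_nifti: cannot read '", path, "': ",
                         conditionMessage(e))
                  })
  arr <- as.array(img)
  d <- dim(arr)
  out <- if (length(d) == 4L) {
    t(matrix(arr, nrow = prod(d[1:3]), ncol = d[4]))
  } else {
    as.numeric(arr)
  }
  attr(out, "grid_dim") <- d[1:3]
  out
}

#' Persist a trained weight map as NIfTI plus a JSON sidecar
#'
#' @param map a \code{heat_weight_map}.
#' @param prefix output path prefix; writes \code{<prefix>.nii.gz} and
#'   \code{<prefix>.json}.
#' @param grid_dim lattice dimensions for the voxel vector.
#' @return named character vector of the two paths, invisibly.
#' @export
write_weight_map <- function(map, prefix, grid_dim = c(10L, 10L, 20L)) {
  stopifnot(inherits(map, "heat_weight_map"))
  nii <- paste0(prefix, ".nii.gz")
  js <- paste0(prefix, ".json")
  write_voxels_nifti(map$w_vox, nii, grid_dim)
  meta <- list(alpha = map$alpha, lambda = map$lambda,
               cv_error = map$cv_error, cv_metric = map$cv_metric,
               intercept = map$intercept,
               n_components = map$n_components,
               n_nonzero_components = map$n_nonzero_components,
               n_voxels = length(map$w_vox))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(nifti = nii, json = js))
}

#' Write / read tab-separated tables
#'
#' Plain TSV with a header row, the interchange format for trial, rating, MHE
#' and result tables.
#'
#' @param x data.frame.
#' @param path file path.
#' @return \code{path} (write) or a data.frame (read).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
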