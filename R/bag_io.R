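# HDF5 persistence of feature bags.
#
# Schema (one bag per file):
#   /features        float64 N x C   per-tile feature matrix
#   /coords          int     N x 2   0-based tile top-left (x, y) pixels
#   /instance_truth  int     N       optional witness mask (simulator only)
#   attributes on "/": slide_id, label, stain, tile_size, extractor_name
#
# Features are stored at full double precision so that read(write(bag))
# reproduces the in-memory bag bit-exactly.

REQUIRED_DATASETS <- c("features", "coords")

#' Write a feature bag to an HDF5 file
#'
#' @param bag A [feature_bag()].
#' @param path Output file path; overwritten if it exists.
#' @return `path`, invisibly.
#' @seealso [read_bag()]
#' @export
write_bag <- function(bag, path) {
  stopifnot(inherits(bag, "feature_bag"))
  if (file.exists(path)) unlink(path)
  fid <- rhdf5::H5Fcreate(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeDataset(bag$features, fid, "features")
  rhdf5::h5writeDataset(bag$coords, fid, "coords")
  if (!is.null(bag$instance_truth)) {
    rhdf5::h5writeDataset(as.integer(bag$instance_truth), fid, "instance_truth")
  }
  rhdf5::h5writeAttribute(bag$slide_id, fid, "slide_id")
  rhdf5::h5writeAttribute(bag$bag_label, fid, "label")
  rhdf5::h5writeAttribute(bag$stain, fid, "stain")
  rhdf5::h5writeAttribute(bag$tile_size, fid, "tile_size")
  rhdf5::h5writeAttribute(bag$extractor_name, fid, "extractor_name")
  invisible(path)
}

#' Read a feature bag from an HDF5 file
#'
#' @param path File written by [write_bag()] (or any file following the
#'   documented schema).
#' @return A [feature_bag()].
#' @export
read_bag <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  present <- contents$name[contents$group == "/"]
  missing <- setdiff(REQUIRED_DATASETS, present)
  if (length(missing) > 0L) {
    stop(sprintf("bag file schema error: missing dataset(s) %s",
                 paste(sQuote(missing), collapse = ", ")))
  }
  features <- rhdf5::h5read(path, "features")
  coords <- rhdf5::h5read(path, "coords")
  truth <- if ("instance_truth" %in% present) {
    as.integer(rhdf5::h5read(path, "instance_truth"))
  }
  attrs <- rhdf5::h5readAttributes(path, "/")
  attr_or <- function(name, default) {
    if (!is.null(attrs[[name]])) as.vector(attrs[[name]]) else default
  }
  slide_id <- attr_or("slide_id", "slide")
  label <- attr_or("label", 0L)
  stain <- attr_or("stain", "synthetic")
  tile_size <- attr_or("tile_size", 256L)
  extractor_name <- attr_or("extractor_name", "unknown")
  feature_bag(
    features = features,
    coords = coords,
    bag_label = label,
    instance_truth = truth,
    slide_id = slide_id,
    stain = stain,
    tile_size = tile_size,
    extractor_name = extractor_name
  )
}
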