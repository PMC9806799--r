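# Stable on-disk formats: multi-page 16-bit TIFF per round with a JSON
# sidecar, CSV cell tables, JSON reports.

#' Write an image set to disk
#'
#' One multi-page TIFF per round (page order = channel order, unsigned
#' 16-bit) plus a JSON sidecar naming rounds, channels, true shifts (when
#' synthetic), pixel size and seed. The round trip through
#' \code{\link{read_image_set}} is lossless.
#'
#' @param image_set an \code{image_set}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default the field id).
#' @return the sidecar path, invisibly.
#' @export
write_image_set <- function(image_set, dir, prefix = image_set$field_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rounds_meta <- vector("list", length(image_set$rounds))
  for (r in seq_along(image_set$rounds)) {
    fn <- paste0(prefix, "_round", r, ".tif")
    pages <- lapply(image_set$rounds[[r]]$channels,
                    function(m) unclass(m) / 65535)
    tiff::writeTIFF(pages, file.path(dir, fn), bits.per.sample = 16,
                    compression = "none")
    rounds_meta[[r]] <- list(
      file = fn,
      channels = names(image_set$rounds[[r]]$channels),
      true_shift = image_set$rounds[[r]]$true_shift)
  }
  sidecar <- file.path(dir, paste0(prefix, "_imageset.json"))
  jsonlite::write_json(
    list(rounds = rounds_meta, pixel_um = image_set$pixel_um,
         nuclear_channel = image_set$nuclear_channel,
         field_id = image_set$field_id, seed = image_set$seed),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

#' Read an image set from a JSON sidecar
#'
#' @param sidecar path to the \code{*_imageset.json} written by
#'   \code{\link{write_image_set}}.
#' @return an \code{image_set}; errors name any missing sidecar field and
#'   flag TIFFs whose page count disagrees with the channel list.
#' @export
read_image_set <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  for (f in c("rounds", "pixel_um", "nuclear_channel", "field_id"))
    if (is.null(meta[[f]]))
      stop("malformed sidecar: missing field '", f, "'")
  dir <- dirname(sidecar)
  rounds <- lapply(seq_along(meta$rounds), function(r) {
    rm <- meta$rounds[[r]]
    for (f in c("file", "channels"))
      if (is.null(rm[[f]]))
        stop("malformed sidecar: round ", r, " missing field '", f, "'")
    pages <- tiff::readTIFF(file.path(dir, rm$file), all = TRUE)
    if (length(pages) != length(rm$channels))
      stop("round ", r, ": TIFF has ", length(pages),
           " page(s) but sidecar lists ", length(rm$channels),
           " channel(s)")
    chans <- lapply(pages, function(p) round(p * 65535))
    names(chans) <- rm$channels
    list(channels = chans,
         true_shift = if (!is.null(rm$true_shift))
           as.numeric(rm$true_shift) else NULL)
  })
  structure(list(rounds = rounds, pixel_um = meta$pixel_um,
                 nuclear_channel = meta$nuclear_channel,
                 field_id = meta$field_id, seed = meta$seed),
            class = "image_set")
}

#' Write a label image as 16-bit TIFF with an object-summary CSV
#'
#' @param labels a \code{label_image}.
#' @param path TIFF path; the objects table (label, centroid, areas,
#'   border flag) is written next to it with suffix \code{_objects.csv}.
#' @return the TIFF path, invisibly.
#' @export
write_label_image <- function(labels, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  m <- unclass(labels)
  attributes(m) <- list(dim = dim(m))
  if (max(m) > 65535) stop("more than 65535 labels cannot be stored")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16,
                  compression = "none")
  utils::write.csv(label_objects(labels),
                   sub("\\.tiff?$", "_objects.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Write / read a per-cell feature table as CSV
#'
#' Missing values are preserved; logical flag columns survive the round
#' trip.
#'
#' @param cells CellTable data.frame.
#' @param path CSV path.
#' @return \code{write_cell_table}: the path, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cells, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
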