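# Nuclear segmentation from the nuclear channel, constrained thickening
# into cell regions, and cytosol derivation.

.label_objects <- function(lab, provenance) {
  labs <- sort(unique(lab[lab > 0L]))
  if (length(labs) && !identical(labs, seq_along(labs))) {
    map <- integer(max(labs)); map[labs] <- seq_along(labs)
    lab[lab > 0L] <- map[lab[lab > 0L]]
    labs <- seq_along(labs)
  }
  n <- length(labs)
  if (n) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    rs <- ((idx - 1L) %% nrow(lab)) + 1L
    cs <- ((idx - 1L) %/% nrow(lab)) + 1L
    area <- tabulate(l, nbins = n)
    cen_r <- rowsum(as.numeric(rs), l)[, 1] / area
    cen_c <- rowsum(as.numeric(cs), l)[, 1] / area
    border <- as.logical(tabulate(
      l[rs == 1L | rs == nrow(lab) | cs == 1L | cs == ncol(lab)],
      nbins = n))
    obj <- data.frame(label = labs, row = cen_r, col = cen_c,
                      area_px = area, border = border)
  } else {
    obj <- data.frame(label = integer(), row = numeric(), col = numeric(),
                      area_px = integer(), border = logical())
  }
  structure(lab, class = c("label_image", "matrix"),
            provenance = provenance, objects = obj)
}

#' @export
print.label_image <- function(x, ...) {
  cat("<label_image> ", attr(x, "provenance"), ", ",
      nrow(attr(x, "objects")), " object(s), ",
      nrow(x), "x", ncol(x), " px\n", sep = "")
  invisible(x)
}

#' Objects summary of a label image
#'
#' @param labels a \code{label_image}.
#' @return data.frame with label, centroid (row, col), area_px, border flag.
#' @export
label_objects <- function(labels) attr(labels, "objects")

#' Segment nuclei from a nuclear-channel image
#'
#' Binarizes (Otsu's rule on the image histogram, or a fixed intensity
#' threshold), fills holes, removes objects below a minimum area,
#' optionally splits touching nuclei by watershed on the distance
#' transform, and labels connected components. Objects touching the image
#' border are flagged in the objects table.
#'
#' @param nuclear_image 2D matrix (max-projected upstream if a z-stack).
#' @param params list: \code{threshold} ("otsu" or a fixed intensity in the
#'   image's units), \code{min_area_px}, \code{fill_holes},
#'   \code{split_touching}.
#' @return a \code{label_image} (provenance "nucleus"); empty (with a
#'   warning) if thresholding leaves no foreground.
#' @export
segment_nuclei <- function(nuclear_image,
                           params = list()) {
  p <- utils::modifyList(
    list(threshold = "otsu", min_area_px = 30, fill_holes = TRUE,
         split_touching = FALSE), params)
  if (length(dim(nuclear_image)) != 2)
    stop("segment_nuclei expects a 2D image; max-project z-stacks first")
  img <- nuclear_image
  if (identical(p$threshold, "otsu")) {
    mx <- max(img)
    if (mx <= min(img)) {
      warning("all-background image: no objects segmented")
      return(.label_objects(matrix(0L, nrow(img), ncol(img)), "nucleus"))
    }
    thr01 <- EBImage::otsu(EBImage::Image(img / mx), range = c(0, 1))
    mask <- img / mx > thr01
  } else {
    mask <- img > p$threshold
  }
  if (!any(mask)) {
    warning("all-background after thresholding: no objects segmented")
    return(.label_objects(matrix(0L, nrow(img), ncol(img)), "nucleus"))
  }
  m <- EBImage::Image(mask * 1)
  if (isTRUE(p$fill_holes)) m <- EBImage::fillHull(m)
  if (isTRUE(p$split_touching)) {
    dm <- EBImage::distmap(m)
    lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  } else {
    lab <- EBImage::bwlabel(m)
  }
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(img))
  if (p$min_area_px > 0) {
    area <- tabulate(lab[lab > 0L])
    drop <- which(area < p$min_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  .label_objects(lab, "nucleus")
}

#' Thicken nuclei into cell regions
#'
#' Every pixel within \code{radius_px} (Euclidean) of a nucleus is assigned
#' to the nearest nucleus label (ties broken toward the lower label), so
#' neighboring cells are separated along the equidistant boundary. Nucleus
#' pixels keep their labels; cell k always contains nucleus k.
#'
#' @param nuclei a nucleus \code{label_image}.
#' @param radius_px thickening radius in pixels (>= 0).
#' @return a cell \code{label_image}.
#' @export
expand_cells <- function(nuclei, radius_px) {
  if (radius_px < 0) stop("radius_px must be >= 0")
  lab <- .expand_labels_nearest(unclass(nuclei), radius_px)
  out <- .label_objects(lab, "cell")
  # keep the nucleus objects' border flags ORed with the cell's own
  out
}

#' Derive cytosol regions
#'
#' Cytosol k = cell k minus nucleus k. Cells whose cytosol is empty
#' (thickening radius 0) are retained with empty regions and flagged in
#' the objects table (\code{empty}).
#'
#' @param cells cell \code{label_image} from \code{\link{expand_cells}}.
#' @param nuclei the matching nucleus \code{label_image}.
#' @return a cytosol \code{label_image}.
#' @export
derive_cytosol <- function(cells, nuclei) {
  lc <- sort(unique(cells[cells > 0L]))
  ln <- sort(unique(nuclei[nuclei > 0L]))
  if (!identical(lc, ln))
    stop("label mismatch between cells and nuclei: ",
         paste(union(setdiff(lc, ln), setdiff(ln, lc)), collapse = ", "))
  lab <- unclass(cells)
  lab[unclass(nuclei) > 0L] <- 0L
  present <- tabulate(lab[lab > 0L], nbins = length(lc))
  out <- structure(lab, class = c("label_image", "matrix"),
                   provenance = "cytosol")
  obj <- attr(cells, "objects")
  obj$area_px <- as.integer(present)
  obj$empty <- present == 0L
  attr(out, "objects") <- obj
  out
}

#' Compare a nucleus segmentation with the generator's ground truth
#'
#' Rasterizes the true nucleus ellipses, matches each true cell to the
#' predicted label with maximal overlap, and scores object recall and
#' precision (IoU >= \code{iou_match} counts as a match) plus the median
#' IoU of matched pairs.
#'
#' @param nuclei a nucleus \code{label_image}.
#' @param gt ground-truth table (from the truth attribute of a rendered
#'   field).
#' @param config the \code{sim_config} used for rendering.
#' @param iou_match IoU threshold for counting a match.
#' @return list(recall, precision, median_iou, n_true, n_pred, iou).
#' @export
evaluate_segmentation <- function(nuclei, gt, config, iou_match = 0.5) {
  true_lab <- .rasterize_nuclei(gt, config)
  pred <- unclass(nuclei)
  n_true <- nrow(gt)
  n_pred <- length(unique(pred[pred > 0L]))
  iou <- rep(NA_real_, n_true)
  matched_pred <- integer(0)
  for (i in seq_len(n_true)) {
    idx <- which(true_lab == i)
    if (!length(idx)) next
    cand <- pred[idx]
    cand <- cand[cand > 0L]
    if (!length(cand)) { iou[i] <- 0; next }
    tab <- table(cand)
    k <- as.integer(names(tab)[which.max(tab)])
    inter <- sum(pred[idx] == k)
    uni <- length(idx) + sum(pred == k) - inter
    iou[i] <- inter / uni
    if (iou[i] >= iou_match) matched_pred <- c(matched_pred, k)
  }
  n_match <- sum(iou >= iou_match, na.rm = TRUE)
  list(recall = n_match / n_true,
       precision = if (n_pred) length(unique(matched_pred)) / n_pred else 0,
       median_iou = stats::median(iou[iou >= iou_match], na.rm = TRUE),
       n_true = n_true, n_pred = n_pred, iou = iou)
}
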