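# Reduction of aligned images + label images to a per-cell feature table.

#' Maximum intensity projection
#'
#' Per-pixel maximum over the z axis (z first). 2D input is returned
#' unchanged, so the projection is idempotent.
#'
#' @param zstack a 3D array (z, y, x) or a 2D matrix.
#' @return a 2D matrix.
#' @export
max_project <- function(zstack) {
  d <- dim(zstack)
  if (is.null(d) || length(d) < 2 || any(d == 0))
    stop("empty or malformed stack")
  if (length(d) == 2) return(zstack)
  if (length(d) != 3) stop("max_project expects a 2D image or 3D z-stack")
  out <- zstack[1, , ]
  for (z in seq_len(d[1])[-1]) out <- pmax(out, zstack[z, , ])
  out
}

# Stable measurement column name for round r, channel ch.
.meas_col <- function(round, channel, stat) {
  paste0("r", round, "_", channel, "_", stat)
}

#' Measure per-cell intensities over all rounds and channels
#'
#' One row per cell label; for every round and channel the mean and sum
#' intensity over the cell region (columns \code{r{round}_{channel}_mean}
#' and \code{_sum}). Flags: \code{border} (cell touches the image border),
#' \code{invalid} (cell overlaps registration-invalid pixels), and
#' \code{died} (nucleus area below \code{died_area_px}, the shrunken-
#' nucleus signature of a non-resealed cell).
#'
#' Pixels on the contested boundary between touching cells carry signal
#' spillover from the neighbor; intensities are therefore measured over
#' the cell region minus a \code{guard_px}-wide band around any boundary
#' with a different cell (the measured area is reported as
#' \code{area_measured_px}). Set \code{guard_px = 0} to measure the full
#' region.
#'
#' @param cells cell \code{label_image}.
#' @param aligned an aligned \code{image_set} (its optional \code{$valid}
#'   mask drives the \code{invalid} flag).
#' @param nuclei optional nucleus \code{label_image} (adds nucleus and
#'   cytosol areas and the died flag).
#' @param died_area_px nucleus area threshold for the died flag.
#' @param guard_px width (px) of the excluded band along boundaries
#'   shared with another cell.
#' @param condition,field_id metadata copied into the table.
#' @return a \code{data.frame} (CellTable).
#' @export
measure_cells <- function(cells, aligned, nuclei = NULL,
                          died_area_px = 95, guard_px = 2,
                          condition = NA_character_,
                          field_id = NA_character_) {
  obj <- attr(cells, "objects")
  if (is.null(obj) || !nrow(obj)) stop("no cells to measure")
  lab <- unclass(cells)
  n <- nrow(obj)
  d1 <- dim(aligned$rounds[[1]]$channels[[1]])
  if (!identical(dim(lab), d1))
    stop("label image and images have different shapes")
  idx <- which(lab > 0L)
  l <- lab[idx]
  if (!identical(sort(unique(l)), seq_len(n)))
    stop("label image contains labels with zero pixels")
  area_full <- tabulate(l, nbins = n)
  if (guard_px > 0) {
    contested <- matrix(FALSE, nrow(lab), ncol(lab))
    steps <- expand.grid(dy = -1:1, dx = -1:1)
    steps <- steps[!(steps$dy == 0 & steps$dx == 0), ]
    for (s in seq_len(nrow(steps))) {
      ls <- .roll_fill(lab, steps$dy[s], steps$dx[s], fill = 0L)
      contested <- contested | (lab > 0L & ls > 0L & ls != lab)
    }
    for (g in seq_len(guard_px - 1)) {
      grown <- contested
      for (s in seq_len(nrow(steps)))
        grown <- grown | .roll_fill(contested, steps$dy[s], steps$dx[s],
                                    fill = FALSE)
      contested <- grown
    }
    keep <- !contested[idx]
    # never let the guard empty a cell
    kept_area <- tabulate(l[keep], nbins = n)
    emptied <- which(kept_area == 0)
    if (length(emptied)) keep[l %in% emptied] <- TRUE
    idx <- idx[keep]
    l <- l[keep]
  }
  area <- tabulate(l, nbins = n)
  tab <- data.frame(cell_id = obj$label, field_id = field_id,
                    condition = condition, row = obj$row, col = obj$col,
                    area_cell_px = area_full, area_measured_px = area,
                    stringsAsFactors = FALSE)
  if (!is.null(nuclei)) {
    nl <- unclass(nuclei)
    tab$area_nucleus_px <- tabulate(nl[nl > 0L], nbins = n)
    tab$area_cytosol_px <- area_full - tab$area_nucleus_px
    tab$died <- tab$area_nucleus_px < died_area_px
  }
  for (r in seq_along(aligned$rounds)) {
    chs <- aligned$rounds[[r]]$channels
    for (ch in names(chs)) {
      if (!identical(dim(chs[[ch]]), d1))
        stop("image shape mismatch in round ", r, " channel ", ch)
      s <- rowsum(as.numeric(chs[[ch]][idx]), l)[, 1]
      tab[[.meas_col(r, ch, "sum")]] <- as.numeric(s)
      tab[[.meas_col(r, ch, "mean")]] <- as.numeric(s) / area
    }
  }
  tab$border <- obj$border
  tab$invalid <- if (!is.null(aligned$valid))
    as.logical(tabulate(l[!aligned$valid[idx]], nbins = n) > 0)
  else FALSE
  tab
}

#' Per-cell Pearson colocalization over the cytosol
#'
#' For each cell, the Pearson correlation of two channels' pixel
#' intensities over that cell's cytosol region. Cells with fewer than
#' 3 cytosol pixels or zero variance in either channel get \code{NA}.
#'
#' @param cytosol cytosol \code{label_image}.
#' @param channel_a,channel_b 2D matrices, same shape as \code{cytosol}.
#' @return data.frame(cell_id, n_px, pearson).
#' @export
colocalize <- function(cytosol, channel_a, channel_b) {
  if (!identical(dim(unclass(cytosol)), dim(channel_a)) ||
      !identical(dim(channel_a), dim(channel_b)))
    stop("cytosol and channel images must share shape")
  obj <- attr(cytosol, "objects")
  nmax <- if (!is.null(obj) && nrow(obj)) max(obj$label) else
    max(0L, unclass(cytosol))
  lab <- unclass(cytosol)
  idx <- which(lab > 0L)
  l <- lab[idx]
  a <- as.numeric(channel_a[idx]); b <- as.numeric(channel_b[idx])
  n <- tabulate(l, nbins = nmax)
  sa <- rowsum(a, l); sb <- rowsum(b, l)
  saa <- rowsum(a * a, l); sbb <- rowsum(b * b, l); sab <- rowsum(a * b, l)
  full <- function(s) { v <- numeric(nmax); v[as.integer(rownames(s))] <- s[, 1]; v }
  sa <- full(sa); sb <- full(sb); saa <- full(saa); sbb <- full(sbb)
  sab <- full(sab)
  cov_ab <- sab - sa * sb / pmax(n, 1)
  var_a <- saa - sa^2 / pmax(n, 1)
  var_b <- sbb - sb^2 / pmax(n, 1)
  r <- rep(NA_real_, nmax)
  ok <- n >= 3 & var_a > 1e-12 & var_b > 1e-12
  r[ok] <- cov_ab[ok] / sqrt(var_a[ok] * var_b[ok])
  data.frame(cell_id = seq_len(nmax), n_px = n, pearson = r)
}
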