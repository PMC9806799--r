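# Rendering ground-truth populations as multi-round fluorescence images.
#
# Scenes are piecewise constant per cell region (nucleus / cytoplasm), so
# with noise, carryover and drift switched off, per-cell region means are
# exactly the configured truths.

# Rasterize the nuclei of a ground-truth table into an integer label
# matrix. Died (non-resealed) cells are drawn with shrunken nuclei.
.rasterize_nuclei <- function(gt, config) {
  shp <- config$field_shape
  lab <- matrix(0L, shp[1], shp[2])
  shrink <- config$nucleus$died_shrink
  for (i in seq_len(nrow(gt))) {
    a <- gt$nuc_a[i] * if (gt$died[i]) shrink else 1
    b <- a * gt$nuc_ratio[i]
    th <- gt$nuc_theta[i]
    r0 <- gt$row[i]; c0 <- gt$col[i]
    ext <- ceiling(a) + 1L
    rr <- max(1L, floor(r0 - ext)):min(shp[1], ceiling(r0 + ext))
    cc <- max(1L, floor(c0 - ext)):min(shp[2], ceiling(c0 + ext))
    dy <- rr - r0
    dx <- matrix(cc, nrow = length(rr), ncol = length(cc),
                 byrow = TRUE) - c0
    dym <- matrix(dy, nrow = length(rr), ncol = length(cc))
    u <- (dx * cos(th) + dym * sin(th)) / a
    v <- (-dx * sin(th) + dym * cos(th)) / b
    inside <- u * u + v * v <= 1
    sub <- lab[rr, cc, drop = FALSE]
    sub[inside & sub == 0L] <- i
    lab[rr, cc] <- sub
  }
  lab
}

# Expand a nucleus label matrix by `radius` px (Euclidean distance to the
# nucleus region), assigning each expanded pixel to the NEAREST nucleus
# (ties to the lower label). Exact: per-label windowed distance transforms
# combined by global argmin. Used by both the renderer and expand_cells so
# rendered and segmented cell regions coincide.
.expand_labels_nearest <- function(lab, radius) {
  if (radius < 0) stop("radius_px must be >= 0")
  labs <- sort(unique(lab[lab > 0L]))
  if (radius == 0 || !length(labs)) return(lab)
  shp <- dim(lab)
  bestd <- matrix(Inf, shp[1], shp[2])
  out <- matrix(0L, shp[1], shp[2])
  rad <- ceiling(radius) + 1L
  idx_all <- which(lab > 0L)
  l_all <- lab[idx_all]
  r_all <- ((idx_all - 1L) %% shp[1]) + 1L
  c_all <- ((idx_all - 1L) %/% shp[1]) + 1L
  by_lab <- split(seq_along(l_all), l_all)
  for (k in labs) {
    sel <- by_lab[[as.character(k)]]
    rr <- range(r_all[sel]); cc <- range(c_all[sel])
    wr <- max(1L, rr[1] - rad):min(shp[1], rr[2] + rad)
    wc <- max(1L, cc[1] - rad):min(shp[2], cc[2] + rad)
    sub <- lab[wr, wc, drop = FALSE]
    dm <- EBImage::distmap(matrix(as.numeric(sub != k), nrow = length(wr)))
    if (methods::is(dm, "Image")) dm <- EBImage::imageData(dm)
    upd <- dm <= radius & dm < bestd[wr, wc] - 1e-9
    bsub <- bestd[wr, wc, drop = FALSE]
    osub <- out[wr, wc, drop = FALSE]
    bsub[upd] <- dm[upd]
    osub[upd] <- k
    bestd[wr, wc] <- bsub
    out[wr, wc] <- osub
  }
  # nucleus pixels always belong to their own label
  out[lab > 0L] <- lab[lab > 0L]
  out
}

# Integer translation with constant fill: content moves +dy rows, +dx cols.
.roll_fill <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Per-cell scene value for a channel name, given the truth table.
.channel_values <- function(gt, channel, config, compartment) {
  n <- nrow(gt)
  if (channel == config$nuclear_channel) {
    if (compartment == "nucleus") gt$dna else rep(0, n)
  } else if (channel == "ab") {
    gt$A
  } else if (channel == "target") {
    if (compartment == "nucleus") gt$X * config$nuclear_target_ratio else gt$X
  } else if (channel == "blank") {
    rep(0, n)
  } else if (paste0("P_", channel) %in% names(gt)) {
    if (compartment == "nucleus") rep(0, n) else gt[[paste0("P_", channel)]]
  } else {
    stop("unknown channel '", channel, "'")
  }
}

#' Render a ground-truth population as a multi-round image set
#'
#' Nuclei are filled ellipses in the nuclear channel; the cytoplasm is the
#' nucleus thickened by \code{cyto_radius_px} (nearest-nucleus assignment
#' against neighbors). The antibody channel covers nucleus + cytoplasm; the
#' target covers the cytoplasm and the nucleus at
#' \code{nuclear_target_ratio}; phospho channels cover the cytoplasm. Per
#' round the scene is translated by an integer stage drift drawn from
#' \code{Normal(0, shift_px_sd)} (recorded as the true shift), residual
#' bleaching carryover from the previous round's same-slot channel is
#' added, then a background plane + gradient, Poisson shot noise, Gaussian
#' read noise, and clipping to unsigned 16-bit.
#'
#' @param gt ground-truth table from \code{\link{sample_population}}.
#' @param config the \code{sim_config} used to generate it.
#' @return an \code{image_set}: list with \code{rounds} (each a list of
#'   \code{channels} matrices and the \code{true_shift}), \code{pixel_um},
#'   \code{nuclear_channel} and \code{field_id}. The truth table augmented
#'   with realized region areas and per-channel true region means
#'   (\code{true_<channel>}) is attached as attribute \code{"truth"}.
#' @export
render_rounds <- function(gt, config) {
  config <- validate_sim_config(config)
  shp <- config$field_shape
  ext_need <- max(gt$nuc_a) + config$cyto_radius_px + 2
  if (any(gt$row < ext_need) || any(gt$row > shp[1] - ext_need) ||
      any(gt$col < ext_need) || any(gt$col > shp[2] - ext_need))
    stop("cells do not fit in field_shape with the required margin")
  set.seed(config$seed + 1L)

  nuc_lab <- .rasterize_nuclei(gt, config)
  cell_lab <- .expand_labels_nearest(nuc_lab, config$cyto_radius_px)
  n <- nrow(gt)
  nuc_area <- tabulate(nuc_lab[nuc_lab > 0L], nbins = n)
  cell_area <- tabulate(cell_lab[cell_lab > 0L], nbins = n)
  gt$area_nucleus_px <- nuc_area
  gt$area_cell_px <- cell_area

  channels <- unique(unlist(config$rounds))
  scenes <- vector("list", length(channels)); names(scenes) <- channels
  in_nuc <- nuc_lab > 0L
  in_cyto <- cell_lab > 0L & !in_nuc
  for (ch in channels) {
    sc <- matrix(0, shp[1], shp[2])
    vn <- .channel_values(gt, ch, config, "nucleus")
    vc <- .channel_values(gt, ch, config, "cytoplasm")
    sc[in_nuc] <- vn[nuc_lab[in_nuc]]
    sc[in_cyto] <- vc[cell_lab[in_cyto]]
    scenes[[ch]] <- sc
    tm <- rowsum(sc[cell_lab > 0L], cell_lab[cell_lab > 0L])[, 1]
    gt[[paste0("true_", ch)]] <- as.numeric(tm) / pmax(cell_area, 1)
  }

  bgf <- config$noise$background +
    config$noise$gradient *
    (outer(seq_len(shp[1]) / shp[1], seq_len(shp[2]) / shp[2], "+")) / 2

  rounds <- vector("list", length(config$rounds))
  prev_eff <- NULL
  for (r in seq_along(config$rounds)) {
    chs <- config$rounds[[r]]
    shift <- if (r == 1) c(0, 0) else
      round(stats::rnorm(2, 0, config$shift_px_sd))
    eff <- vector("list", length(chs)); names(eff) <- chs
    imgs <- vector("list", length(chs)); names(imgs) <- chs
    for (j in seq_along(chs)) {
      ch <- chs[j]
      e <- scenes[[ch]]
      if (r > 1 && config$bleach_carryover > 0 &&
          ch != config$nuclear_channel &&
          j <= length(config$rounds[[r - 1]]) &&
          config$rounds[[r - 1]][j] != config$nuclear_channel) {
        e <- e + config$bleach_carryover * prev_eff[[j]]
      }
      eff[[j]] <- e
      img <- .roll_fill(e, shift[1], shift[2], fill = 0) + bgf
      quantize <- isTRUE(config$noise$shot) || config$noise$read_sd > 0
      if (isTRUE(config$noise$shot))
        img <- matrix(stats::rpois(length(img), img), nrow = shp[1])
      if (config$noise$read_sd > 0)
        img <- img + stats::rnorm(length(img), 0, config$noise$read_sd)
      # detector counts are integers; a noise-free render keeps the exact
      # scene values so region means equal the configured truths
      img <- pmin(pmax(img, 0), 65535)
      if (quantize) img <- round(img)
      imgs[[j]] <- img
    }
    prev_eff <- eff
    rounds[[r]] <- list(channels = imgs, true_shift = as.numeric(shift))
  }

  iset <- structure(
    list(rounds = rounds, pixel_um = config$pixel_um,
         nuclear_channel = config$nuclear_channel,
         field_id = "field1", seed = config$seed),
    class = "image_set")
  attr(iset, "truth") <- gt
  iset
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$rounds[[1]]$channels[[1]])
  cat("<image_set> ", length(x$rounds), " round(s), ", d[1], "x", d[2],
      " px, pixel ", x$pixel_um, " um\n", sep = "")
  for (r in seq_along(x$rounds))
    cat("  round ", r, ": ",
        paste(names(x$rounds[[r]]$channels), collapse = ", "),
        "  shift (", paste(x$rounds[[r]]$true_shift, collapse = ", "),
        ")\n", sep = "")
  invisible(x)
}

#' Simulate one field end to end
#'
#' Convenience wrapper: \code{\link{sample_population}} then
#' \code{\link{apply_spatial_mode}} then \code{\link{render_rounds}}.
#'
#' @param config a \code{sim_config}.
#' @return an \code{image_set} with the truth table attached
#'   (attribute \code{"truth"}).
#' @export
simulate_field <- function(config) {
  gt <- sample_population(config)
  gt <- apply_spatial_mode(gt, config)
  render_rounds(gt, config)
}
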