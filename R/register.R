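# Translation registration of cyclic-immunofluorescence rounds against the
# round-1 nuclear image, by normalized cross-correlation (phase
# correlation) in the frequency domain with optional sub-pixel refinement
# via a locally upsampled DFT.

# Wrap an index of an n-periodic axis into a signed shift in (-n/2, n/2].
.wrap_shift <- function(idx, n) {
  s <- idx - 1
  ifelse(s > n / 2, s - n, s)
}

# Matrix-multiplication DFT of the cross-power spectrum over a small
# window around `center` (in shift space) at resolution 1/upsample.
.upsampled_peak <- function(cps, center, upsample, halfwidth = 1.5) {
  nr <- nrow(cps); nc <- ncol(cps)
  steps <- seq(-halfwidth, halfwidth, by = 1 / upsample)
  ry <- center[1] + steps
  rx <- center[2] + steps
  fy <- .wrap_shift(seq_len(nr), nr) / nr
  fx <- .wrap_shift(seq_len(nc), nc) / nc
  Ey <- exp(2i * pi * outer(ry, fy))          # |ry| x nr
  Ex <- exp(2i * pi * outer(fx, rx))          # nc x |rx|
  m <- Re(Ey %*% cps %*% Ex)
  pk <- which(m == max(m), arr.ind = TRUE)[1, ]
  c(ry[pk[1]], rx[pk[2]])
}

#' Estimate the translation between two nuclear images
#'
#' Translation-only estimate by phase correlation: the normalized
#' cross-power spectrum is inverted to a correlation surface whose peak
#' gives the integer shift; when \code{upsample > 1} the peak is refined
#' on a locally upsampled DFT to \code{1/upsample}-pixel resolution. The
#' returned score is the Pearson correlation between the reference and the
#' moving image shifted back by the (rounded) estimate, over the
#' overlapping region.
#'
#' @param reference,moving equal-shaped 2D images (matrices).
#' @param upsample sub-pixel refinement factor (1 = integer only).
#' @param max_shift largest plausible shift in pixels; estimates beyond it
#'   are flagged \code{low_confidence} (default one tenth of the image width).
#' @return list with \code{shift} (dy, dx) such that \code{moving} is the
#'   reference translated by \code{shift}, \code{score} between -1 and 1, and
#'   \code{low_confidence}.
#' @export
#' @examples
#' img <- matrix(stats::rnorm(64 * 64), 64)
#' estimate_shift(img, img)$shift
estimate_shift <- function(reference, moving, upsample = 10,
                           max_shift = NULL) {
  if (!identical(dim(reference), dim(moving)))
    stop("reference and moving images must have identical shapes")
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0)
    stop("no registration signal: constant image")
  if (is.null(max_shift)) max_shift <- 0.1 * ncol(reference)
  F1 <- stats::fft(reference - mean(reference))
  F2 <- stats::fft(moving - mean(moving))
  R <- F1 * Conj(F2)
  cps <- R / pmax(Mod(R), 1e-12)
  corr <- Re(stats::fft(cps, inverse = TRUE)) / length(cps)
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  shift <- c(.wrap_shift(pk[1], nrow(corr)), .wrap_shift(pk[2], ncol(corr)))
  # phase-correlation peak at +s when moving(x) = reference(x - s)
  shift <- -shift
  if (upsample > 1)
    shift <- -.upsampled_peak(cps, -shift, upsample)
  ish <- round(shift)
  back <- .roll_fill(moving, -ish[1], -ish[2], fill = NA)
  ok <- !is.na(back)
  score <- if (sum(ok) > 3 && stats::sd(back[ok]) > 0 &&
               stats::sd(reference[ok]) > 0)
    stats::cor(reference[ok], back[ok]) else NA_real_
  low_conf <- sqrt(sum(shift^2)) > max_shift
  if (low_conf)
    warning("estimated shift (", paste(signif(shift, 4), collapse = ", "),
            ") exceeds max_shift = ", max_shift, "; flagged low-confidence")
  list(shift = as.numeric(shift), score = score, low_confidence = low_conf)
}

#' Translate an image back onto the reference frame
#'
#' Undoes a displacement: the image is translated by \code{-shift}.
#' Integer shifts are exact pixel rolls with \code{fill} at exposed
#' borders; fractional shifts use first-order (bilinear) interpolation.
#' A logical validity mask (pixels sampled entirely inside the input) is
#' attached as attribute \code{"valid"}.
#'
#' @param image 2D matrix.
#' @param shift numeric (dy, dx): the displacement to undo.
#' @param fill value for exposed border pixels.
#' @return the translated matrix, same shape.
#' @export
apply_shift <- function(image, shift, fill = 0) {
  if (!all(is.finite(shift)) || length(shift) != 2)
    stop("shift must be two finite numbers")
  dy <- shift[1]; dx <- shift[2]
  nr <- nrow(image); nc <- ncol(image)
  if (dy == round(dy) && dx == round(dx)) {
    out <- .roll_fill(image, -round(dy), -round(dx), fill = fill)
    valid <- .roll_fill(matrix(TRUE, nr, nc), -round(dy), -round(dx),
                        fill = FALSE)
  } else {
    # out(r, c) = image(r + dy, c + dx), bilinear
    sr <- seq_len(nr) + dy
    sc <- seq_len(nc) + dx
    r0 <- floor(sr); c0 <- floor(sc)
    wr <- sr - r0; wc <- sc - c0
    gv <- function(ri, ci) {
      ok_r <- ri >= 1 & ri <= nr
      ok_c <- ci >= 1 & ci <= nc
      m <- matrix(fill, nr, nc)
      if (any(ok_r) && any(ok_c))
        m[which(ok_r), which(ok_c)] <- image[ri[ok_r], ci[ok_c],
                                             drop = FALSE]
      m
    }
    W_r <- matrix(wr, nr, nc)
    W_c <- matrix(wc, nr, nc, byrow = TRUE)
    out <- (1 - W_r) * (1 - W_c) * gv(r0, c0) +
      (1 - W_r) * W_c * gv(r0, c0 + 1) +
      W_r * (1 - W_c) * gv(r0 + 1, c0) +
      W_r * W_c * gv(r0 + 1, c0 + 1)
    valid <- outer(r0 >= 1 & (r0 + 1) <= nr | (wr == 0 & r0 >= 1 & r0 <= nr),
                   c0 >= 1 & (c0 + 1) <= nc | (wc == 0 & c0 >= 1 & c0 <= nc),
                   "&")
  }
  attr(out, "valid") <- valid
  out
}

#' Register all rounds of an image set to round 1
#'
#' Each round's shift is estimated from its nuclear channel against the
#' round-1 nuclear channel and then applied to all channels of that round.
#' Round 1 is never altered. A validity mask (pixels valid in every round
#' after alignment) is attached to the aligned set as \code{$valid}.
#'
#' @param image_set an \code{image_set}.
#' @param upsample sub-pixel factor passed to \code{\link{estimate_shift}}.
#' @param max_shift passed to \code{\link{estimate_shift}}.
#' @return list with \code{aligned} (a new \code{image_set}) and
#'   \code{report} (data.frame: round, dy, dx, score, low_confidence,
#'   residual after alignment in px).
#' @export
register_rounds <- function(image_set, upsample = 10, max_shift = NULL) {
  nuc <- image_set$nuclear_channel
  for (r in seq_along(image_set$rounds))
    if (!nuc %in% names(image_set$rounds[[r]]$channels))
      stop("round ", r, " is missing the nuclear channel '", nuc, "'")
  ref <- image_set$rounds[[1]]$channels[[nuc]]
  aligned <- image_set
  nr <- length(image_set$rounds)
  rep_df <- data.frame(round = seq_len(nr), dy = 0, dx = 0, score = NA_real_,
                       low_confidence = FALSE, residual = 0)
  valid <- matrix(TRUE, nrow(ref), ncol(ref))
  rep_df$score[1] <- 1
  for (r in seq_len(nr)[-1]) {
    est <- estimate_shift(ref, image_set$rounds[[r]]$channels[[nuc]],
                          upsample = upsample, max_shift = max_shift)
    aligned$rounds[[r]]$channels <- lapply(
      image_set$rounds[[r]]$channels,
      function(ch) {
        out <- apply_shift(ch, est$shift)
        attr(out, "valid") <- NULL
        out
      })
    vr <- attr(apply_shift(image_set$rounds[[r]]$channels[[nuc]], est$shift),
               "valid")
    valid <- valid & vr
    res <- estimate_shift(ref, aligned$rounds[[r]]$channels[[nuc]],
                          upsample = upsample, max_shift = max_shift)
    rep_df[r, c("dy", "dx")] <- est$shift
    rep_df$score[r] <- est$score
    rep_df$low_confidence[r] <- est$low_confidence
    rep_df$residual[r] <- sqrt(sum(res$shift^2))
    aligned$rounds[[r]]$estimated_shift <- est$shift
  }
  aligned$valid <- valid
  list(aligned = aligned, report = rep_df)
}
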