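# Ground-truth population sampling: who got permeabilized, how much
# antibody each cell received, and how much target remains.

# Random non-overlapping cell placement by dart throwing with a coarse
# occupancy grid. Errors when the field cannot hold n cells at the
# requested spacing.
.place_cells <- function(n, shape, min_spacing, margin) {
  lo_r <- margin; hi_r <- shape[1] - margin
  lo_c <- margin; hi_c <- shape[2] - margin
  if (hi_r <= lo_r || hi_c <= lo_c)
    stop("field too small for the configured margin")
  cap <- floor(0.6 * (hi_r - lo_r) * (hi_c - lo_c) /
                 (pi * (min_spacing / 2)^2))
  if (n > cap)
    stop("field too small: cannot place ", n, " cells at spacing ",
         min_spacing, " px (approximate capacity ", cap, ")")
  # grid cells of spacing/sqrt(2) hold at most one accepted point, so a
  # +/-2 cell neighborhood scan sees every point within min_spacing
  cs <- min_spacing / sqrt(2)
  grid <- matrix(0L, nrow = ceiling(shape[1] / cs), ncol = ceiling(shape[2] / cs))
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L; attempts <- 0L; max_attempts <- 400L * n
  msq <- min_spacing^2
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- stats::runif(1, lo_r, hi_r)
    c <- stats::runif(1, lo_c, hi_c)
    gr <- ceiling(r / cs); gc <- ceiling(c / cs)
    ok <- TRUE
    for (dr in -2:2) for (dc in -2:2) {
      gi <- gr + dr; gj <- gc + dc
      if (gi < 1 || gj < 1 || gi > nrow(grid) || gj > ncol(grid)) next
      k <- grid[gi, gj]
      if (k > 0L && (rows[k] - r)^2 + (cols[k] - c)^2 < msq) ok <- FALSE
    }
    if (ok) {
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- c
      grid[gr, gc] <- placed
    }
  }
  if (placed < n)
    stop("field too small: placed only ", placed, " of ", n,
         " cells at spacing ", min_spacing, " px")
  data.frame(row = rows, col = cols)
}

# Fill in all latent truths downstream of the permeabilization
# probabilities (delivery, resealing, degradation, phospho channels).
.sample_latents <- function(pos, p_perm, config) {
  n <- nrow(pos)
  kin <- config$deg_kinetics
  permeabilized <- stats::runif(n) < p_perm
  reseal_fail <- stats::runif(n) < config$reseal_fail_prob
  died <- permeabilized & reseal_fail
  A <- ifelse(permeabilized,
              stats::rlnorm(n, config$antibody_lognormal[1],
                            config$antibody_lognormal[2]), 0)
  T21 <- stats::rlnorm(n, config$trim21_lognormal[1],
                       config$trim21_lognormal[2])
  X0 <- stats::rlnorm(n, config$target_lognormal[1],
                      config$target_lognormal[2])
  k <- kin$k_max * (A / (A + kin$K_A)) * (T21 / (T21 + kin$K_T))
  k[A == 0] <- 0
  if (config$condition == "targeting") {
    X <- X0 * (kin$f_res + (1 - kin$f_res) * exp(-k * config$incubation_h))
    X[A == 0] <- X0[A == 0]
  } else {
    X <- X0
  }
  cc <- stats::runif(n) < config$cc_subpop[["pi"]]
  gt <- data.frame(
    cell_id = seq_len(n),
    row = pos$row, col = pos$col,
    nuc_a = stats::rlnorm(n, config$nucleus$r_meanlog, config$nucleus$r_sdlog),
    nuc_ratio = stats::runif(n, config$nucleus$ratio_range[1],
                             config$nucleus$ratio_range[2]),
    nuc_theta = stats::runif(n, 0, pi),
    dna = stats::rlnorm(n, config$dna_lognormal[1], config$dna_lognormal[2]),
    perm_prob = p_perm,
    permeabilized = permeabilized,
    resealed = !died,
    died = died,
    A = A, T21 = T21, X0 = X0, X = X,
    cc = cc,
    condition = config$condition,
    stringsAsFactors = FALSE
  )
  for (ch in names(config$phospho_link)) {
    ph <- config$phospho_link[[ch]]
    P <- ph$beta * X^ph$gamma * exp(stats::rnorm(n, 0, ph$noise_sd))
    if (ch %in% config$cc_channels)
      P <- P * ifelse(cc, config$cc_subpop[["fold"]], 1)
    gt[[paste0("P_", ch)]] <- P
  }
  gt
}

#' Sample a ground-truth cell population
#'
#' Draws one field's worth of cells under the delivery/degradation model:
#' per-cell permeabilization probability from the Hill dose response
#' modulated by a lognormal membrane-cholesterol factor, Bernoulli
#' resealing failure among permeabilized cells, lognormal antibody / TRIM21
#' / target amounts, saturating first-order degradation of the target in
#' the targeting condition, and downstream phospho channels coupled to the
#' remaining target (with a high-pS6 subpopulation).
#'
#' @param config a \code{sim_config}.
#' @return a \code{data.frame} (the ground-truth table) with one row per
#'   cell: position, nuclear geometry, latent amounts \code{A} (antibody),
#'   \code{T21}, \code{X0}/\code{X} (target before/after incubation),
#'   flags (\code{permeabilized}, \code{resealed}, \code{died}), phospho
#'   levels \code{P_*}, and condition. The config is attached as
#'   attribute \code{"config"}.
#' @export
#' @examples
#' gt <- sample_population(sim_config(n_cells = 50, seed = 3))
#' mean(gt$permeabilized)
sample_population <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  pos <- .place_cells(config$n_cells, config$field_shape,
                      config$min_spacing_px, config$margin_px)
  n <- nrow(pos)
  chol <- stats::rlnorm(n, 0, config$chol_sdlog)
  h <- config$perm_hill[["h"]]
  d <- (config$slo_dose * chol)^h
  p <- if (config$slo_dose > 0)
    d / (d + config$perm_hill[["K_dose"]]^h) else rep(0, n)
  gt <- .sample_latents(pos, p, config)
  gt$chol <- chol
  attr(gt, "config") <- config
  gt
}

#' Apply a spatial delivery-efficiency mode
#'
#' In \code{center_gradient} mode (adherent electroporation geometry) the
#' permeabilization probability is rescaled by a logistic radial falloff
#' \code{g(r) = 1 - a + a / (1 + exp((r/R - midpoint) / steepness))} in the
#' distance r from the field center (R = half the smaller field dimension),
#' and all downstream latents (delivery, resealing, degradation, phospho)
#' are re-drawn under the new probabilities. \code{uniform} mode returns
#' the table unchanged; amplitude 0 degenerates to uniform.
#'
#' @param gt a ground-truth table from \code{\link{sample_population}}.
#' @param config the \code{sim_config} (its \code{spatial_mode} applies).
#' @return the (possibly re-drawn) ground-truth table.
#' @export
apply_spatial_mode <- function(gt, config) {
  config <- validate_sim_config(config)
  if (config$spatial_mode == "uniform") return(gt)
  a <- config$spatial_params[["amplitude"]]
  if (a == 0) return(gt)
  set.seed(config$seed + 2L)
  ctr <- config$field_shape / 2
  R <- min(config$field_shape) / 2
  r <- sqrt((gt$row - ctr[1])^2 + (gt$col - ctr[2])^2) / R
  mid <- config$spatial_params[["midpoint_frac"]]
  stp <- config$spatial_params[["steepness_frac"]]
  g <- 1 - a + a / (1 + exp((r - mid) / stp))
  out <- .sample_latents(gt[c("row", "col")], gt$perm_prob * g, config)
  out$chol <- gt$chol
  attr(out, "config") <- config
  attr(out, "radial_falloff") <- g
  out
}
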