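# End-to-end orchestration: simulate -> register -> project -> segment ->
# measure -> gate -> knockdown / percentile analysis -> embedding.

# Measurement column holding a channel's per-cell mean: first round that
# stains the channel.
.channel_column <- function(config, channel, stat = "mean") {
  for (r in seq_along(config$rounds))
    if (channel %in% config$rounds[[r]])
      return(.meas_col(r, channel, stat))
  NULL
}

#' Simulate fields and reduce them to a measured cell table
#'
#' Runs the image half of the pipeline: the requested number of cells is
#' split into fields, each field is simulated and rendered, rounds are
#' registered to round 1, the nuclear channel is max-projected and
#' segmented, nuclei are thickened into cell regions, and per-cell
#' intensities are measured. Ground truth is pooled alongside for
#' validation.
#'
#' @param config a \code{sim_config}.
#' @param n_cells total cells to simulate (split into fields of at most
#'   \code{n_per_field}).
#' @param seed simulation seed (each field derives its own sub-seed).
#' @param n_per_field cells per field.
#' @param seg_params overrides for \code{\link{segment_nuclei}}.
#' @param upsample registration sub-pixel factor.
#' @return list: \code{cells} (measured CellTable over all fields),
#'   \code{truth} (pooled ground truth), \code{shifts} (per-field shift
#'   reports), \code{n_fields}.
#' @export
simulate_celltable <- function(config, n_cells = config$n_cells,
                               seed = config$seed, n_per_field = 850,
                               seg_params = list(), upsample = 10) {
  config <- validate_sim_config(config)
  n_fields <- ceiling(n_cells / n_per_field)
  sizes <- rep(floor(n_cells / n_fields), n_fields)
  rem <- n_cells - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  tabs <- vector("list", n_fields)
  gts <- vector("list", n_fields)
  shifts <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    cfg <- config
    cfg$n_cells <- sizes[f]
    cfg$seed <- as.integer(seed + 977L * f)
    iset <- simulate_field(cfg)
    iset$field_id <- paste0("field", f)
    reg <- register_rounds(iset, upsample = upsample)
    nuc_img <- max_project(
      reg$aligned$rounds[[1]]$channels[[config$nuclear_channel]])
    nuclei <- segment_nuclei(nuc_img, seg_params)
    cells_lab <- expand_cells(nuclei, config$cyto_radius_px)
    tab <- measure_cells(cells_lab, reg$aligned, nuclei = nuclei,
                         died_area_px = config$died_area_px,
                         condition = config$condition,
                         field_id = iset$field_id)
    tab$cell_id <- paste0("f", f, "_", tab$cell_id)
    gt <- attr(iset, "truth")
    gt$field_id <- iset$field_id
    gt$cell_id <- paste0("f", f, "_", gt$cell_id)
    rep_f <- reg$report; rep_f$field_id <- iset$field_id
    tabs[[f]] <- tab; gts[[f]] <- gt; shifts[[f]] <- rep_f
  }
  list(cells = do.call(rbind, tabs), truth = do.call(rbind, gts),
       shifts = do.call(rbind, shifts), n_fields = n_fields)
}

#' Pipeline run configuration
#'
#' Validated description of one end-to-end run: which preset (or explicit
#' \code{sim_config}) to simulate, how many cells per condition, the
#' gating rule, the percentile levels, and the output directory. Unknown
#' keys are rejected before any stage runs.
#'
#' @param preset preset name (see \code{\link{preset_config}}); ignored if
#'   \code{config} is given.
#' @param config explicit \code{sim_config} (optional).
#' @param n_cells cells per condition.
#' @param seed run seed.
#' @param conditions character subset of c("targeting", "NC").
#' @param outdir output directory.
#' @param gating_rule rule list for \code{\link{gate_positive}}.
#' @param n_null cells in the no-delivery null used for gating.
#' @param percentiles top-percentile levels for the separation analysis.
#' @param seg_params segmentation overrides.
#' @param embed logical: run the t-SNE embedding stage.
#' @param write_images logical: write the rendered TIFF image sets.
#' @param n_boot bootstrap resamples for knockdown CIs.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(preset = NULL, config = NULL, n_cells = 2000,
                       seed = 1, conditions = c("targeting", "NC"),
                       outdir = file.path(tempdir(), "trimcycif_run"),
                       gating_rule = list(type = "quantile", q = 0.99),
                       n_null = 600,
                       percentiles = c(100, 50, 25, 10, 5),
                       seg_params = list(), embed = FALSE,
                       write_images = FALSE, n_boot = 500) {
  if (is.null(config)) {
    if (is.null(preset)) stop("provide either a preset name or a config")
    config <- preset_config(preset, n_cells = min(n_cells, 650L),
                            seed = as.integer(seed))
  }
  config <- validate_sim_config(config)
  conditions <- match.arg(conditions, c("targeting", "NC"),
                          several.ok = TRUE)
  structure(list(preset = preset, config = config, n_cells = n_cells,
                 seed = as.integer(seed), conditions = conditions,
                 outdir = outdir, gating_rule = gating_rule,
                 n_null = n_null, percentiles = percentiles,
                 seg_params = seg_params, embed = embed,
                 write_images = write_images, n_boot = n_boot),
            class = "run_config")
}

.config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' Executes simulate -> register -> max-project -> segment -> measure for
#' every requested condition, then gates delivery-positive cells against a
#' no-delivery null, estimates knockdown (bulk, gated and per top
#' percentile) when both conditions are present, computes the separation
#' curve, and optionally a t-SNE embedding. Every stage logs a line with
#' its parameters; artifacts (CSV tables, JSON reports, a manifest tying
#' outputs to the config hash) are written under \code{outdir}.
#'
#' @param rc a \code{run_config}.
#' @param quiet suppress stage log messages.
#' @return (invisibly) list: per-condition \code{cells} tables,
#'   \code{gating}, \code{knockdown} (list per mode), \code{separation},
#'   \code{embedding} (or NULL), \code{manifest}, \code{outdir}.
#' @export
run_pipeline <- function(rc, quiet = FALSE) {
  stopifnot(inherits(rc, "run_config"))
  say <- function(...) if (!quiet) message("[trimcycif] ", ...)
  cfg <- rc$config
  dir.create(rc$outdir, recursive = TRUE, showWarnings = FALSE)
  ab_col <- .channel_column(cfg, "ab")
  target_col <- .channel_column(cfg, "target")

  stage <- "simulate+measure"
  res <- list()
  counts <- list()
  tryCatch({
    for (cond in rc$conditions) {
      ccfg <- cfg; ccfg$condition <- cond
      say(stage, ": condition ", cond, ", n = ", rc$n_cells,
          ", seed = ", rc$seed)
      sct <- simulate_celltable(ccfg, n_cells = rc$n_cells, seed = rc$seed,
                                seg_params = rc$seg_params)
      res[[cond]] <- sct
      counts[[cond]] <- list(
        segmented = nrow(sct$cells),
        died = sum(sct$cells$died),
        border = sum(sct$cells$border),
        invalid = sum(sct$cells$invalid),
        analyzable = nrow(.analyzable(sct$cells)))
      write_cell_table(sct$cells,
                       file.path(rc$outdir, paste0("cells_", cond, ".csv")))
      utils::write.csv(sct$shifts,
                       file.path(rc$outdir, paste0("shifts_", cond, ".csv")),
                       row.names = FALSE)
      if (rc$write_images) {
        icfg <- ccfg; icfg$n_cells <- min(rc$n_cells, 650L)
        write_image_set(simulate_field(icfg),
                        file.path(rc$outdir, "images"),
                        prefix = paste0(cond, "_example"))
      }
    }

    stage <- "gate"
    ncfg <- cfg
    ncfg$slo_dose <- 0; ncfg$condition <- "NC"
    say(stage, ": no-delivery null, n = ", rc$n_null)
    null_sct <- simulate_celltable(ncfg, n_cells = rc$n_null,
                                   seed = rc$seed + 5000L,
                                   seg_params = rc$seg_params)
    gating <- lapply(res, function(sct)
      gate_positive(.analyzable(sct$cells), ab_col,
                    .analyzable(null_sct$cells), rule = rc$gating_rule))
    for (cond in names(gating))
      say("gate: ", cond, " positive fraction ",
          round(100 * gating[[cond]]$positive_fraction, 1), "%")

    knockdown <- NULL
    separation <- NULL
    if (all(c("targeting", "NC") %in% rc$conditions) &&
        !is.null(target_col)) {
      stage <- "knockdown"
      tt <- res$targeting$cells; nc <- res$NC$cells
      knockdown <- list(
        bulk = estimate_knockdown(tt, nc, target_col, mode = "bulk",
                                  n_boot = rc$n_boot, seed = rc$seed),
        gated = estimate_knockdown(tt, nc, target_col, mode = "gated",
                                   gating = gating$targeting,
                                   n_boot = rc$n_boot, seed = rc$seed))
      for (p in setdiff(rc$percentiles, 100))
        knockdown[[paste0("top", p)]] <-
          estimate_knockdown(tt, nc, target_col, mode = "percentile",
                             ab_channel = ab_col, top_pct = p,
                             n_boot = rc$n_boot, seed = rc$seed)
      say("knockdown: bulk ", round(100 * knockdown$bulk$fraction, 1),
          "%, gated ", round(100 * knockdown$gated$fraction, 1), "%")
      stage <- "separation"
      separation <- separation_curve(tt, nc, feature = target_col,
                                     filter_channel = ab_col,
                                     percentiles = rc$percentiles)
      utils::write.csv(separation,
                       file.path(rc$outdir, "separation_curve.csv"),
                       row.names = FALSE)
    }

    embedding <- NULL
    if (isTRUE(rc$embed)) {
      stage <- "embed"
      pooled <- do.call(rbind, lapply(res, function(s) s$cells))
      feats <- grep("_mean$", names(pooled), value = TRUE)
      pooled <- .analyzable(pooled)
      ok <- stats::complete.cases(pooled[feats])
      perp <- min(30, floor((sum(ok) - 1) / 3) - 1)
      say(stage, ": ", sum(ok), " cells, perplexity ", perp)
      embedding <- tsne_embed(pooled[ok, ], feats, perplexity = perp,
                              seed = rc$seed)
      utils::write.csv(embedding$coordinates,
                       file.path(rc$outdir, "embedding.csv"),
                       row.names = FALSE)
    }
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         " (partial outputs retained in ", rc$outdir, ")", call. = FALSE)
  })

  died_fraction <- vapply(counts, function(x) x$died / x$segmented, 0)
  manifest <- list(
    config_hash = .config_hash(rc$config),
    preset = rc$config$preset, seed = rc$seed, n_cells = rc$n_cells,
    conditions = rc$conditions,
    counts = counts,
    died_fraction = as.list(died_fraction),
    gating = lapply(gating, function(g)
      g[c("threshold", "positive_fraction", "n", "null_source")]),
    knockdown = if (!is.null(knockdown)) lapply(knockdown, function(k)
      list(mode = k$mode, fraction = k$fraction, ci = k$ci,
           n_treated = k$n_treated, n_control = k$n_control)),
    outputs = list.files(rc$outdir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(rc$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: manifest written to ", file.path(rc$outdir, "manifest.json"))
  invisible(list(cells = lapply(res, function(s) s$cells),
                 truth = lapply(res, function(s) s$truth),
                 gating = gating, knockdown = knockdown,
                 separation = separation, embedding = embedding,
                 manifest = manifest, outdir = rc$outdir))
}
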