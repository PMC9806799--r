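# Gating, percentile filtering, knockdown estimation and condition
# comparisons on per-cell feature tables.

#' Gate antibody-positive cells against a null distribution
#'
#' Classifies cells as having received the delivered antibody by
#' thresholding the delivery-marker column against a null sample
#' (typically a no-SLO / no-antibody control). Default rule: the 99th
#' percentile of the null distribution.
#'
#' @param cells CellTable to gate.
#' @param ab_channel column name of the delivery-marker intensity
#'   (e.g. "r1_ab_mean").
#' @param null_cells CellTable providing the null distribution.
#' @param rule list(type = "quantile", q = 0.99) or
#'   list(type = "mean_sd", k = 3).
#' @param null_source free-text provenance of the null recorded in the
#'   result.
#' @return object of class \code{gating_result}: rule, threshold,
#'   per-cell \code{positive} flags, \code{positive_fraction}, n.
#' @export
gate_positive <- function(cells, ab_channel, null_cells,
                          rule = list(type = "quantile", q = 0.99),
                          null_source = "no-delivery control") {
  if (!nrow(cells) || !nrow(null_cells)) stop("empty cell table")
  if (!ab_channel %in% names(cells) || !ab_channel %in% names(null_cells))
    stop("unknown channel column '", ab_channel, "'")
  nullv <- null_cells[[ab_channel]]
  thr <- switch(rule$type,
    quantile = stats::quantile(nullv, rule$q, names = FALSE, type = 7),
    mean_sd = mean(nullv) + rule$k * stats::sd(nullv),
    stop("unknown gating rule type '", rule$type, "'"))
  positive <- cells[[ab_channel]] > thr
  structure(list(rule = rule, threshold = as.numeric(thr),
                 ab_channel = ab_channel, positive = positive,
                 positive_fraction = mean(positive), n = nrow(cells),
                 null_source = null_source, n_null = nrow(null_cells)),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat("<gating_result> ", x$ab_channel, " > ", signif(x$threshold, 5),
      " (", x$rule$type, "): ", round(100 * x$positive_fraction, 1),
      "% positive of ", x$n, " cells\n", sep = "")
  invisible(x)
}

#' Keep the cells in the top delivery percentile
#'
#' Restricts a CellTable to rows whose channel value is at or above the
#' (100 - top_pct) percentile, computed within each condition, mirroring
#' filtering by the fluorescence of the introduced antibody. Ties are
#' included, so the subset may slightly exceed the nominal fraction.
#'
#' @param cells CellTable with a \code{condition} column (a missing
#'   condition column is treated as a single condition).
#' @param channel column name to filter on.
#' @param top_pct percentage in (0, 100].
#' @return the filtered CellTable.
#' @export
top_percentile_filter <- function(cells, channel, top_pct) {
  if (!is.numeric(top_pct) || top_pct <= 0 || top_pct > 100)
    stop("top_pct must be in (0, 100]")
  if (!channel %in% names(cells))
    stop("unknown channel column '", channel, "'")
  if (top_pct == 100) return(cells)
  cond <- if ("condition" %in% names(cells)) cells$condition else
    rep("all", nrow(cells))
  keep <- logical(nrow(cells))
  for (cn in unique(cond)) {
    i <- cond == cn
    thr <- stats::quantile(cells[[channel]][i], 1 - top_pct / 100,
                           names = FALSE, type = 7)
    keep[i] <- cells[[channel]][i] >= thr
  }
  cells[keep, , drop = FALSE]
}

# Rows usable for statistics: drop border / registration-invalid / died.
.analyzable <- function(cells) {
  keep <- rep(TRUE, nrow(cells))
  for (fl in c("border", "invalid", "died"))
    if (fl %in% names(cells)) keep <- keep & !cells[[fl]]
  cells[keep, , drop = FALSE]
}

#' Estimate the Trim-Away knockdown fraction
#'
#' Degradation fraction \code{1 - mean(target | treated) / mean(target |
#' control)} with a nonparametric bootstrap CI over cells. Subsets per
#' mode: \code{bulk} = all analyzable cells (the western-blot-equivalent
#' readout), \code{gated} = delivery-positive cells only (requires a
#' \code{gating} threshold), \code{percentile} = cells in the top
#' \code{top_pct} by \code{ab_channel}. The default estimator is the ratio
#' of means (matching densitometry aggregation); \code{median_ratio}
#' (1 - median/median) is exposed as a robust alternative.
#'
#' @param treated,control CellTables for the targeting and NC conditions.
#' @param target_channel column name of the target-protein intensity.
#' @param mode "bulk", "gated" or "percentile".
#' @param gating a \code{gating_result} (for mode "gated").
#' @param ab_channel delivery-marker column (modes "gated"/"percentile").
#' @param top_pct top percentile (mode "percentile").
#' @param estimator "ratio_of_means" or "median_ratio".
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @param conf CI level.
#' @return object of class \code{knockdown_estimate}: mode, fraction,
#'   ci, n_treated, n_control, channel, estimator.
#' @export
estimate_knockdown <- function(treated, control, target_channel,
                               mode = c("bulk", "gated", "percentile"),
                               gating = NULL, ab_channel = NULL,
                               top_pct = NULL,
                               estimator = c("ratio_of_means",
                                             "median_ratio"),
                               n_boot = 1000, seed = 1, conf = 0.95) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  if (!target_channel %in% names(treated) ||
      !target_channel %in% names(control))
    stop("unknown channel column '", target_channel, "'")
  treated <- .analyzable(treated)
  control <- .analyzable(control)
  subset_tab <- function(tab) {
    if (mode == "bulk") return(tab)
    if (mode == "gated") {
      if (is.null(gating) || !inherits(gating, "gating_result"))
        stop("mode 'gated' requires a gating_result")
      ch <- if (is.null(ab_channel)) gating$ab_channel else ab_channel
      return(tab[tab[[ch]] > gating$threshold, , drop = FALSE])
    }
    if (is.null(ab_channel) || is.null(top_pct))
      stop("mode 'percentile' requires ab_channel and top_pct")
    top_percentile_filter(tab, ab_channel, top_pct)
  }
  tt <- subset_tab(treated)
  cc <- subset_tab(control)
  if (!nrow(tt)) stop("empty treated subset in mode '", mode, "'")
  if (!nrow(cc)) stop("empty control subset in mode '", mode, "'")
  est <- function(tv, cv) {
    if (estimator == "ratio_of_means") {
      mc <- mean(cv)
      if (mc <= 0) stop("control mean <= 0; knockdown undefined")
      1 - mean(tv) / mc
    } else {
      mc <- stats::median(cv)
      if (mc <= 0) stop("control median <= 0; knockdown undefined")
      1 - stats::median(tv) / mc
    }
  }
  tv <- tt[[target_channel]]; cv <- cc[[target_channel]]
  fraction <- est(tv, cv)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(i)
      est(tv[sample.int(length(tv), replace = TRUE)],
          cv[sample.int(length(cv), replace = TRUE)]), 0)
    a <- (1 - conf) / 2
    ci <- stats::quantile(bs, c(a, 1 - a), names = FALSE)
  }
  structure(list(mode = mode, fraction = fraction, ci = ci, conf = conf,
                 n_treated = nrow(tt), n_control = nrow(cc),
                 channel = target_channel, estimator = estimator,
                 top_pct = top_pct, n_boot = n_boot),
            class = "knockdown_estimate")
}

#' @export
print.knockdown_estimate <- function(x, ...) {
  cat("<knockdown_estimate> ", x$mode,
      if (!is.null(x$top_pct)) paste0(" (top ", x$top_pct, "%)"),
      ": ", round(100 * x$fraction, 1), "%",
      if (all(is.finite(x$ci)))
        paste0(" [", round(100 * x$ci[1], 1), ", ",
               round(100 * x$ci[2], 1), "]"),
      "  n = ", x$n_treated, "/", x$n_control, "\n", sep = "")
  invisible(x)
}

#' Add per-cell intensity-ratio features
#'
#' Per-cell ratio of mean intensities (e.g. pAkt/Akt, pS6rp/S6rp).
#' Non-positive denominators give NA and are flagged.
#'
#' @param cells CellTable.
#' @param pairs list of c(numerator, denominator) column-name pairs.
#' @return the CellTable with added \code{ratio_<num>_over_<den>} columns.
#' @export
ratio_features <- function(cells, pairs) {
  for (p in pairs) {
    if (!all(p %in% names(cells)))
      stop("unknown channel column(s): ",
           paste(setdiff(p, names(cells)), collapse = ", "))
    den <- cells[[p[2]]]
    v <- ifelse(den > 0, cells[[p[1]]] / den, NA_real_)
    nm <- paste0("ratio_", p[1], "_over_", p[2])
    cells[[nm]] <- v
    cells[[paste0(nm, "_undefined")]] <- den <= 0
  }
  cells
}

#' Condition separation as a function of delivery filtering
#'
#' For each top-percentile level of the delivery marker, computes a
#' standardized separation between conditions on the feature: the absolute
#' standardized mean difference \code{|m1 - m2| / sqrt((s1^2 + s2^2)/2)}
#' (default) or the two-sample Kolmogorov-Smirnov statistic. Mirrors the
#' observation that condition differences sharpen as analysis narrows to
#' the most efficiently resealed cells.
#'
#' @param treated,control CellTables.
#' @param feature feature column to compare.
#' @param filter_channel delivery-marker column used for the percentile
#'   filtering (defaults to \code{feature}).
#' @param percentiles top-percentile levels (at least 2).
#' @param method "smd" or "ks".
#' @param min_n subsets smaller than this are marked unreliable.
#' @return data.frame(percentile, effect, n_treated, n_control, reliable).
#' @export
separation_curve <- function(treated, control, feature,
                             filter_channel = feature,
                             percentiles = c(100, 50, 25, 10, 5),
                             method = c("smd", "ks"), min_n = 20) {
  method <- match.arg(method)
  if (length(percentiles) < 2) stop("need at least 2 percentile levels")
  treated <- .analyzable(treated); control <- .analyzable(control)
  out <- lapply(percentiles, function(p) {
    tt <- top_percentile_filter(treated, filter_channel, p)[[feature]]
    cc <- top_percentile_filter(control, filter_channel, p)[[feature]]
    tt <- tt[is.finite(tt)]; cc <- cc[is.finite(cc)]
    eff <- if (length(tt) >= 2 && length(cc) >= 2) {
      if (method == "smd") {
        sp <- sqrt((stats::var(tt) + stats::var(cc)) / 2)
        if (sp > 0) abs(mean(tt) - mean(cc)) / sp else 0
      } else {
        suppressWarnings(
          as.numeric(stats::ks.test(tt, cc)$statistic))
      }
    } else NA_real_
    data.frame(percentile = p, effect = eff, n_treated = length(tt),
               n_control = length(cc),
               reliable = length(tt) >= min_n && length(cc) >= min_n)
  })
  do.call(rbind, out)
}

#' Welch's t-test between two conditions
#'
#' Two-sided Welch's unequal-variance t-test; returns statistics, not
#' verdicts.
#'
#' @param values_a,values_b numeric samples (each n >= 2, nonzero
#'   variance in at least one).
#' @return list(statistic, df, p_value, mean_a, mean_b, method).
#' @export
compare_conditions <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each sample needs n >= 2 finite values")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(statistic = 0, df = length(values_a) +
                    length(values_b) - 2, p_value = 1,
                  mean_a = mean(values_a), mean_b = mean(values_b),
                  method = "welch"))
    stop("degenerate samples: both have zero variance")
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(statistic = as.numeric(tt$statistic),
       df = as.numeric(tt$parameter),
       p_value = tt$p.value,
       mean_a = mean(values_a), mean_b = mean(values_b),
       method = "welch")
}

#' Many-to-one comparisons against a reference condition
#'
#' Per-group Welch's t-tests against the reference with Holm family-wise
#' adjustment, an approximation of the classic many-to-one (Dunnett-style)
#' comparison.
#'
#' @param groups named list of numeric samples.
#' @param reference numeric reference sample.
#' @return data.frame(group, statistic, df, p_value, p_adjusted).
#' @export
compare_many_to_one <- function(groups, reference) {
  if (!length(groups)) stop("no groups to compare")
  res <- lapply(names(groups), function(g) {
    w <- compare_conditions(groups[[g]], reference)
    data.frame(group = g, statistic = w$statistic, df = w$df,
               p_value = w$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  out
}
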