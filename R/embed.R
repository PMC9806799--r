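# Multivariate exploration of the per-cell feature table.

#' Pairwise feature summary
#'
#' Symmetric Pearson correlation matrix over the requested features plus
#' per-feature, per-condition histogram bins on a common break grid — the
#' numeric content of a pairwise-plot panel. Zero-variance features get NA
#' correlations and are listed in the \code{flagged} element.
#'
#' @param cells CellTable.
#' @param features character vector of >= 2 feature column names.
#' @param bins number of histogram bins.
#' @return list(correlations, histograms, flagged).
#' @export
pairwise_summary <- function(cells, features, bins = 30) {
  if (length(features) < 2) stop("need at least 2 features")
  if (nrow(cells) < 3) stop("need at least 3 cells")
  miss <- setdiff(features, names(cells))
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(cells[features])
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  flagged <- features[!is.na(sds) & sds == 0]
  cm <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  cm[flagged, ] <- NA; cm[, flagged] <- NA
  diag(cm) <- ifelse(features %in% flagged, NA, 1)
  cond <- if ("condition" %in% names(cells)) cells$condition else
    rep("all", nrow(cells))
  histograms <- lapply(features, function(f) {
    v <- cells[[f]]; v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    breaks <- seq(min(v), max(v), length.out = bins + 1)
    if (breaks[1] == breaks[bins + 1])
      breaks <- breaks[1] + seq(-0.5, 0.5, length.out = bins + 1)
    per_cond <- lapply(split(cells[[f]], cond), function(x) {
      x <- x[is.finite(x)]
      h <- graphics::hist(pmin(pmax(x, breaks[1]), breaks[bins + 1]),
                          breaks = breaks, plot = FALSE)
      h$counts
    })
    list(breaks = breaks, counts = per_cond)
  })
  names(histograms) <- features
  list(correlations = cm, histograms = histograms, flagged = flagged)
}

#' t-SNE embedding of per-cell features
#'
#' Features are z-scored over the pooled table, then embedded in 2D with
#' Barnes-Hut t-SNE (Rtsne). Deterministic given the seed and parameters.
#' Coordinates are for visualization / QC; no quantitative inference is
#' attached to the embedding geometry.
#'
#' @param cells CellTable (rows with non-finite feature values are
#'   rejected; complete cases are required).
#' @param features feature column names.
#' @param perplexity t-SNE perplexity; requires n > 3 * perplexity.
#' @param seed RNG seed.
#' @param max_iter gradient-descent iterations.
#' @return object of class \code{embedding_result}: \code{coordinates}
#'   (data.frame cell_id, x, y, order preserved), \code{params},
#'   \code{features}.
#' @export
tsne_embed <- function(cells, features, perplexity = 30, seed = 0,
                       max_iter = 500) {
  miss <- setdiff(features, names(cells))
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(cells[features])
  if (any(!is.finite(X)))
    stop(sum(!stats::complete.cases(X)),
         " cell(s) with non-finite feature values; drop them first")
  n <- nrow(X)
  if (n <= 3 * perplexity)
    stop("too few cells for perplexity ", perplexity,
         ": need n > ", 3 * perplexity)
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  set.seed(seed)
  fit <- Rtsne::Rtsne(Xs, dims = 2, perplexity = perplexity,
                      theta = 0.5, max_iter = max_iter,
                      check_duplicates = FALSE, pca = FALSE,
                      verbose = FALSE)
  ids <- if ("cell_id" %in% names(cells)) cells$cell_id else seq_len(n)
  structure(list(
    coordinates = data.frame(cell_id = ids, x = fit$Y[, 1], y = fit$Y[, 2]),
    params = list(perplexity = perplexity, seed = seed,
                  max_iter = max_iter, scaling = "z-score (pooled)"),
    features = features), class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("<embedding_result> ", nrow(x$coordinates), " cells, features: ",
      paste(x$features, collapse = ", "), " (perplexity ",
      x$params$perplexity, ", seed ", x$params$seed, ")\n", sep = "")
  invisible(x)
}
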