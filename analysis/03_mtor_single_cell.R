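#!/usr/bin/env Rscript
# Single-cell cyclic-immunofluorescence analysis of mTOR Trim-Away:
# three staining rounds (antibody + S6 / pS6 + mTOR / Akt + pAkt),
# registration, per-cell quantification, gated vs bulk knockdown,
# pairwise correlations, delivery-percentile filtering and a t-SNE map.
#
# Outputs: results/mtor_cells.csv, results/mtor_separation.csv,
# results/mtor_embedding.csv, results/mtor_summary.json and (if ggplot2
# is installed) results/mtor_tsne.pdf.

suppressPackageStartupMessages(library(trimcycif))

seed <- 303L
rc <- run_config(preset = "mTOR-12h", n_cells = 2000, seed = seed,
                 outdir = file.path("results", "mtor_run"),
                 embed = TRUE, n_boot = 500)
res <- run_pipeline(rc)

dir.create("results", showWarnings = FALSE)
cells <- rbind(res$cells$targeting, res$cells$NC)
cells <- ratio_features(cells, list(c("r3_pAkt_mean", "r3_Akt_mean"),
                                    c("r2_pS6_mean", "r1_S6_mean")))
write_cell_table(cells, "results/mtor_cells.csv")
write.csv(res$separation, "results/mtor_separation.csv", row.names = FALSE)

feats <- c("r2_target_mean", "r3_pAkt_mean", "r3_Akt_mean",
           "r2_pS6_mean", "r1_S6_mean", "r1_ab_mean")
ps <- pairwise_summary(cells[cells$condition == "targeting" &
                               !cells$died, ], feats)
message("\nPairwise correlations (targeting condition):")
print(round(ps$correlations, 2))
message("Antibody load vs remaining mTOR: r = ",
        round(ps$correlations["r1_ab_mean", "r2_target_mean"], 3),
        " (negative: better-delivered cells degrade more target)")

if (!is.null(res$embedding))
  write.csv(res$embedding$coordinates, "results/mtor_embedding.csv",
            row.names = FALSE)

summary <- list(
  bulk_knockdown = res$knockdown$bulk$fraction,
  gated_knockdown = res$knockdown$gated$fraction,
  top5_knockdown = res$knockdown$top5$fraction,
  ab_target_correlation =
    ps$correlations["r1_ab_mean", "r2_target_mean"],
  separation = res$separation)
jsonlite::write_json(summary, "results/mtor_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

message("\nKnockdown: bulk ", round(100 * res$knockdown$bulk$fraction, 1),
        "%, delivery-gated ",
        round(100 * res$knockdown$gated$fraction, 1),
        "%, top-5% delivered ",
        round(100 * res$knockdown$top5$fraction, 1), "%")
message("Separation (|SMD| of mTOR intensity) grows as analysis narrows ",
        "to the best-delivered cells:")
print(res$separation, row.names = FALSE, digits = 3)

if (requireNamespace("ggplot2", quietly = TRUE) &&
    !is.null(res$embedding)) {
  em <- res$embedding$coordinates
  em$condition <- cells$condition[match(em$cell_id, cells$cell_id)]
  p <- ggplot2::ggplot(em, ggplot2::aes(x, y, color = condition)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(title = "t-SNE of per-cell cyclic-IF features",
                  x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
  ggplot2::ggsave("results/mtor_tsne.pdf", p, width = 5, height = 4)
  message("t-SNE map written to results/mtor_tsne.pdf")
}
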