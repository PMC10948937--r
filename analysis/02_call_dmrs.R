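# Call DMRs on both platforms for every tumor-pair comparison, filter the
# array calls by the tumor-vs-control comparisons, and extract the
# cancer-specific hyper/hypomethylated region sets. Findings go to
# results/ as TSV/BED-style tables.
source("analysis/00_config.R")

study <- simulate_study(study_cfg)
res <- suppressWarnings(run_study(study))

for (nm in names(res$tile_dmrs)) {
  write_tsv(gr_df(res$tile_dmrs[[nm]]$regions),
            sprintf("dmrs_tiles_%s.tsv", nm))
  write_tsv(gr_df(res$probe_filtered[[nm]]$regions),
            sprintf("dmrs_array_filtered_%s.tsv", nm))
}
write_tsv(res$fourfield, "cancer_specific_fourfield.tsv")

ff <- res$fourfield
message("hyper/hypo balance per cancer (array):")
for (cn in unique(ff$cancer)) {
  sub <- ff[ff$cancer == cn & ff$platform == "array", ]
  message(sprintf("  %s: %d hyper (%.0f%%), %d hypo", cn,
                  sub$n[sub$direction == "hyper"],
                  sub$pct[sub$direction == "hyper"],
                  sub$n[sub$direction == "hypo"]))
}

ev <- evaluate_recovery(study, res)
message(sprintf("planted-tile recovery: sensitivity %.3f, FDR %.3f (n = %d)",
                ev$tile_sensitivity, ev$tile_fdr, ev$n_tile_truth))

# DMR pool clustering: median methylation per cluster and sample group
if (!is.null(res$clustering)) {
  write_tsv(res$clustering$aic_curve, "kmeans_aic_curve.tsv")
  message(sprintf("k-means over the pooled DMRs: chosen k = %d",
                  res$clustering$chosen_k))
}
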