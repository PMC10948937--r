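# TF binding-site enrichment of the cancer-specific region sets on both
# platforms, cross-platform validation, the categorized-catalog variant
# and pairwise co-localization of the validated TFs.
source("analysis/00_config.R")

study <- simulate_study(study_cfg)
res <- suppressWarnings(run_study(study))

for (cls in names(res$enrich_array)) {
  if (!is.null(res$enrich_array[[cls]]))
    write_tsv(res$enrich_array[[cls]], sprintf("tf_enrichment_array_%s.tsv", cls))
  if (!is.null(res$enrich_tiles[[cls]]))
    write_tsv(res$enrich_tiles[[cls]], sprintf("tf_enrichment_tiles_%s.tsv", cls))
}
validated <- res$validated_tfs
for (cls in names(validated))
  message(sprintf("validated TFs in %s: %s", cls,
                  paste(validated[[cls]], collapse = ", ")))
write_tsv(data.frame(class = rep(names(validated),
                                 lengths(validated)),
                     tf = unlist(validated)), "tf_validated.tsv")
write_tsv(res$categorized, "tf_enrichment_categorized_ATRT_hyper.tsv")

# co-localization of the validated AT/RT-hyper TFs in their target regions
tfs <- validated$ATRT_hyper
if (length(tfs) >= 2) {
  cm <- colocalization_matrix(tfs, res$specific$ATRT$array$hyper,
                              study$catalog)
  write_tsv(cbind(tf = rownames(cm$adj_p), as.data.frame(cm$adj_p)),
            "tf_colocalization_adjp.tsv")
}

# methylation around the top validated TF's binding sites
if (length(tfs) >= 1) {
  bm <- binding_site_methylation(study$probe_se, study$catalog, tfs[1])
  agg <- aggregate(beta ~ group, bm, mean)
  write_tsv(agg, sprintf("tf_site_methylation_%s.tsv", tfs[1]))
  message(sprintf("mean beta near %s sites: %s", tfs[1],
                  paste(sprintf("%s=%.2f", agg$group, agg$beta),
                        collapse = ", ")))
}
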