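# Situate the AT/RT-specific regions relative to PSC and fetal-brain
# methylomes: reference DMRs, the membership matrix and the developmental
# categories, checked against the planted labels.
source("analysis/00_config.R")

study <- simulate_study(study_cfg)
res <- suppressWarnings(run_study(study))

stopifnot(!is.null(res$develop))
tab <- cbind(gr_df(res$develop$atoms), res$develop$flags,
             category = res$develop$category)
write_tsv(tab, "developmental_matrix_ATRT.tsv")
write_tsv(as.data.frame(table(category = res$develop$category)),
          "developmental_category_counts.tsv")

ev <- evaluate_recovery(study, res)
message(sprintf("category labels agree with the planted truth for %.0f%% of %d regions",
                100 * ev$category_agreement, ev$n_category_regions))
print(table(res$develop$category))
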