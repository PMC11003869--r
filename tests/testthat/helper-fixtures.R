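# Shared fixtures, built in code at test time.

# Small titration experiment with planted truth, CLR assay attached.
small_titration <- function(n_per = 300, seed = 11, n_adts = 20,
                            n_clusters = 4) {
  cfg <- titrationConfig(n_cells_per_concentration = n_per,
                         n_adts = n_adts, n_clusters = n_clusters,
                         seed = seed)
  clrTransform(simulateTitration(cfg))
}

# Strip doublets/QC failures the way the pipeline does.
filtered_titration <- function(te) {
  keep <- applyQC(te) & demuxCalls(callHashes(te))$call == "singlet"
  te[, keep]
}

truth_df <- function(te) as.data.frame(adtTruth(te))
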