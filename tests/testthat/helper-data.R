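# Shared synthetic datasets, generated once per test run and cached.
# Sizes: 32 patients x 10 beats (separated) and 40 x 10 (overlap-heavy)
# keep the full-pipeline checks statistically meaningful while the whole
# suite stays fast.

.pv_test_cache <- new.env(parent = emptyenv())

cached_feature_table <- function(difficulty,
                                 n_patients = if (difficulty == "separated") 32 else 40,
                                 beats_per_patient = 10, seed = 2024) {
  key <- paste(difficulty, n_patients, beats_per_patient, seed, sep = "_")
  if (is.null(.pv_test_cache[[key]])) {
    d <- file.path(tempdir(), paste0("pvds_", key))
    generate_dataset(d, n_patients = n_patients,
                     beats_per_patient = beats_per_patient,
                     difficulty = difficulty, seed = seed)
    ds <- load_dataset(d)
    .pv_test_cache[[key]] <- extract_feature_table(ds$recordings, ds$beats)
  }
  .pv_test_cache[[key]]
}
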