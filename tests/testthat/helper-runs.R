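# One shared end-to-end run of the synthetic study design, computed lazily
# and reused by the pipeline and acceptance tests (the culture + field
# analysis is the expensive part of the suite).

.run_cache <- new.env(parent = emptyenv())

study_config <- function() {
  if (is.null(.run_cache$cfg)) {
    .run_cache$cfg <- synth_config(n_events = 1200, seed = 1)
  }
  .run_cache$cfg
}

study_culture_run <- function() {
  if (is.null(.run_cache$cul)) {
    .run_cache$cul <- suppressMessages(run_culture_analysis(study_config()))
  }
  .run_cache$cul
}

study_field_run <- function() {
  if (is.null(.run_cache$fld)) {
    .run_cache$fld <- suppressMessages(
      run_field_assessment(study_culture_run(), study_config()))
  }
  .run_cache$fld
}
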