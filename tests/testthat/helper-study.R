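# The desk-scale reproduction study is expensive (several minutes), so the
# acceptance tests share one run, computed on first use.
study_cache <- new.env()

cached_study <- function() {
  if (is.null(study_cache$study))
    study_cache$study <- mwi_study(seed = 2026)
  study_cache$study
}

cached_localization <- function() {
  if (is.null(study_cache$loc))
    study_cache$loc <- mwi_localization_study(seed = 2027)
  study_cache$loc
}
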