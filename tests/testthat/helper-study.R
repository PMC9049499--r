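# The 5-seed ablation study is used by two acceptance properties (variant
# ordering and fusion-weight concentration); run it once and cache.
.study_cache <- new.env(parent = emptyenv())

cached_ablation_study <- function() {
  if (is.null(.study_cache$res)) {
    .study_cache$res <- ablation_study(seeds = 1:5)
  }
  .study_cache$res
}
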