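.onLoad <- function(libname, pkgname) {
  # shipped deterministic mocks standing in for the masked-language-model
  # ensemble; real transformer scorers are adapters with the same contract
  register_scorer("overlap_query", make_overlap_scorer("query"))
  register_scorer("overlap_question", make_overlap_scorer("question"))
  register_scorer("overlap_narrative", make_overlap_scorer("narrative"))
  invisible()
}
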