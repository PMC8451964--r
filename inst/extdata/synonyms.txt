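# Query-expansion synonym groups: one comma-separated group per line.
# Terms are normalized (lower-case, Porter-stemmed) before lookup, so
# surface variants that share a stem need not be listed.
covid-19, sars-cov-2, coronavirus, 2019-ncov, ncov
sars, sars-cov
mers, mers-cov
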