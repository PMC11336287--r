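# Regenerates the packaged example data. Run from the package root:
#   Rscript tools/make_fixtures.R
library(wwtpopt)
write_influent_csv(generate_synthetic_influent(days = 5, seed = 101),
                   "inst/extdata/influent_5d.csv")
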