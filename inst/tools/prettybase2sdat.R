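#!/usr/bin/env Rscript
# contract: <Rscript> prettybase2sdat.R <PrettyBase-in> <SDAT-out>
a <- commandArgs(TRUE)
if (length(a) != 2) stop("usage: prettybase2sdat.R <input> <output>")
pipegraph::prettybase_to_sdat(a[1], a[2])
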