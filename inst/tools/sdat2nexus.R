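#!/usr/bin/env Rscript
# contract: <Rscript> sdat2nexus.R <SDAT-in> <NEXUS-out>
a <- commandArgs(TRUE)
if (length(a) != 2) stop("usage: sdat2nexus.R <input> <output>")
pipegraph::sdat_to_nexus(a[1], a[2])
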