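#!/usr/bin/env Rscript
# contract: <Rscript> sdat2structure.R <SDAT-in> <Structure-out> <mainparam> <extraparam>
a <- commandArgs(TRUE)
if (length(a) != 4) stop("usage: sdat2structure.R <input> <output> <mainparam> <extraparam>")
pipegraph::sdat_to_structure(a[1], a[2], a[3], a[4])
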