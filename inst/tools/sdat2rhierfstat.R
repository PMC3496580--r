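#!/usr/bin/env Rscript
# contract: <Rscript> sdat2rhierfstat.R <SDAT-in> <SDAT-extra>... <RHierfstat-out>
a <- commandArgs(TRUE)
if (length(a) < 3) stop("usage: sdat2rhierfstat.R <input> <extra>... <output>")
pipegraph::sdat_to_rhierfstat(a[1], a[length(a)], extra_pops = a[-c(1, length(a))])
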