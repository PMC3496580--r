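#!/usr/bin/env Rscript
# contract: <Rscript> nexus2rhierfstat.R <NEXUS-in> <NEXUS-extra>... <RHierfstat-out>
a <- commandArgs(TRUE)
if (length(a) < 2) stop("usage: nexus2rhierfstat.R <input> [extra...] <output>")
pipegraph::nexus_to_rhierfstat(a[1], a[length(a)], extra_pops = a[-c(1, length(a))])
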