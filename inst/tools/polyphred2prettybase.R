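#!/usr/bin/env Rscript
# contract: <Rscript> polyphred2prettybase.R <PolyPhred-in> <PrettyBase-out>
a <- commandArgs(TRUE)
if (length(a) != 2) stop("usage: polyphred2prettybase.R <input> <output>")
pipegraph::polyphred_to_prettybase(a[1], a[2])
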