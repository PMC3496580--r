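#!/usr/bin/env Rscript
# contract: <Rscript> phase2fasta.R <PHASE-out-in> <Fragments> <RefSeq> <Fasta-out>
a <- commandArgs(TRUE)
if (length(a) != 4) stop("usage: phase2fasta.R <input> <fragments> <refseq> <output>")
pipegraph::phase_to_fasta(a[1], a[2], a[3], a[4])
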