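---
title: "Composing format-conversion pipelines over a tool graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composing format-conversion pipelines over a tool graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipegraph)
```

## The model

`pipegraph` treats a collection of command-line conversion tools as a
directed multigraph. Each registry entry
$E_j = (i, o, t, l, c, XI, XO, f, \dots)$ describes one tool: main input
format $i$, main output format $o$, executable $t$, interpreter $l$, unique
integer code $c$, the ordered lists of extra input formats $XI$ and
secondary output formats $XO$, and a performance measure $f$ (mean response
time in seconds). Formats become nodes; each tool becomes one edge
$i \to o$ with weight

$$
w_j = \begin{cases} f_j & \text{criterion \texttt{performance}} \\
                    |XI_j| & \text{criterion \texttt{dependencies}}
      \end{cases}
$$

A pipeline answering a request $(start, end)$ is a path through this graph;
the system selects the path minimising $\sum_j w_j$, i.e. the fastest
pipeline or the one demanding the fewest user-supplied files. Both weights
are non-negative by construction (validated at parse time), which is what
makes Dijkstra's algorithm exact here — including when the dependencies
criterion produces zero-weight edges.

Assumptions worth stating explicitly:

- **Sequential pipelines only.** A path is a chain; the model does not
  express fork/join parallelism.
- **One main input, one main output per tool.** Extra files are side
  channels ($XI$, $XO$), not alternative routes.
- **Format names are exact, case-sensitive strings.** No normalisation is
  attempted; `SDAT` and `sdat` are different formats.
- **Tools are honest about their formats.** The composer never inspects
  file contents; correctness of each conversion is the tool author's
  responsibility.

## Graph construction details

Primary nodes come from tool inputs/outputs; a tool with $i = o$ becomes a
self-loop (legitimate for trimmers/filters that preserve the format).
Every $XI$/$XO$ occurrence then joins the graph as an *auxiliary* node with
a zero-weight edge labelled with the owning tool's code — XI aux node
$\to$ tool's output node, tool's input node $\to$ XO aux node. The
direction convention depicts extra inputs feeding the conversion and
subproducts leaving it; since aux edges are excluded from traversal
(below), the convention affects only bookkeeping and DOT rendering.

When an aux occurrence's format name already names a node, an alias with a
per-name counter is created (`SDAT1`, `SDAT2`, ...), assigned in registry
order, so rebuilding a graph from the same registry file is
bit-deterministic. These aliases also name staged files: the hierfstat
tool's extra population file under run id `02` is `SDAT202` (`SDAT2` +
`02`).

**Aux edges are never traversed as conversions.** A zero-weight edge from
`Fragments` into `Fasta` would otherwise offer a free "conversion" from a
site map to a sequence file, which is meaningless. The required-input and
output lists of a compiled pipeline ($LI$, $LO$) are computed from registry
fields, not by walking aux edges.

## Path search and determinism

`find_path()` is a hand-written Dijkstra over tool edges with a composite
ordering: total weight, then number of edges, then lexicographic order of
the tool-code sequence. The composite order is preserved when the same
edge is appended to two competing paths (weights add equally, lengths add
equally, and appending the same code preserves lexicographic order between
equal-length sequences), so the composite-key Dijkstra is exact, and two
equal-weight alternatives always resolve the same way — a property the
test suite depends on. Parallel edges between the same format pair are
relaxed individually, so the better of two competing tools wins and the
worse one remains available as an alternative.

`find_path_bellman_ford()` implements the same contract by Bellman-Ford
relaxation sweeps; the two must agree everywhere, and the test suite checks
both against an exhaustive enumeration of all simple tool-edge paths and
against `igraph::distances()`. Why hand-written rather than delegated to a
graph library? The deterministic tie-break and multigraph-with-codes
contract *is* the algorithmic core of the package; library routines return
*a* shortest path, not a canonical one, and are therefore used here as
independent cross-checks instead.

Degenerate requests are classed errors rather than guesses: an endpoint
that is not a primary node (`pg_unknown_format`), an unreachable end
(`pg_no_pipeline`), and $start = end$ without a self-loop tool
(`pg_identity_request` — identity is not a conversion; it resolves only
through an explicit same-format tool, the cheapest one when several exist).

## Compilation and execution

`compile_pipeline()` emits one command per step in the fixed contract
`<language> <tool> <input> [xi...] <output> [xo...]`, naming every file
`<FormatLabel><run_id>` so that consecutive commands chain by
construction and concurrent runs with different run ids never collide.
$LI$ is the start file plus each step's XI files in path order; $LO$ is the
end file plus each step's XO files. The three manifests are written as
`pipeline.inputs`, `pipeline.exec` (with a `#!/bin/sh` header: the file is
directly runnable) and `pipeline.outputs`.

`run_pipeline()` validates that every $LI$ file exists before touching
anything, then executes commands sequentially in the working directory,
halting at the first non-zero exit — later steps consume earlier outputs,
so continuing would be meaningless. Each step's standard error is appended
to `pipeline.err` prefixed with the step number and a timestamp. Files
produced before a failure are deliberately left in place for diagnosis.

## Connectivity analytics and the gain convention

`count_conversions()` counts ordered pairs $(s, t)$, $s \neq t$, of
*primary* formats connected by a tool-edge path: the conversions a user can
actually request. Aux nodes and self-pairs are excluded. On the bundled
15-tool catalogue this yields 26 conversions — combination is the point, as
26 exceeds the 15 registered tools.

`gain_analysis()` answers "what do I get if I write a tool
`new_input -> new_output`?" It returns the ordered pairs reachable after
inserting the hypothetical edge that were not reachable before, *excluding
the inserted pair itself*: the direct conversion is the new tool's own
functionality, while the gain measures what graph composition adds on top.
On the bundled catalogue, `formatX -> SDAT` gains 6 composed conversions
(formatX to PrettyBase, PHASEIN, StructureFormat, NEXUS, RHierfstat,
RGenetics) versus 1 for `formatX -> NEXUS` (formatX to RHierfstat). Under
this convention, for a fresh source format,
`count_conversions(after) - count_conversions(before)` equals the gain
*plus one* (the direct pair); the planner tests assert exactly that
relation.

`best_extension()` maximises the gain over candidate target formats (ties
alphabetical). Note that on well-connected catalogues the unrestricted
optimum is often the *source* end of long chains (here a `formatX ->
PolyPhred` tool would gain 7); restricting `candidates` to the formats one
could realistically emit is usually the more meaningful question.

## The bundled registries

`pipegraph_registry("basic")` is a minimal five-tool catalogue
(PolyPhred→PrettyBase→SDAT plus SDAT→Structure, SDAT→hierfstat,
PHASE→FASTA) used throughout the documentation.

`pipegraph_registry("full_synthetic")` is a **synthetic** fifteen-tool
catalogue for the whole conversion suite — a constructed example, not a
published registry, as the filename says. It extends the basic catalogue
with the reverse SDAT→PrettyBase mapping, PHASE-input writers, NEXUS in
and out of the suite, RGenetics and Haploview targets, and a slower
alternative version of one tool (exercising parallel edges). Its
performances are chosen so that the printed scenarios behave sensibly: the
direct SDAT→RHierfstat tool (0.02) beats the two-step route via NEXUS
(0.21 + 0.15 = 0.36), and the PolyPhred→Structure conversion keeps its
three-step path under the performance criterion.

## Converter dialects

The cited programs' own format documentation lives (or lived) with the
programs, so the package pins down one concrete, fully specified dialect
per format; each is close enough to the conventions of the target program
for downstream use while remaining parseable with standard tools:

- **PolyPhred report**: a `BEGIN GENOTYPES` / `END GENOTYPES` section of
  `site sample allele1 allele2` records; anything outside the section is
  ignored.
- **PrettyBase**: one tab-separated `site sample allele1 allele2` line per
  call; missing alleles are `N`.
- **SDAT**: a `Sample` + site-ID header, one row per sample, genotypes
  `X/Y` with missing `N/N` — the suite's central matrix format.
- **Structure input**: two rows per individual, alleles recoded
  A,C,G,T→1..4, missing −9; `mainparam`/`extraparam` declare `NUMINDS` and
  `NUMLOCI` consistent with the data file.
- **hierfstat table**: a `pop` index column (populations in file order)
  plus per-locus two-digit codes $10 a_1 + a_2$ on the same recode,
  smaller allele first, `NA` for missing. At most five populations — the
  cap the underlying tools advertise.
- **PHASE output**: a `BEGIN BESTPAIRS` section with `#id` plus two
  haplotype lines per individual; parenthesised alleles (PHASE's uncertain
  phase marker) are rejected rather than silently accepted.
- **NEXUS**: a standard `DATA` block, one taxon per allele row
  (`NTAX = 2 × samples`, taxa `<sample>_1/_2`), with site IDs preserved in
  a `[sites: ...]` comment that standard readers (e.g.
  `ape::read.nexus.data`, used as this package's reader) skip.
- **FASTA**: via `seqinr`; haplotype reconstruction substitutes phased
  alleles into the reference at the positions given by the `Site`/
  `Position` map ("fragments" file).

Unordered genotypes are always rendered with alleles in A&lt;C&lt;G&lt;T
order, which makes shuffled inputs, duplicate records and the two
SDAT→hierfstat routes (direct vs via NEXUS) produce byte-identical
outputs. Missing data propagates through every conversion; nothing is
imputed. Only diploid data is modelled — the formats themselves are
diploid-centric, and generalised ploidy is out of scope.

## The synthetic-data generator

`generate_genotypes()` emulates the structural shape of re-sequencing
genotype data: biallelic sites with per-site allele pairs drawn from
{A,C,G,T}, strictly increasing positions on a shared reference, uniform
haplotype draws, whole-call missingness at a configurable rate, several
populations sharing one site list, and a reference sequence whose base at
each site is the site's first allele. Defaults (10 samples, 5 sites, no
missingness, one population) are desk-scale on purpose; tests that need
other shapes say so explicitly.

It deliberately does **not** emulate population-genetic realism: no
linkage disequilibrium, no allele-frequency spectrum, no demography, no
genotyping-error model. Passing tests therefore demonstrate structural
correctness of conversions and pipelines (shapes, allele conservation,
dialect validity, route equivalence), not statistical properties of real
data. `random_registry()` similarly generates structurally varied tool
catalogues (parallel edges, self-loops, sporadic XI/XO) for the
shortest-path property tests, with no pretence of resembling a curated
registry.

Every generator takes an explicit seed and restores the session RNG state,
so artifacts are reproducible byte for byte and generation never perturbs
a user's random stream.

## Benchmarking

`benchmark_tool()` measures a tool's response time as the arithmetic mean
of wall-clock seconds over `reps` runs (default 10) of the standard
command contract on a sample input, with scratch names supplied for extra
inputs and outputs. The mean over repeated runs is the simplest statistic
consistent with "mean response time"; users wanting robustness to
scheduler noise can raise `reps` or benchmark on larger inputs. The result
feeds `performance`, hence the performance-criterion edge weights.

## Problem sizes and known limitations

The test suite and the reproduction script run at desk scale by choice:
shortest-path properties are verified exhaustively on 200 random
registries of up to 8 tools over 3–5 formats (about a thousand
start/end pairs, each checked against full path enumeration,
Bellman-Ford and `igraph`), and the three end-to-end scenarios run on
3-sample × 4-site datasets. The algorithms are polynomial and the graphs
in realistic registries are small (tens of nodes), so scale is not the
interesting axis; determinism and correctness are.

Known limitations, all deliberate scope choices: no parallel-step
pipelines; no user-facing choice among alternative paths (the composite
order picks one canonically); no tool parameters beyond files (strings or
thresholds on command lines are not modelled); no remote execution,
scheduling, retries or provenance; converter coverage limited to the
dialects above — the Haploview and RGenetics *formats* appear in the full
catalogue as graph nodes but ship without converter implementations,
exactly like any registry entry whose executable lives outside the
package.
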