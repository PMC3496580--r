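# pipegraph

Graph-based composition of extensible format-conversion pipelines for
population genetics and genetic epidemiology.

## The problem

Analyses in population genetics routinely chain several programs —
polymorphism calling (PolyPhred), haplotype phasing (PHASE), population
structure inference (Structure), F-statistics in R (hierfstat) — whose file
formats are mutually incompatible. Conversion scripts bridge the gaps, but
hard-coding every possible chain of scripts makes a pipeline brittle: each
new tool or format forces a programmer to rewire the system.

`pipegraph` takes the graph view instead. A **tool registry** (a TSV table)
describes each command-line tool: its main input and output format, extra
input files it depends on (XI), secondary outputs it emits (XO), and a mean
response-time performance measure. The registry is compiled on demand into a
**directed multigraph** *G* in which formats are nodes and every tool *j* is
an edge from its input format to its output format carrying a weight
*w<sub>j</sub>*:

- under the *performance* criterion, *w<sub>j</sub>* is the tool's mean
  response time;
- under the *dependencies* criterion, *w<sub>j</sub>* = |XI<sub>j</sub>|,
  the number of extra inputs the user must supply.

XI/XO formats join the graph as zero-weight auxiliary nodes (aliased with a
numerical index, e.g. `SDAT2`, when the name is already taken); they are
bookkeeping only and are never traversed as conversions.

A conversion request (*start*, *end*) becomes a shortest-path problem:
Dijkstra's algorithm (parallel edges compete individually; ties break
deterministically by fewest edges, then smallest code sequence) returns the
tool path *P<sub>start,end</sub>* with the minimal weight sum. The path is
compiled into an executable, function-specific pipeline: the required-input
list *LI* (start file plus every step's XI), one command line per step of
the form

```
<language> <tool> <input> [xi...] <output> [xo...]
```

and the output list *LO* (end file plus every step's XO), materialised as
`pipeline.inputs`, `pipeline.exec` (runnable as a shell file) and
`pipeline.outputs`, plus a `pipeline.err` error log at run time. Adding a
tool is one registry row — no code changes — and connectivity analytics
(`count_conversions()`, `gain_analysis()`, `best_extension()`) quantify how
many ordered format pairs a registry serves and what a prospective new tool
would add.

The package bundles working converters (PolyPhred genotype reports,
PrettyBase, SDAT genotype matrices, Structure input + parameter files,
PHASE best-pairs output, NEXUS, FASTA haplotype reconstruction, hierfstat
tables) so composed pipelines run end to end, and a synthetic-data module
generating diploid genotype datasets and random registries for testing.

## Worked example

```r
library(pipegraph)

reg <- parse_registry(pipegraph_registry("full_synthetic"))
g   <- build_tool_graph(reg, "performance")

p <- find_path(g, "PolyPhred", "StructureFormat")
print(p)
#> <pipeline_path> PolyPhred -> StructureFormat via codes [1, 2, 5], total weight 0.164
#>   PolyPhred -> PrettyBase -> SDAT -> StructureFormat

print(compile_pipeline(p, reg, "01"))
#> <executable_pipeline> run 01: 3 command(s)
#> .inputs:  PolyPhred01
#>   $ perl PolyPhred2PrettyBase.pl PolyPhred01 PrettyBase01
#>   $ perl PrettyBase2SDAT.pl PrettyBase01 SDAT01
#>   $ perl SDAT2Structure.pl SDAT01 StructureFormat01 mainparam01 extraparam01
#> .outputs: StructureFormat01, mainparam01, extraparam01

count_conversions(g)
#> [1] 26
gain_analysis(g, "formatX", "SDAT")
#>      from              to
#> 1 formatX           NEXUS
#> 2 formatX         PHASEIN
#> 3 formatX      PrettyBase
#> 4 formatX       RGenetics
#> 5 formatX      RHierfstat
#> 6 formatX StructureFormat
```

The three-step path converts a PolyPhred genotype report into Structure
input: one file in, three files out (the Structure data file plus the
`mainparam`/`extraparam` settings files the end-line tool emits as
subproducts). The 15-tool catalogue serves 26 ordered format conversions;
a hypothetical `formatX -> SDAT` tool would add 6 composed conversions on
top of its own, against 1 for `formatX -> NEXUS` — so SDAT is the more
valuable target format for a new converter.

The same operations are available from a shell through the installed CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pipegraph.R", package = "pipegraph"))')" \
  compose --registry reg.tsv --start SDAT --end RHierfstat \
  --weight performance --run-id 02 --out rundir/
```

with subcommands `registry` (validate / add / benchmark), `graph build`
(with DOT export), `compose`, `run`, `plan` (count / gain / best) and
`fixtures genotypes`.

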