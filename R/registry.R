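# Tool registry: the tabular catalogue of conversion tools that drives graph
# construction, pipeline compilation and the connectivity analytics.

REGISTRY_REQUIRED_COLS <- c("Input", "Output", "Tool", "Language", "Code",
                            "XI", "XO", "Performance")
REGISTRY_OPTIONAL_COLS <- c("Observations", "Provider", "Contact")

#' Create a single tool-registry entry
#'
#' An entry describes one command-line tool: the main input format it accepts,
#' the main output format it produces, its executable name and interpreter,
#' a unique integer code, its extra input formats (`xi`, "input
#' dependencies"), its secondary output formats (`xo`, "subproducts") and a
#' mean response-time performance measure used as the edge weight under the
#' performance criterion.
#'
#' @param input,output Format names (case-sensitive, non-empty). `input` may
#'   equal `output` for same-format tools (trimmers, filters), which become
#'   self-loop edges in the tool graph.
#' @param tool Executable file name (or path).
#' @param language Interpreter used to invoke the tool (e.g. `"perl"`,
#'   `"Rscript"`); empty string for native binaries.
#' @param code Unique positive integer identifier.
#' @param xi,xo Character vectors of extra-input / secondary-output format
#'   names, in command-line order; may be empty.
#' @param performance Non-negative mean response time (seconds). Non-negative
#'   weights are required for shortest-path correctness.
#' @param observations,provider,contact Free-text metadata.
#' @return An object of class `tool_entry`.
#' @examples
#' tool_entry("PrettyBase", "SDAT", "PrettyBase2SDAT.pl", "perl", 2,
#'            performance = 0.01)
#' @export
tool_entry <- function(input, output, tool, language = "", code,
                       xi = character(), xo = character(), performance = 0,
                       observations = "", provider = "", contact = "") {
  if (!is.character(input) || length(input) != 1L || !nzchar(input) ||
      !is.character(output) || length(output) != 1L || !nzchar(output)) {
    pg_stop("pg_validation_error", "input and output must be non-empty strings")
  }
  code <- as.integer(code)
  if (is.na(code) || code < 1L) {
    pg_stop("pg_validation_error", "code must be a positive integer")
  }
  performance <- as.numeric(performance)
  if (is.na(performance) || performance < 0) {
    pg_stop("pg_validation_error",
            sprintf("performance must be >= 0 (entry code %d)", code))
  }
  structure(list(
    input = input, output = output, tool = tool,
    language = as.character(language), code = code,
    xi = as.character(xi), xo = as.character(xo),
    performance = performance,
    observations = as.character(observations),
    provider = as.character(provider), contact = as.character(contact)
  ), class = "tool_entry")
}

#' @export
print.tool_entry <- function(x, ...) {
  cat(sprintf("<tool_entry %d> %s -> %s  [%s %s]  perf=%g\n",
              x$code, x$input, x$output, x$language, x$tool, x$performance))
  if (length(x$xi)) cat("  xi:", paste(x$xi, collapse = ", "), "\n")
  if (length(x$xo)) cat("  xo:", paste(x$xo, collapse = ", "), "\n")
  invisible(x)
}

new_tool_registry <- function(entries, source_path = NA_character_) {
  reg <- structure(list(entries = entries, source_path = source_path),
                   class = "tool_registry")
  validate_registry(reg)
  reg
}

#' Assemble a tool registry from entries
#'
#' @param ... `tool_entry` objects (or a single list of them). Order is
#'   preserved: iteration order equals file order, which keeps downstream
#'   graphs deterministic.
#' @return A `tool_registry`.
#' @export
tool_registry <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1]]) &&
      !inherits(entries[[1]], "tool_entry")) {
    entries <- entries[[1]]
  }
  new_tool_registry(entries)
}

#' Validate a tool registry
#'
#' Checks code uniqueness, non-negative performances and non-empty format
#' names; called on every parse and construction.
#'
#' @param reg A `tool_registry`.
#' @return `reg`, invisibly.
#' @export
validate_registry <- function(reg) {
  stopifnot(inherits(reg, "tool_registry"))
  codes <- vapply(reg$entries, `[[`, integer(1), "code")
  dup <- unique(codes[duplicated(codes)])
  if (length(dup)) {
    pg_stop("pg_validation_error",
            sprintf("duplicate tool code(s): %s", paste(dup, collapse = ", ")))
  }
  invisible(reg)
}

#' @export
length.tool_registry <- function(x) length(x$entries)

#' @export
print.tool_registry <- function(x, ...) {
  cat(sprintf("<tool_registry> %d entries", length(x)))
  if (!is.na(x$source_path)) cat(" from", x$source_path)
  cat("\n")
  print(as.data.frame(x), right = FALSE)
  invisible(x)
}

#' @export
as.data.frame.tool_registry <- function(x, ...) {
  fmt_list <- function(v) if (length(v)) paste(v, collapse = ",") else "-"
  do.call(rbind, lapply(x$entries, function(e) {
    data.frame(Input = e$input, Output = e$output, Tool = e$tool,
               Language = if (nzchar(e$language)) e$language else "-",
               Code = e$code, XI = fmt_list(e$xi), XO = fmt_list(e$xo),
               Performance = e$performance, Observations = e$observations,
               Provider = e$provider, Contact = e$contact,
               stringsAsFactors = FALSE)
  }))
}

registry_codes <- function(reg) vapply(reg$entries, `[[`, integer(1), "code")

#' Look up a registry entry by code
#'
#' @param reg A `tool_registry`.
#' @param code Integer tool code.
#' @return The matching `tool_entry`.
#' @export
registry_entry <- function(reg, code) {
  idx <- which(registry_codes(reg) == code)
  if (!length(idx)) {
    pg_stop("pg_consistency_error", sprintf("no tool with code %d", code))
  }
  reg$entries[[idx[1]]]
}

parse_format_list <- function(s) {
  s <- trimws(s)
  if (is.na(s) || !nzchar(s) || s == "-") return(character())
  v <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  v[nzchar(v)]
}

#' Parse a tool registry from a TSV file
#'
#' The on-disk format is tab-separated with header columns `Input`, `Output`,
#' `Tool`, `Language`, `Code`, `XI`, `XO`, `Performance` and optional
#' `Observations`, `Provider`, `Contact`. `XI`/`XO` are comma-separated
#' format-name lists with `-` denoting the empty list; `-` (or empty) in
#' `Language` denotes a native binary.
#'
#' @param path Path to the TSV file.
#' @return A `tool_registry` whose entry order equals file order.
#' @examples
#' reg <- parse_registry(pipegraph_registry("basic"))
#' length(reg)
#' @export
parse_registry <- function(path) {
  if (!file.exists(path)) {
    pg_stop("pg_io_error", sprintf("registry file not found: %s", path))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", strip.white = TRUE,
                          blank.lines.skip = TRUE)
  missing <- setdiff(REGISTRY_REQUIRED_COLS, names(df))
  if (length(missing)) {
    pg_stop("pg_schema_error",
            sprintf("registry is missing required column(s): %s",
                    paste(missing, collapse = ", ")))
  }
  for (col in REGISTRY_OPTIONAL_COLS) {
    if (is.null(df[[col]])) df[[col]] <- rep("", nrow(df))
  }
  entries <- lapply(seq_len(nrow(df)), function(i) {
    perf <- suppressWarnings(as.numeric(df$Performance[i]))
    if (is.na(perf)) {
      pg_stop("pg_validation_error",
              sprintf("row %d: Performance '%s' is not a number",
                      i, df$Performance[i]))
    }
    lang <- trimws(df$Language[i])
    if (lang == "-") lang <- ""
    tool_entry(
      input = trimws(df$Input[i]), output = trimws(df$Output[i]),
      tool = trimws(df$Tool[i]), language = lang,
      code = suppressWarnings(as.integer(df$Code[i])),
      xi = parse_format_list(df$XI[i]), xo = parse_format_list(df$XO[i]),
      performance = perf, observations = df$Observations[i],
      provider = df$Provider[i], contact = df$Contact[i]
    )
  })
  new_tool_registry(entries, source_path = path)
}

#' Write a tool registry to a TSV file
#'
#' Inverse of [parse_registry()]: `parse_registry(write_registry(reg, f))`
#' reproduces `reg` field for field. Empty `xi`/`xo` lists and empty
#' interpreter names serialise as `-`.
#'
#' @param reg A `tool_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(reg, path) {
  validate_registry(reg)
  df <- if (length(reg)) as.data.frame(reg) else
    stats::setNames(as.data.frame(matrix(character(), ncol = 11)),
                    c(REGISTRY_REQUIRED_COLS, REGISTRY_OPTIONAL_COLS))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) pg_stop("pg_io_error", sprintf("cannot write registry to %s", path))
  invisible(path)
}

#' Register a new tool
#'
#' Appends an entry to the registry without touching any existing entry: this
#' is the whole extension mechanism — no code change is needed for the new
#' tool to participate in composed pipelines, because the tool graph is
#' rebuilt from the registry on demand.
#'
#' @param reg A `tool_registry`.
#' @param entry A `tool_entry` whose code is not yet present.
#' @return The extended `tool_registry`.
#' @export
add_tool <- function(reg, entry) {
  stopifnot(inherits(reg, "tool_registry"), inherits(entry, "tool_entry"))
  if (entry$code %in% registry_codes(reg)) {
    pg_stop("pg_validation_error",
            sprintf("code %d already present in registry", entry$code))
  }
  new_tool_registry(c(reg$entries, list(entry)), source_path = reg$source_path)
}

#' Benchmark a tool's response time
#'
#' Runs the tool `reps` times on a sample input through its standard
#' command-line contract (`<language> <tool> <input> [xi...] <output> [xo...]`,
#' with scratch file names supplied for the extra inputs and outputs) and
#' returns the arithmetic-mean wall-clock time in seconds. The result is the
#' performance measure stored in the registry and used as the edge weight
#' under the performance criterion.
#'
#' @param entry A `tool_entry`.
#' @param sample_input Path to an input file in the tool's input format.
#' @param reps Number of repetitions (default 10).
#' @param xi_files Optional paths for the tool's extra inputs (defaults to
#'   copies of `sample_input`, which suits same-matrix tools; supply real
#'   files otherwise).
#' @return Mean wall-clock response time (seconds, `>= 0`).
#' @export
benchmark_tool <- function(entry, sample_input, reps = 10, xi_files = NULL) {
  stopifnot(inherits(entry, "tool_entry"))
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1) {
    pg_stop("pg_validation_error", "reps must be >= 1")
  }
  if (!file.exists(sample_input)) {
    pg_stop("pg_io_error", sprintf("sample input not found: %s", sample_input))
  }
  work <- tempfile("pgbench")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE), add = TRUE)
  if (is.null(xi_files)) {
    xi_files <- vapply(seq_along(entry$xi), function(k) {
      f <- file.path(work, paste0("xi", k))
      file.copy(sample_input, f)
      f
    }, character(1))
  }
  out_files <- file.path(work, paste0("out", seq_len(1L + length(entry$xo))))
  argv <- c(entry$tool, sample_input, xi_files, out_files)
  cmd <- if (nzchar(entry$language)) entry$language else argv[1]
  args <- if (nzchar(entry$language)) argv else argv[-1]
  times <- vapply(seq_len(reps), function(r) {
    t0 <- proc.time()[["elapsed"]]
    status <- suppressWarnings(
      system2(cmd, shQuote(args), stdout = FALSE, stderr = TRUE)
    )
    elapsed <- proc.time()[["elapsed"]] - t0
    if (is.character(status)) status <- attr(status, "status") %||% 0L
    if (!identical(as.integer(status), 0L) && !is.null(status)) {
      pg_stop("pg_benchmark_error",
              sprintf("tool %s exited with status %s", entry$tool,
                      as.character(status)),
              diagnostics = status)
    }
    elapsed
  }, numeric(1))
  max(mean(times), 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paths to the bundled example registries
#'
#' Two registries ship with the package: `"basic"`, a minimal five-tool
#' catalogue for the population-genetics conversion suite, and
#' `"full_synthetic"`, a synthetic fifteen-tool catalogue covering the whole
#' suite (PolyPhred, PrettyBase, SDAT, Structure, PHASE, NEXUS, FASTA,
#' Haploview, hierfstat and RGenetics formats). The full catalogue is
#' synthetic: a constructed example registry, not a published one.
#'
#' @param which `"basic"` or `"full_synthetic"`.
#' @return Path to the installed TSV file.
#' @export
pipegraph_registry <- function(which = c("basic", "full_synthetic")) {
  which <- match.arg(which)
  fn <- switch(which, basic = "registry_basic.tsv",
               full_synthetic = "registry_full_synthetic.tsv")
  system.file("extdata", fn, package = "pipegraph", mustWork = TRUE)
}
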