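# Composer: shortest-path search over the tool graph and compilation of the
# winning tool path into an executable, function-specific pipeline
# (.inputs / .exec / .outputs).

# Composite path order used for deterministic results: total weight first,
# then number of edges, then lexicographic order of the code sequence.
# The order is preserved under appending the same edge to both paths, so
# Dijkstra remains exact with it.
path_key_less <- function(d1, n1, c1, d2, n2, c2) {
  if (d1 != d2) return(d1 < d2)
  if (n1 != n2) return(n1 < n2)
  if (length(c1) && length(c2)) {
    for (k in seq_len(min(length(c1), length(c2)))) {
      if (c1[k] != c2[k]) return(c1[k] < c2[k])
    }
  }
  length(c1) < length(c2)
}

new_pipeline_path <- function(start, end, steps, total_weight, formats) {
  structure(list(start = start, end = end, steps = as.integer(steps),
                 total_weight = total_weight, formats = formats),
            class = "pipeline_path")
}

#' @export
print.pipeline_path <- function(x, ...) {
  cat(sprintf("<pipeline_path> %s -> %s via codes [%s], total weight %g\n",
              x$start, x$end, paste(x$steps, collapse = ", "),
              x$total_weight))
  cat(" ", paste(x$formats, collapse = " -> "), "\n")
  invisible(x)
}

check_endpoints <- function(g, start, end) {
  pn <- primary_nodes(g)
  for (fmt in c(start, end)) {
    if (!(fmt %in% pn)) {
      pg_stop("pg_unknown_format",
              sprintf("'%s' is not a primary format of the tool graph (known: %s)",
                      fmt, paste(sort(pn), collapse = ", ")))
    }
  }
}

self_loop_path <- function(g, start) {
  te <- tool_edges(g)
  loops <- te[te$from == start & te$to == start, , drop = FALSE]
  if (!nrow(loops)) {
    pg_stop("pg_identity_request",
            sprintf("start equals end ('%s') and no same-format tool exists for it",
                    start))
  }
  loops <- loops[order(loops$weight, loops$code), , drop = FALSE]
  new_pipeline_path(start, start, loops$code[1], loops$weight[1],
                    c(start, start))
}

#' Find the optimal tool path between two formats
#'
#' Dijkstra's shortest-path search over the graph's tool edges (auxiliary
#' XI/XO edges carry no processing and are never traversed). Among paths of
#' equal total weight the result is deterministic: fewest edges first, then
#' the lexicographically smallest code sequence. Parallel edges between the
#' same pair of formats compete individually, so the better of two
#' alternative tools wins. A request with `start == end` resolves only
#' through an explicit same-format (self-loop) tool.
#'
#' @param g A `tool_graph`.
#' @param start,end Primary format names.
#' @return A `pipeline_path` with the ordered tool codes and total weight.
#' @examples
#' g <- build_tool_graph(parse_registry(pipegraph_registry("basic")))
#' find_path(g, "PolyPhred", "StructureFormat")$steps  # 1 2 5
#' @export
find_path <- function(g, start, end) {
  stopifnot(inherits(g, "tool_graph"))
  check_endpoints(g, start, end)
  if (start == end) return(self_loop_path(g, start))
  te <- tool_edges(g)
  pn <- primary_nodes(g)
  dist <- stats::setNames(rep(Inf, length(pn)), pn)
  nstep <- stats::setNames(rep(Inf, length(pn)), pn)
  codes <- stats::setNames(vector("list", length(pn)), pn)
  visited <- stats::setNames(rep(FALSE, length(pn)), pn)
  dist[start] <- 0; nstep[start] <- 0; codes[[start]] <- integer()
  repeat {
    u <- NA_character_
    for (v in pn[!visited]) {
      if (!is.finite(dist[v])) next
      if (is.na(u) || path_key_less(dist[v], nstep[v], codes[[v]],
                                    dist[u], nstep[u], codes[[u]])) u <- v
    }
    if (is.na(u)) break
    visited[u] <- TRUE
    if (u == end) break
    out <- te[te$from == u & te$from != te$to, , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      v <- out$to[i]
      cand_d <- dist[u] + out$weight[i]
      cand_n <- nstep[u] + 1
      cand_c <- c(codes[[u]], out$code[i])
      if (path_key_less(cand_d, cand_n, cand_c,
                        dist[v], nstep[v], codes[[v]] %||% integer())) {
        dist[v] <- cand_d; nstep[v] <- cand_n; codes[[v]] <- cand_c
      }
    }
  }
  if (!is.finite(dist[end])) {
    pg_stop("pg_no_pipeline",
            sprintf("no available pipeline converts '%s' into '%s'", start, end))
  }
  steps <- codes[[end]]
  outs <- vapply(steps, function(cd) registry_entry(g$registry, cd)$output,
                 character(1))
  new_pipeline_path(start, end, steps, unname(dist[end]), c(start, outs))
}

#' Bellman-Ford variant of the path search
#'
#' Same contract and same deterministic tie-breaking as [find_path()], using
#' Bellman-Ford relaxation sweeps instead of Dijkstra. Exists as an
#' independent route to the same answer (the two must agree on every graph
#' with non-negative weights); useful for cross-validation.
#'
#' @inheritParams find_path
#' @return A `pipeline_path`.
#' @export
find_path_bellman_ford <- function(g, start, end) {
  stopifnot(inherits(g, "tool_graph"))
  check_endpoints(g, start, end)
  if (start == end) return(self_loop_path(g, start))
  te <- tool_edges(g)
  te <- te[te$from != te$to, , drop = FALSE]
  pn <- primary_nodes(g)
  dist <- stats::setNames(rep(Inf, length(pn)), pn)
  nstep <- stats::setNames(rep(Inf, length(pn)), pn)
  codes <- stats::setNames(vector("list", length(pn)), pn)
  dist[start] <- 0; nstep[start] <- 0; codes[[start]] <- integer()
  for (pass in seq_len(max(length(pn) - 1L, 1L))) {
    changed <- FALSE
    for (i in seq_len(nrow(te))) {
      u <- te$from[i]; v <- te$to[i]
      if (!is.finite(dist[u])) next
      cand_d <- dist[u] + te$weight[i]
      cand_n <- nstep[u] + 1
      cand_c <- c(codes[[u]], te$code[i])
      if (path_key_less(cand_d, cand_n, cand_c,
                        dist[v], nstep[v], codes[[v]] %||% integer())) {
        dist[v] <- cand_d; nstep[v] <- cand_n; codes[[v]] <- cand_c
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!is.finite(dist[end])) {
    pg_stop("pg_no_pipeline",
            sprintf("no available pipeline converts '%s' into '%s'", start, end))
  }
  steps <- codes[[end]]
  outs <- vapply(steps, function(cd) registry_entry(g$registry, cd)$output,
                 character(1))
  new_pipeline_path(start, end, steps, unname(dist[end]), c(start, outs))
}

#' Compile a tool path into an executable pipeline
#'
#' Materialises a path as the three manifests of a function-specific
#' pipeline: the full required-input list `li` (the start file plus every
#' step's extra inputs, in path order), one command line per step of the form
#' `<language> <tool> <input> [xi...] <output> [xo...]`, and the full output
#' list `lo` (the end file plus every step's secondary outputs, in path
#' order). File names are `<FormatLabel><run_id>`, where the label of an
#' aliased extra-input occurrence includes its numerical index (e.g. the
#' second registered SDAT extra input under run id `"02"` becomes
#' `SDAT202`). Intermediate files chain: each command's output name is the
#' next command's input name.
#'
#' @param p A `pipeline_path`.
#' @param reg The `tool_registry` the path was found in.
#' @param run_id String token appended to every file name, isolating
#'   concurrent runs.
#' @return An object of class `executable_pipeline` with fields `li`,
#'   `commands`, `lo`, `run_id`.
#' @examples
#' reg <- parse_registry(pipegraph_registry("basic"))
#' g <- build_tool_graph(reg)
#' ep <- compile_pipeline(find_path(g, "PHASEOUT", "Fasta"), reg, "03")
#' ep$li  # PHASEOUT03 Fragments03 RefSeq03
#' @export
compile_pipeline <- function(p, reg, run_id = "01") {
  stopifnot(inherits(p, "pipeline_path"), inherits(reg, "tool_registry"))
  aux <- registry_aux_labels(reg)
  codes <- registry_codes(reg)
  li <- paste0(p$start, run_id)
  lo <- paste0(p$end, run_id)
  commands <- character(length(p$steps))
  for (k in seq_along(p$steps)) {
    idx <- which(codes == p$steps[k])
    if (!length(idx)) {
      pg_stop("pg_consistency_error",
              sprintf("path step code %d not present in registry", p$steps[k]))
    }
    e <- reg$entries[[idx]]
    xi_lab <- vapply(aux[[idx]]$xi, `[[`, character(1), "label")
    xo_lab <- vapply(aux[[idx]]$xo, `[[`, character(1), "label")
    xi_files <- if (length(xi_lab)) paste0(xi_lab, run_id) else character()
    xo_files <- if (length(xo_lab)) paste0(xo_lab, run_id) else character()
    in_file <- paste0(e$input, run_id)
    out_file <- paste0(e$output, run_id)
    commands[k] <- trimws(paste(e$language, e$tool,
                                paste(c(in_file, xi_files), collapse = " "),
                                paste(c(out_file, xo_files), collapse = " ")))
    li <- c(li, xi_files)
    lo <- c(lo, xo_files)
  }
  structure(list(li = li, commands = commands, lo = lo, run_id = run_id),
            class = "executable_pipeline")
}

#' @export
print.executable_pipeline <- function(x, ...) {
  cat(sprintf("<executable_pipeline> run %s: %d command(s)\n",
              x$run_id, length(x$commands)))
  cat(".inputs: ", paste(x$li, collapse = ", "), "\n")
  for (cmd in x$commands) cat("  $", cmd, "\n")
  cat(".outputs:", paste(x$lo, collapse = ", "), "\n")
  invisible(x)
}

#' Write a compiled pipeline's run files
#'
#' Writes `pipeline.inputs` (required input files, one per line),
#' `pipeline.exec` (the command sequence, runnable as a shell file) and
#' `pipeline.outputs` (produced files, one per line) into `dir`.
#'
#' @param ep An `executable_pipeline`.
#' @param dir Directory to write into (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_files <- function(ep, dir) {
  stopifnot(inherits(ep, "executable_pipeline"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) pg_stop("pg_io_error", sprintf("cannot create directory %s", dir))
  }
  wr <- function(lines, fn) {
    path <- file.path(dir, fn)
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) pg_stop("pg_io_error", sprintf("cannot write %s", path))
    path
  }
  wr(ep$li, "pipeline.inputs")
  exec <- wr(c("#!/bin/sh", paste0("# run_id: ", ep$run_id), ep$commands),
             "pipeline.exec")
  Sys.chmod(exec, "0755")
  wr(ep$lo, "pipeline.outputs")
  invisible(dir)
}

#' Read back a pipeline's run files
#'
#' Inverse of [write_run_files()]: reconstructs the `executable_pipeline`
#' from the three manifests.
#'
#' @param dir Directory containing `pipeline.inputs`, `pipeline.exec`,
#'   `pipeline.outputs`.
#' @return An `executable_pipeline`.
#' @export
read_run_files <- function(dir) {
  rd <- function(fn) {
    path <- file.path(dir, fn)
    if (!file.exists(path)) {
      pg_stop("pg_io_error", sprintf("missing run file: %s", path))
    }
    readLines(path)
  }
  exec <- rd("pipeline.exec")
  run_id <- sub("^# run_id: ", "", grep("^# run_id: ", exec, value = TRUE)[1])
  if (is.na(run_id)) run_id <- ""
  structure(list(li = rd("pipeline.inputs"),
                 commands = exec[!grepl("^#", exec) & nzchar(exec)],
                 lo = rd("pipeline.outputs"),
                 run_id = run_id),
            class = "executable_pipeline")
}

#' Compose a pipeline from a registry in one call
#'
#' Convenience wrapper: build the graph, find the path, compile it.
#'
#' @param reg A `tool_registry` (or path to a registry TSV).
#' @param start,end Primary format names.
#' @param criterion Weight criterion, see [edge_weight()].
#' @param run_id Run token for file naming.
#' @return A list with `path` (the `pipeline_path`) and `pipeline` (the
#'   `executable_pipeline`).
#' @export
compose_pipeline <- function(reg, start, end,
                             criterion = c("performance", "dependencies"),
                             run_id = "01") {
  if (is.character(reg)) reg <- parse_registry(reg)
  criterion <- match.arg(criterion)
  g <- build_tool_graph(reg, criterion)
  p <- find_path(g, start, end)
  list(path = p, pipeline = compile_pipeline(p, reg, run_id))
}
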