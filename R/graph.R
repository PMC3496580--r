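# Tool graph: directed multigraph compiled from a registry. Formats are
# nodes, tools are weighted edges (parallel edges allowed and distinguished
# by code); extra inputs (XI) and secondary outputs (XO) appear as zero-weight
# auxiliary nodes/edges, aliased with a numerical index when their format
# name already exists in the graph. Aux edges are bookkeeping/visualisation
# only: path search runs over tool edges.

#' Edge weight of a registry entry under a weight criterion
#'
#' Under the `performance` criterion the weight is the entry's mean response
#' time; under the `dependencies` criterion it is the number of extra input
#' files the tool requires, so that the cheapest pipeline is the one asking
#' least of the user.
#'
#' @param entry A `tool_entry`.
#' @param criterion `"performance"` or `"dependencies"`.
#' @return Non-negative numeric weight.
#' @examples
#' e <- tool_entry("PHASEOUT", "Fasta", "Phase2Fasta.pl", "perl", 9,
#'                 xi = c("Fragments", "RefSeq"), performance = 0.02)
#' edge_weight(e, "performance")   # 0.02
#' edge_weight(e, "dependencies")  # 2
#' @export
edge_weight <- function(entry, criterion = c("performance", "dependencies")) {
  stopifnot(inherits(entry, "tool_entry"))
  criterion <- match.arg(criterion)
  switch(criterion,
         performance = entry$performance,
         dependencies = length(entry$xi))
}

# Deterministic alias labels for every XI/XO occurrence, in registry order.
# A per-base-name counter starts at 1 and an index is attached only when the
# base name already names a node (primary or aux) in the graph so far.
registry_aux_labels <- function(reg) {
  primary <- unique(unlist(lapply(reg$entries, function(e) c(e$input, e$output))))
  existing <- primary
  counters <- new.env(parent = emptyenv())
  label_one <- function(name) {
    if (name %in% existing) {
      idx <- (get0(name, envir = counters, ifnotfound = 0L)) + 1L
      assign(name, idx, envir = counters)
      lab <- paste0(name, idx)
    } else {
      idx <- NA_integer_
      lab <- name
    }
    existing <<- c(existing, lab)
    list(name = name, label = lab, alias_index = idx)
  }
  lapply(reg$entries, function(e) {
    list(xi = lapply(e$xi, label_one), xo = lapply(e$xo, label_one))
  })
}

#' Build the directed tool graph from a registry
#'
#' Every entry contributes its input and output formats as primary nodes and
#' one weighted tool edge (a self-loop when input equals output). Then every
#' XI and XO format contributes an auxiliary node — aliased with a numerical
#' index when its name is already taken — and a zero-weight auxiliary edge
#' labelled with the tool's code: XI aux node to the tool's output node,
#' tool's input node to XO aux node. Rebuilding from the same registry yields
#' an identical graph.
#'
#' @param reg A `tool_registry`.
#' @param criterion Weight criterion, see [edge_weight()].
#' @return An object of class `tool_graph` with `nodes` and `edges` data
#'   frames, the criterion and the originating registry.
#' @examples
#' g <- build_tool_graph(parse_registry(pipegraph_registry("basic")))
#' sum(!g$nodes$is_aux)  # 7 primary format nodes
#' @export
build_tool_graph <- function(reg, criterion = c("performance", "dependencies")) {
  validate_registry(reg)
  criterion <- match.arg(criterion)
  primary <- unique(unlist(lapply(reg$entries, function(e) c(e$input, e$output))))
  nodes <- data.frame(name = primary, label = primary,
                      is_aux = rep(FALSE, length(primary)),
                      alias_index = rep(NA_integer_, length(primary)),
                      stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(reg$entries, function(e) {
    data.frame(from = e$input, to = e$output, code = e$code,
               weight = edge_weight(e, criterion), is_aux = FALSE,
               stringsAsFactors = FALSE)
  }))
  aux <- registry_aux_labels(reg)
  for (j in seq_along(reg$entries)) {
    e <- reg$entries[[j]]
    for (a in aux[[j]]$xi) {
      nodes <- rbind(nodes, data.frame(name = a$name, label = a$label,
                                       is_aux = TRUE, alias_index = a$alias_index,
                                       stringsAsFactors = FALSE))
      edges <- rbind(edges, data.frame(from = a$label, to = e$output,
                                       code = e$code, weight = 0, is_aux = TRUE,
                                       stringsAsFactors = FALSE))
    }
    for (a in aux[[j]]$xo) {
      nodes <- rbind(nodes, data.frame(name = a$name, label = a$label,
                                       is_aux = TRUE, alias_index = a$alias_index,
                                       stringsAsFactors = FALSE))
      edges <- rbind(edges, data.frame(from = e$input, to = a$label,
                                       code = e$code, weight = 0, is_aux = TRUE,
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        code = integer(), weight = numeric(),
                        is_aux = logical(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, criterion = criterion,
                 registry = reg),
            class = "tool_graph")
}

#' @export
print.tool_graph <- function(x, ...) {
  cat(sprintf("<tool_graph> %d primary + %d aux nodes, %d tool + %d aux edges (criterion: %s)\n",
              sum(!x$nodes$is_aux), sum(x$nodes$is_aux),
              sum(!x$edges$is_aux), sum(x$edges$is_aux), x$criterion))
  invisible(x)
}

primary_nodes <- function(g) g$nodes$label[!g$nodes$is_aux]

tool_edges <- function(g) g$edges[!g$edges$is_aux, , drop = FALSE]

#' Export a tool graph in DOT format
#'
#' Writes a Graphviz DOT rendition: primary format nodes as circles, aux
#' (XI/XO) nodes double-circled, edges labelled `code (weight)`, aux edges
#' dashed. Useful for visually inspecting a registry's connectivity.
#'
#' @param g A `tool_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_dot <- function(g, path) {
  q <- function(s) paste0('"', gsub('"', '\\\\"', s), '"')
  lines <- c("digraph toolgraph {", "  rankdir=LR;")
  for (i in seq_len(nrow(g$nodes))) {
    n <- g$nodes[i, ]
    shape <- if (n$is_aux) "doublecircle" else "ellipse"
    lines <- c(lines, sprintf("  %s [shape=%s];", q(n$label), shape))
  }
  for (i in seq_len(nrow(g$edges))) {
    e <- g$edges[i, ]
    style <- if (e$is_aux) ", style=dashed" else ""
    lines <- c(lines,
               sprintf('  %s -> %s [label="%d (%g)"%s];',
                       q(e$from), q(e$to), e$code, e$weight, style))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
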