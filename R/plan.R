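# Planner: connectivity analytics over the tool graph, used when deciding
# which conversion tool is most worth writing next. "Possible conversions"
# are ordered pairs (s, t), s != t, of primary format nodes connected by a
# tool-edge path; aux nodes and self-pairs are excluded.

reach_closure <- function(formats, edges_from, edges_to) {
  # boolean reachability matrix by BFS from each node (graphs here are tiny)
  n <- length(formats)
  reach <- matrix(FALSE, n, n, dimnames = list(formats, formats))
  adj <- lapply(formats, function(f) unique(edges_to[edges_from == f]))
  names(adj) <- formats
  for (s in formats) {
    frontier <- adj[[s]]
    seen <- character()
    while (length(frontier)) {
      nxt <- setdiff(frontier, seen)
      seen <- c(seen, nxt)
      frontier <- unique(unlist(adj[nxt], use.names = FALSE))
    }
    reach[s, seen[seen %in% formats]] <- TRUE
  }
  diag(reach) <- FALSE
  reach
}

#' Conversion reachability matrix
#'
#' @param g A `tool_graph`.
#' @return An object of class `conversion_matrix`: a boolean matrix over
#'   ordered pairs of primary formats, `TRUE` where a tool-edge path converts
#'   the row format into the column format (the transitive closure of the
#'   tool-edge relation; the diagonal is excluded).
#' @export
conversion_matrix <- function(g) {
  stopifnot(inherits(g, "tool_graph"))
  te <- tool_edges(g)
  m <- reach_closure(primary_nodes(g), te$from, te$to)
  structure(m, class = c("conversion_matrix", class(m)))
}

#' @export
print.conversion_matrix <- function(x, ...) {
  cat(sprintf("<conversion_matrix> %d formats, %d possible conversions\n",
              nrow(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Count the possible conversions a registry offers
#'
#' The number of ordered primary-format pairs (s, t), s != t, for which some
#' sequence of registered tools converts s into t. Combination is the point:
#' the count typically exceeds the number of tools.
#'
#' @param g A `tool_graph`.
#' @return Integer count.
#' @examples
#' g <- build_tool_graph(parse_registry(pipegraph_registry("full_synthetic")))
#' count_conversions(g)  # 26 from 15 tools
#' @export
count_conversions <- function(g) {
  sum(conversion_matrix(g))
}

#' Conversions gained by registering a hypothetical new tool
#'
#' Inserts a hypothetical edge `new_input -> new_output` (the source may be a
#' format new to the graph) and returns the ordered format pairs that become
#' reachable and were not before, excluding the inserted pair itself: the
#' direct conversion is the new tool's own functionality, while the gain
#' measures what graph composition adds on top of it.
#'
#' @param g A `tool_graph`.
#' @param new_input,new_output Format names for the hypothetical tool's main
#'   input and output; `new_output` is normally an existing primary format.
#' @return A data frame with columns `from` and `to`, one row per gained
#'   ordered pair (zero rows when the edge duplicates existing reachability).
#' @examples
#' g <- build_tool_graph(parse_registry(pipegraph_registry("full_synthetic")))
#' nrow(gain_analysis(g, "formatX", "SDAT"))   # 6
#' nrow(gain_analysis(g, "formatX", "NEXUS"))  # 1
#' @export
gain_analysis <- function(g, new_input, new_output) {
  stopifnot(inherits(g, "tool_graph"))
  te <- tool_edges(g)
  formats <- unique(c(primary_nodes(g), new_input, new_output))
  before <- reach_closure(formats, te$from, te$to)
  after <- reach_closure(formats, c(te$from, new_input), c(te$to, new_output))
  gained <- which(after & !before, arr.ind = TRUE)
  out <- data.frame(from = formats[gained[, 1]], to = formats[gained[, 2]],
                    stringsAsFactors = FALSE)
  out <- out[!(out$from == new_input & out$to == new_output), , drop = FALSE]
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most valuable target format for a new conversion tool
#'
#' Given the input format of a tool one is considering writing, returns the
#' existing primary format whose choice as the tool's output maximises the
#' number of gained conversions (see [gain_analysis()]); ties are broken
#' alphabetically. `candidates` restricts the comparison to a shortlist.
#'
#' @param g A non-empty `tool_graph`.
#' @param new_input Format name of the prospective tool's input.
#' @param candidates Optional character vector of candidate target formats
#'   (default: all primary formats).
#' @return The selected format name, with the gained-pair count as attribute
#'   `gain`.
#' @export
best_extension <- function(g, new_input, candidates = NULL) {
  stopifnot(inherits(g, "tool_graph"))
  pn <- primary_nodes(g)
  if (!length(pn)) pg_stop("pg_validation_error", "graph has no primary nodes")
  if (is.null(candidates)) candidates <- pn
  candidates <- sort(intersect(candidates, pn))
  gains <- vapply(candidates,
                  function(t) nrow(gain_analysis(g, new_input, t)), integer(1))
  best <- candidates[which.max(gains)]  # which.max keeps the first = alphabetical tie-break
  structure(best, gain = max(gains))
}
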