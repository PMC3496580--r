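# Shared test fixtures and independent oracles.

basic_reg <- function() parse_registry(pipegraph_registry("basic"))
full_reg <- function() parse_registry(pipegraph_registry("full_synthetic"))

# Exhaustive enumeration over all simple tool-edge paths: the independent
# shortest-path oracle (self-loops are irrelevant for start != end because
# weights are non-negative).
brute_min_weight <- function(g, start, end) {
  te <- pipegraph:::tool_edges(g)
  te <- te[te$from != te$to, , drop = FALSE]
  best <- Inf
  rec <- function(node, visited, w) {
    if (node == end) {
      best <<- min(best, w)
      return(invisible())
    }
    out <- which(te$from == node)
    for (i in out) {
      if (te$to[i] %in% visited) next
      rec(te$to[i], c(visited, te$to[i]), w + te$weight[i])
    }
  }
  rec(start, start, 0)
  best
}

# Brute-force transitive closure for the planner oracle.
brute_reachable_pairs <- function(g) {
  te <- pipegraph:::tool_edges(g)
  pn <- pipegraph:::primary_nodes(g)
  pairs <- character()
  for (s in pn) for (t in pn) {
    if (s != t && is.finite(brute_min_weight(g, s, t))) {
      pairs <- c(pairs, paste(s, t))
    }
  }
  pairs
}

# Small genotype dataset helpers
make_tabs <- function(n_samples = 4, n_sites = 3, missing_rate = 0, seed = 7,
                      n_populations = 1) {
  generate_genotypes(fixture_spec(n_samples, n_sites, missing_rate, seed,
                                  n_populations))
}

# Unordered call multiset of a genotype_table, for allele-conservation checks
call_set <- function(tab) {
  p <- pipegraph:::sorted_pair(tab$a1, tab$a2)
  m <- matrix(paste(ifelse(is.na(p$a1), "N", p$a1),
                    ifelse(is.na(p$a2), "N", p$a2)),
              nrow = length(tab$samples))
  dimnames(m) <- list(tab$samples, tab$sites$id)
  m
}

# Stage a scenario's required input files into workdir, matching ep$li names.
stage_inputs <- function(ep, workdir, start_tab, extra_tabs = list()) {
  stopifnot(dir.exists(workdir))
  li <- ep$li
  start_fmt <- sub(paste0(ep$run_id, "$"), "", li[1])
  render_genotypes(start_tab, start_fmt, file.path(workdir, li[1]))
  for (k in seq_along(li[-1])) {
    fname <- li[k + 1L]
    base <- sub(paste0(ep$run_id, "$"), "", fname)
    fmt <- sub("[0-9]+$", "", base)  # strip alias index (SDAT1 -> SDAT)
    tab <- if (k <= length(extra_tabs)) extra_tabs[[k]] else start_tab
    render_genotypes(tab, fmt, file.path(workdir, fname))
  }
  invisible(li)
}

expect_pg_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
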