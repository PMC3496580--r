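test_that("printed conversion scenarios compose to the expected tool paths", {
  g <- build_tool_graph(basic_reg())
  p3 <- find_path(g, "PolyPhred", "StructureFormat")
  expect_identical(p3$steps, c(1L, 2L, 5L))
  expect_equal(p3$total_weight, 0.004 + 0.01 + 0.15)

  p4 <- find_path(g, "PHASEOUT", "Fasta")
  expect_identical(p4$steps, 9L)

  expect_error(find_path(g, "StructureFormat", "PolyPhred"),
               class = "pg_no_pipeline")
  expect_error(find_path(g, "SDAT", "NoSuchFormat"),
               class = "pg_unknown_format")
  expect_error(find_path(g, "SDAT", "SDAT"), class = "pg_identity_request")
})

test_that("the direct tool beats the two-step alternative route on the full catalogue", {
  g <- build_tool_graph(full_reg())
  p <- find_path(g, "SDAT", "RHierfstat")
  expect_identical(p$steps, 7L)
  via_nexus <- edge_weight(registry_entry(full_reg(), 10), "performance") +
    edge_weight(registry_entry(full_reg(), 11), "performance")
  expect_lt(p$total_weight, via_nexus)
})

test_that("same-format requests resolve only through self-loop tools", {
  reg <- tool_registry(list(
    tool_entry("F", "F", "trimA.sh", "sh", 1, performance = 0.4),
    tool_entry("F", "F", "trimB.sh", "sh", 2, performance = 0.1),
    tool_entry("F", "G", "conv.sh", "sh", 3, performance = 0.2)))
  g <- build_tool_graph(reg)
  p <- find_path(g, "F", "F")
  expect_identical(p$steps, 2L)  # cheaper self-loop wins
  expect_equal(p$total_weight, 0.1)
})

test_that("parallel edges compete individually and ties break deterministically", {
  reg <- tool_registry(list(
    tool_entry("A", "B", "slow.sh", "sh", 1, performance = 0.9),
    tool_entry("A", "B", "fast.sh", "sh", 2, performance = 0.1),
    tool_entry("B", "C", "bc.sh", "sh", 3, performance = 0.1),
    tool_entry("A", "C", "ac.sh", "sh", 4, performance = 0.2)))
  g <- build_tool_graph(reg)
  # parallel A->B edges: the better one is chosen
  expect_identical(find_path(g, "A", "B")$steps, 2L)
  # equal-weight alternatives (2,3 vs 4): fewest edges wins
  expect_identical(find_path(g, "A", "C")$steps, 4L)

  # pure weight tie with equal lengths: lexicographically smallest codes
  reg2 <- tool_registry(list(
    tool_entry("A", "B", "x.sh", "sh", 5, performance = 0.2),
    tool_entry("A", "B", "y.sh", "sh", 2, performance = 0.2)))
  expect_identical(find_path(build_tool_graph(reg2), "A", "B")$steps, 2L)
})

test_that("auxiliary edges are never traversed as conversions", {
  # Fragments/RefSeq aux nodes feed Phase2Fasta with zero weight; a path
  # from them would be a spurious free conversion
  g <- build_tool_graph(basic_reg())
  expect_error(find_path(g, "Fragments", "Fasta"), class = "pg_unknown_format")
  # and zero-weight aux edges do not shortcut real conversions
  p <- find_path(g, "PolyPhred", "RHierfstat")
  expect_identical(p$steps, c(1L, 2L, 7L))
  expect_equal(p$total_weight, 0.004 + 0.01 + 0.02)
})

test_that("shortest paths match the exhaustive oracle, Bellman-Ford and igraph", {
  skip_if_not_installed("igraph")
  for (seed in 1:50) {
    reg <- random_registry(2 + (seed %% 7), 3 + (seed %% 3), seed)
    g <- build_tool_graph(reg)
    te <- pipegraph:::tool_edges(g)
    pn <- pipegraph:::primary_nodes(g)
    ig <- igraph::graph_from_data_frame(te[c("from", "to", "weight")],
                                        vertices = pn)
    for (s in pn) for (t in pn) {
      if (s == t) next
      oracle <- brute_min_weight(g, s, t)
      igd <- igraph::distances(ig, v = s, to = t, mode = "out",
                               weights = igraph::E(ig)$weight)[1, 1]
      p <- tryCatch(find_path(g, s, t), pg_no_pipeline = function(e) NULL)
      pb <- tryCatch(find_path_bellman_ford(g, s, t),
                     pg_no_pipeline = function(e) NULL)
      if (is.null(p)) {
        expect_false(is.finite(oracle))
        expect_false(is.finite(igd))
        expect_null(pb)
      } else {
        expect_equal(p$total_weight, oracle)
        expect_equal(p$total_weight, igd)
        expect_equal(pb$total_weight, p$total_weight)
        expect_identical(pb$steps, p$steps)
        # chaining: consecutive steps connect
        fmts <- p$formats
        for (k in seq_along(p$steps)) {
          e <- registry_entry(reg, p$steps[k])
          expect_identical(e$input, fmts[k])
          expect_identical(e$output, fmts[k + 1])
        }
      }
    }
  }
})

test_that("compiled pipelines have the documented command shape and manifests", {
  reg <- basic_reg()
  g <- build_tool_graph(reg)

  ep <- compile_pipeline(find_path(g, "PolyPhred", "StructureFormat"), reg, "01")
  expect_identical(ep$li, "PolyPhred01")
  expect_length(ep$commands, 3)
  expect_identical(ep$lo, c("StructureFormat01", "mainparam01", "extraparam01"))
  expect_identical(
    ep$commands[3],
    "perl SDAT2Structure.pl SDAT01 StructureFormat01 mainparam01 extraparam01")

  ep4 <- compile_pipeline(find_path(g, "PHASEOUT", "Fasta"), reg, "03")
  expect_identical(ep4$li, c("PHASEOUT03", "Fragments03", "RefSeq03"))
  expect_identical(ep4$commands,
                   "perl Phase2Fasta.pl PHASEOUT03 Fragments03 RefSeq03 Fasta03")
  expect_identical(ep4$lo, "Fasta03")

  # the full catalogue names the hierfstat extra input with its alias index
  full <- full_reg()
  ep1 <- compile_pipeline(find_path(build_tool_graph(full), "SDAT", "RHierfstat"),
                          full, "02")
  expect_identical(ep1$li, c("SDAT02", "SDAT202"))
  expect_identical(ep1$commands,
                   "perl SDAT2Rhierfstat.pl SDAT02 SDAT202 RHierfstat02")
  expect_identical(ep1$lo, "RHierfstat02")

  expect_error(
    compile_pipeline(pipegraph:::new_pipeline_path("A", "B", 99L, 0, c("A", "B")),
                     reg, "01"),
    class = "pg_consistency_error")
})

test_that("LI/LO conservation and chaining hold on composed random pipelines", {
  n_checked <- 0
  for (seed in 1:40) {
    reg <- random_registry(2 + (seed %% 7), 3 + (seed %% 3), seed * 13)
    g <- build_tool_graph(reg)
    pn <- pipegraph:::primary_nodes(g)
    for (s in pn) for (t in pn) {
      if (s == t) next
      p <- tryCatch(find_path(g, s, t), pg_no_pipeline = function(e) NULL)
      if (is.null(p)) next
      ep <- compile_pipeline(p, reg, "07")
      entries <- lapply(p$steps, registry_entry, reg = reg)
      expect_length(ep$li, 1 + sum(lengths(lapply(entries, `[[`, "xi"))))
      expect_length(ep$lo, 1 + sum(lengths(lapply(entries, `[[`, "xo"))))
      expect_length(ep$commands, length(p$steps))
      # command k's main output file equals command k+1's main input file
      for (k in seq_along(entries)) {
        expect_identical(paste0(entries[[k]]$input, "07"),
                         if (k == 1) ep$li[1] else
                           paste0(entries[[k - 1]]$output, "07"))
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 50)
})

test_that("run files round-trip and .exec is a runnable shell file", {
  reg <- basic_reg()
  res <- compose_pipeline(reg, "PolyPhred", "StructureFormat", run_id = "01")
  d <- withr::local_tempdir()
  write_run_files(res$pipeline, d)

  expect_identical(readLines(file.path(d, "pipeline.inputs")), res$pipeline$li)
  expect_identical(readLines(file.path(d, "pipeline.outputs")), res$pipeline$lo)
  exec <- readLines(file.path(d, "pipeline.exec"))
  expect_identical(exec[1], "#!/bin/sh")
  expect_identical(exec[-(1:2)], res$pipeline$commands)

  back <- read_run_files(d)
  expect_identical(back$li, res$pipeline$li)
  expect_identical(back$commands, res$pipeline$commands)
  expect_identical(back$lo, res$pipeline$lo)
  expect_identical(back$run_id, "01")

  expect_error(read_run_files(file.path(d, "nope")), class = "pg_io_error")
})
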