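test_that("PolyPhred reports flatten to PrettyBase and pivot to SDAT losslessly", {
  tab <- make_tabs(2, 3, seed = 5)[[1]]
  d <- withr::local_tempdir()
  pp <- file.path(d, "pp"); pb <- file.path(d, "pb"); sd <- file.path(d, "sd")

  render_genotypes(tab, "PolyPhred", pp)
  polyphred_to_prettybase(pp, pb)
  expect_length(readLines(pb), 2 * 3)  # one line per (site, sample)

  prettybase_to_sdat(pb, sd)
  back <- read_sdat(sd)
  expect_equal(dim(back), c(2, 3))
  expect_identical(call_set(back), call_set(tab))  # every call preserved

  # empty genotype section -> empty outputs
  writeLines(c("BEGIN GENOTYPES", "END GENOTYPES"), pp)
  polyphred_to_prettybase(pp, pb)
  expect_length(readLines(pb), 0)

  # malformed section line -> parse error naming the line
  writeLines(c("BEGIN GENOTYPES", "S01 I01 A", "END GENOTYPES"), pp)
  err <- expect_error(polyphred_to_prettybase(pp, pb),
                      class = "pg_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("PrettyBase pivoting is order-invariant and rejects conflicts", {
  tab <- make_tabs(3, 4, missing_rate = 0.2, seed = 9)[[1]]
  d <- withr::local_tempdir()
  pb <- file.path(d, "pb")
  render_genotypes(tab, "PrettyBase", pb)

  sorted_out <- file.path(d, "s1"); shuffled_out <- file.path(d, "s2")
  prettybase_to_sdat(pb, sorted_out)

  lines <- readLines(pb)
  set.seed(4)
  writeLines(sample(lines), pb)
  prettybase_to_sdat(pb, shuffled_out)
  expect_identical(readLines(shuffled_out), readLines(sorted_out))

  # single call -> 1x1 matrix
  writeLines("S01\tI01\tA\tC", pb)
  prettybase_to_sdat(pb, sorted_out)
  expect_equal(dim(read_sdat(sorted_out)), c(1, 1))

  # agreeing duplicates collapse; conflicting ones error
  writeLines(c("S01\tI01\tA\tC", "S01\tI01\tC\tA"), pb)
  prettybase_to_sdat(pb, sorted_out)
  expect_equal(dim(read_sdat(sorted_out)), c(1, 1))
  writeLines(c("S01\tI01\tA\tC", "S01\tI01\tA\tG"), pb)
  expect_error(prettybase_to_sdat(pb, sorted_out),
               class = "pg_consistency_error")
})

test_that("Structure conversion recodes alleles and declares consistent counts", {
  tab <- make_tabs(2, 3, missing_rate = 0.3, seed = 13)[[1]]
  d <- withr::local_tempdir()
  sd <- file.path(d, "sd"); st <- file.path(d, "st")
  mp <- file.path(d, "mp"); ep <- file.path(d, "ep")
  render_genotypes(tab, "SDAT", sd)
  sdat_to_structure(sd, st, mp, ep)

  rows <- read.table(st, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(rows), 2 * 2)  # two rows per individual
  expect_identical(rows[[1]], rep(tab$samples, each = 2))
  codes <- as.matrix(rows[-1])
  expect_true(all(codes %in% c(1:4, -9)))

  # missing calls appear as the missing code in both allele rows
  miss <- is.na(tab$a1)
  for (i in seq_along(tab$samples)) {
    expect_identical(unname(codes[2 * i - 1, ] == -9), unname(miss[i, ]))
    expect_identical(unname(codes[2 * i, ] == -9), unname(miss[i, ]))
  }

  mp_lines <- readLines(mp)
  expect_true(sprintf("#define NUMINDS %d", 2) %in% mp_lines)
  expect_true(sprintf("#define NUMLOCI %d", 3) %in% mp_lines)

  # empty matrix is rejected
  writeLines("Sample", sd)
  expect_error(sdat_to_structure(sd, st, mp, ep),
               class = "pg_validation_error")
})

test_that("hierfstat tables stack populations with correct indices and codes", {
  tabs <- make_tabs(2, 3, seed = 17, n_populations = 2)
  d <- withr::local_tempdir()
  s1 <- file.path(d, "s1"); s2 <- file.path(d, "s2"); hf <- file.path(d, "hf")
  render_genotypes(tabs[[1]], "SDAT", s1)
  render_genotypes(tabs[[2]], "SDAT", s2)

  sdat_to_rhierfstat(s1, hf, extra_pops = s2)
  df <- read.table(hf, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 4)
  expect_equal(df$pop, c(1, 1, 2, 2))
  vals <- unlist(df[-1])
  expect_true(all(vals %in% c(11:14, 22:24, 33:34, 44) | is.na(vals)))

  # two-digit code is 10*min + max of the A=1..T=4 recode
  known <- pipegraph:::genotype_code(c("A", "T", "G"), c("C", "A", "G"))
  expect_identical(known, c(12L, 14L, 33L))

  # at least one and at most four extra populations
  expect_error(sdat_to_rhierfstat(s1, hf, extra_pops = character()),
               class = "pg_validation_error")
  expect_error(sdat_to_rhierfstat(s1, hf, extra_pops = rep(s2, 5)),
               class = "pg_validation_error")

  # site mismatch across populations names the offending sites
  tab3 <- make_tabs(2, 4, seed = 18)[[1]]
  s3 <- file.path(d, "s3")
  render_genotypes(tab3, "SDAT", s3)
  err <- expect_error(sdat_to_rhierfstat(s1, hf, extra_pops = s3),
                      class = "pg_validation_error")
  expect_match(conditionMessage(err), "S04")
})

test_that("PHASE output rebuilds reference-anchored FASTA haplotypes", {
  d <- withr::local_tempdir()
  ph <- file.path(d, "ph"); fr <- file.path(d, "fr")
  rs <- file.path(d, "rs"); fa <- file.path(d, "fa")

  # one individual, reference AAAA, one site at position 2 phased C|G
  writeLines(c("BEGIN BESTPAIRS", "#I01", "C", "G", "END BESTPAIRS"), ph)
  writeLines(c("Site\tPosition", "S01\t2"), fr)
  writeLines(c(">reference", "AAAA"), rs)
  phase_to_fasta(ph, fr, rs, fa)
  seqs <- seqinr::read.fasta(fa, as.string = TRUE, forceDNAtolower = FALSE)
  expect_identical(toupper(unname(unlist(seqs))), c("ACAA", "AGAA"))
  expect_identical(names(seqs), c("I01_1", "I01_2"))

  # zero polymorphic sites: haplotypes equal the reference
  writeLines(c("BEGIN BESTPAIRS", "#I01", "", "", "END BESTPAIRS"), ph)
  writeLines("Site\tPosition", fr)
  phase_to_fasta(ph, fr, rs, fa)
  seqs <- seqinr::read.fasta(fa, as.string = TRUE, forceDNAtolower = FALSE)
  expect_identical(toupper(unname(unlist(seqs))), c("AAAA", "AAAA"))

  # N individuals -> 2N records, on a generated dataset
  tab <- make_tabs(5, 3, seed = 23)[[1]]
  for (f in c("PHASEOUT", "Fragments", "RefSeq")) {
    render_genotypes(tab, f, file.path(d, f))
  }
  phase_to_fasta(file.path(d, "PHASEOUT"), file.path(d, "Fragments"),
                 file.path(d, "RefSeq"), fa)
  seqs <- seqinr::read.fasta(fa, as.string = TRUE, forceDNAtolower = FALSE)
  expect_length(seqs, 2 * 5)
  # and matches the generator's ground-truth haplotype rendering
  render_genotypes(tab, "Fasta", file.path(d, "truth"))
  expect_identical(readLines(fa), readLines(file.path(d, "truth")))

  # unphased (parenthesised) markers are rejected
  writeLines(c("BEGIN BESTPAIRS", "#I01", "(C)", "(G)", "END BESTPAIRS"), ph)
  writeLines(c("Site\tPosition", "S01\t2"), fr)
  expect_error(phase_to_fasta(ph, fr, rs, fa), class = "pg_parse_error")

  # site position beyond the reference is rejected
  writeLines(c("BEGIN BESTPAIRS", "#I01", "C", "G", "END BESTPAIRS"), ph)
  writeLines(c("Site\tPosition", "S01\t99"), fr)
  expect_error(phase_to_fasta(ph, fr, rs, fa), class = "pg_validation_error")
})

test_that("NEXUS output declares consistent dimensions and parses with ape", {
  tab <- make_tabs(2, 3, missing_rate = 0.2, seed = 29)[[1]]
  d <- withr::local_tempdir()
  sd <- file.path(d, "sd"); nx <- file.path(d, "nx")
  render_genotypes(tab, "SDAT", sd)
  sdat_to_nexus(sd, nx)

  lines <- readLines(nx)
  expect_match(lines[3], "NTAX=4 NCHAR=3")

  dat <- ape::read.nexus.data(nx)  # third-party reader accepts the file
  expect_length(dat, 4)
  expect_true(all(lengths(dat) == 3))

  back <- read_nexus_genotypes(nx)
  expect_identical(call_set(back), call_set(tab))
  expect_identical(back$sites$id, tab$sites$id)

  # 1x1 matrix renders to a minimal valid NEXUS
  one <- make_tabs(1, 1, seed = 31)[[1]]
  render_genotypes(one, "SDAT", sd)
  sdat_to_nexus(sd, nx)
  expect_length(ape::read.nexus.data(nx), 2)

  # empty or odd DATA blocks are rejected
  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=0 NCHAR=0;",
               "FORMAT DATATYPE=DNA;", "MATRIX", ";", "END;"), nx)
  expect_error(read_nexus_genotypes(nx), class = "pg_parse_error")
  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=3 NCHAR=1;",
               "FORMAT DATATYPE=DNA;", "MATRIX", "a_1 A", "a_2 C", "b_1 G",
               ";", "END;"), nx)
  expect_error(read_nexus_genotypes(nx), class = "pg_parse_error")
})

test_that("direct and via-NEXUS hierfstat routes produce identical tables", {
  tabs <- make_tabs(3, 4, missing_rate = 0.1, seed = 37, n_populations = 2)
  d <- withr::local_tempdir()
  s <- file.path(d, c("s1", "s2")); n <- file.path(d, c("n1", "n2"))
  render_genotypes(tabs[[1]], "SDAT", s[1])
  render_genotypes(tabs[[2]], "SDAT", s[2])

  direct <- file.path(d, "direct"); vianx <- file.path(d, "vianx")
  sdat_to_rhierfstat(s[1], direct, extra_pops = s[2])
  sdat_to_nexus(s[1], n[1]); sdat_to_nexus(s[2], n[2])
  nexus_to_rhierfstat(n[1], vianx, extra_pops = n[2])
  expect_identical(readLines(vianx), readLines(direct))

  # single population via NEXUS: all rows carry index 1
  one <- file.path(d, "one")
  nexus_to_rhierfstat(n[1], one)
  df <- read.table(one, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 3)
  expect_true(all(df$pop == 1))
})

test_that("conversions conserve the allele-call multiset across dialects", {
  for (seed in c(41, 43)) {
    tab <- make_tabs(4, 5, missing_rate = 0.15, seed = seed)[[1]]
    d <- withr::local_tempdir()
    render_genotypes(tab, "PrettyBase", file.path(d, "pb"))
    expect_identical(call_set(read_prettybase(file.path(d, "pb"))),
                     call_set(tab))
    render_genotypes(tab, "SDAT", file.path(d, "sd"))
    expect_identical(call_set(read_sdat(file.path(d, "sd"))), call_set(tab))
    render_genotypes(tab, "NEXUS", file.path(d, "nx"))
    expect_identical(call_set(read_nexus_genotypes(file.path(d, "nx"))),
                     call_set(tab))
  }
})
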