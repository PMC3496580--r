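# Synthetic-data module: deterministic generators for genotype datasets
# (renderable in every supported dialect) and for random tool registries
# (driving the shortest-path oracle tests). One explicitly seeded random
# stream per artifact; the global RNG state is left untouched.

with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic genotype dataset
#'
#' @param n_samples,n_sites Counts per population (`>= 1`).
#' @param missing_rate Probability in `[0, 1)` that a call is missing.
#' @param seed Integer seed making every derived artifact reproducible.
#' @param n_populations Number of populations sharing one site list.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_samples = 10, n_sites = 5, missing_rate = 0,
                         seed = 1, n_populations = 1) {
  if (n_samples < 1 || n_sites < 1 || n_populations < 1) {
    pg_stop("pg_validation_error", "counts must be >= 1")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    pg_stop("pg_validation_error", "missing_rate must be in [0, 1)")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_sites = as.integer(n_sites),
                 missing_rate = missing_rate, seed = as.integer(seed),
                 n_populations = as.integer(n_populations)),
            class = "fixture_spec")
}

#' Generate synthetic diploid genotype datasets
#'
#' Produces one phased [genotype_table()] per population. Sites are
#' biallelic with the two alleles drawn per site from {A,C,G,T}; haplotype
#' alleles are drawn uniformly from the site's two alleles; whole calls go
#' missing independently at `missing_rate`. All populations share the same
#' site list (IDs, strictly increasing positions) and the same reference
#' sequence, whose base at each polymorphic position is the site's first
#' allele. Deterministic given `spec$seed`.
#'
#' @param spec A `fixture_spec`.
#' @return A list of `genotype_table`s of length `spec$n_populations`.
#' @export
generate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    w_site <- max(2L, nchar(as.character(spec$n_sites)))
    w_samp <- max(2L, nchar(as.character(spec$n_samples)))
    pos <- sort(sample.int(10L * spec$n_sites, spec$n_sites))
    sites <- data.frame(id = sprintf("S%0*d", w_site, seq_len(spec$n_sites)),
                        pos = pos)
    alleles <- t(vapply(seq_len(spec$n_sites),
                        function(j) sample(names(ALLELE_CODE), 2L),
                        character(2)))
    reflen <- max(pos) + 5L
    refseq <- sample(names(ALLELE_CODE), reflen, replace = TRUE)
    refseq[pos] <- alleles[, 1]
    refseq <- paste(refseq, collapse = "")
    lapply(seq_len(spec$n_populations), function(p) {
      samples <- sprintf("P%dI%0*d", p, w_samp, seq_len(spec$n_samples))
      draw <- function() {
        m <- matrix(NA_character_, spec$n_samples, spec$n_sites)
        for (j in seq_len(spec$n_sites)) {
          m[, j] <- sample(alleles[j, ], spec$n_samples, replace = TRUE)
        }
        m
      }
      a1 <- draw(); a2 <- draw()
      if (spec$missing_rate > 0) {
        miss <- matrix(stats::runif(length(a1)) < spec$missing_rate,
                       nrow = nrow(a1))
        a1[miss] <- NA_character_; a2[miss] <- NA_character_
      }
      genotype_table(samples, sites, a1, a2, phased = TRUE, refseq = refseq)
    })
  })
}

RENDER_FORMATS <- c("PolyPhred", "PrettyBase", "SDAT", "StructureFormat",
                    "RHierfstat", "NEXUS", "PHASEOUT", "Fragments", "RefSeq",
                    "Fasta")

#' Render a genotype table in a supported dialect
#'
#' Writes `tab` to `path` in any dialect of the conversion suite;
#' `"Fragments"` and `"RefSeq"` render the companions a PHASE-to-FASTA run
#' needs, and `"Fasta"` renders the ground-truth haplotype sequences
#' (reference with each individual's phased alleles substituted), useful as
#' an oracle for end-to-end runs.
#'
#' @param tab A `genotype_table`.
#' @param format One of `"PolyPhred"`, `"PrettyBase"`, `"SDAT"`,
#'   `"StructureFormat"`, `"RHierfstat"`, `"NEXUS"`, `"PHASEOUT"`,
#'   `"Fragments"`, `"RefSeq"`, `"Fasta"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
render_genotypes <- function(tab, format, path) {
  stopifnot(inherits(tab, "genotype_table"))
  if (!format %in% RENDER_FORMATS) {
    pg_stop("pg_validation_error",
            sprintf("unsupported render format '%s' (supported: %s)", format,
                    paste(RENDER_FORMATS, collapse = ", ")))
  }
  switch(format,
    PolyPhred = write_polyphred(tab, path),
    PrettyBase = write_prettybase(tab, path),
    SDAT = write_sdat(tab, path),
    StructureFormat = {
      tmp_main <- tempfile(); tmp_extra <- tempfile()
      on.exit(unlink(c(tmp_main, tmp_extra)), add = TRUE)
      tmp_sdat <- tempfile()
      on.exit(unlink(tmp_sdat), add = TRUE)
      write_sdat(tab, tmp_sdat)
      sdat_to_structure(tmp_sdat, path, tmp_main, tmp_extra)
    },
    RHierfstat = write_hierfstat_table(list(tab), path),
    NEXUS = write_nexus_genotypes(tab, path),
    PHASEOUT = write_phase_out(tab, path),
    Fragments = write_fragments(tab, path),
    RefSeq = write_refseq(tab, path),
    Fasta = {
      if (is.null(tab$refseq)) {
        pg_stop("pg_validation_error",
                "genotype table carries no reference sequence")
      }
      seqs <- list(); nms <- character()
      for (i in seq_along(tab$samples)) {
        for (h in 1:2) {
          hap <- if (h == 1) tab$a1[i, ] else tab$a2[i, ]
          s <- strsplit(tab$refseq, "")[[1]]
          s[tab$sites$pos] <- ifelse(is.na(hap), "N", hap)
          seqs <- c(seqs, list(s))
          nms <- c(nms, paste0(tab$samples[i], "_", h))
        }
      }
      seqinr::write.fasta(seqs, names = nms, file.out = path)
      path
    })
  invisible(path)
}

#' Generate a random tool registry
#'
#' Synthetic registries for property testing of the graph and path modules:
#' random input/output format pairs over `n_formats` formats (occasional
#' self-loops and parallel edges arise naturally), uniform non-negative
#' performances rounded to 3 decimals, and sporadic XI/XO lists.
#' Deterministic given `seed`.
#'
#' @param n_entries Number of tools.
#' @param n_formats Number of distinct format names (`>= 2`).
#' @param seed Integer seed.
#' @return A `tool_registry`.
#' @export
random_registry <- function(n_entries, n_formats, seed) {
  if (n_formats < 2) pg_stop("pg_validation_error", "need n_formats >= 2")
  with_local_seed(seed, {
    fmts <- paste0("F", seq_len(n_formats))
    entries <- lapply(seq_len(n_entries), function(k) {
      input <- sample(fmts, 1L)
      output <- if (stats::runif(1) < 0.1) input else sample(fmts, 1L)
      xi <- if (stats::runif(1) < 0.3) {
        sample(fmts, sample(1:2, 1L))
      } else character()
      xo <- if (stats::runif(1) < 0.2) sample(fmts, 1L) else character()
      tool_entry(input, output, sprintf("tool%02d.sh", k), "sh", k,
                 xi = xi, xo = xo,
                 performance = round(stats::runif(1), 3))
    })
    tool_registry(entries)
  })
}

#' Registry of the installed, runnable converter tools
#'
#' Builds a `tool_registry` whose tools are the converter wrapper scripts
#' installed with this package (invoked through `Rscript`), covering the
#' PolyPhred/PrettyBase/SDAT/Structure/PHASE/NEXUS/FASTA/hierfstat suite.
#' Pipelines composed from it execute end to end with [run_pipeline()].
#'
#' @return A `tool_registry` with 7 runnable entries.
#' @export
runnable_registry <- function() {
  rs <- file.path(R.home("bin"), "Rscript")
  tl <- function(fn) system.file("tools", fn, package = "pipegraph",
                                 mustWork = TRUE)
  tool_registry(list(
    tool_entry("PolyPhred", "PrettyBase", tl("polyphred2prettybase.R"), rs, 1,
               performance = 0.004),
    tool_entry("PrettyBase", "SDAT", tl("prettybase2sdat.R"), rs, 2,
               performance = 0.01),
    tool_entry("SDAT", "StructureFormat", tl("sdat2structure.R"), rs, 5,
               xo = c("mainparam", "extraparam"), performance = 0.15),
    tool_entry("SDAT", "RHierfstat", tl("sdat2rhierfstat.R"), rs, 7,
               xi = "SDAT", performance = 0.02),
    tool_entry("PHASEOUT", "Fasta", tl("phase2fasta.R"), rs, 9,
               xi = c("Fragments", "RefSeq"), performance = 0.02),
    tool_entry("SDAT", "NEXUS", tl("sdat2nexus.R"), rs, 10,
               performance = 0.21),
    tool_entry("NEXUS", "RHierfstat", tl("nexus2rhierfstat.R"), rs, 11,
               xi = "NEXUS", performance = 0.15)
  ))
}
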