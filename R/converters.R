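# Format converters for the population-genetics suite. Every converter is a
# file-to-file operation, also installed as a command-line wrapper under
# inst/tools/ obeying the pipeline command contract
#   <interpreter> <tool> <input> [xi...] <output> [xo...]
# so composed pipelines run end to end.

MAX_POPULATIONS <- 5L

#' PolyPhred genotype report to PrettyBase
#'
#' Extracts the genotype section of a PolyPhred-style report and emits one
#' PrettyBase line per (site, sample) call, in the section's order.
#'
#' @param input Path to the PolyPhred genotype report.
#' @param output Path for the PrettyBase file.
#' @return `output`, invisibly.
#' @export
polyphred_to_prettybase <- function(input, output) {
  m <- read_polyphred_records(input)
  lines <- vapply(seq_len(nrow(m)), function(k) {
    paste(m[k, 1], m[k, 2], m[k, 3], m[k, 4], sep = "\t")
  }, character(1))
  writeLines(lines, output)
  invisible(output)
}

#' PrettyBase to SDAT
#'
#' Pivots per-call PrettyBase lines (which may arrive in any order) into the
#' rectangular SDAT sample-by-site genotype matrix. Sites and samples are
#' emitted in sorted order, so shuffled input yields byte-identical output;
#' (site, sample) combinations absent from the input become missing calls;
#' duplicated records must agree or a consistency error is raised.
#'
#' @param input Path to a PrettyBase file.
#' @param output Path for the SDAT file.
#' @return `output`, invisibly.
#' @export
prettybase_to_sdat <- function(input, output) {
  tab <- read_prettybase(input)
  write_sdat(tab, output)
  invisible(output)
}

#' SDAT to Structure input (plus parameter files)
#'
#' Writes the Structure data file — two rows per individual, alleles
#' integer-recoded A,C,G,T to 1..4 and missing to -9 — together with the
#' `mainparam`/`extraparam` settings files declaring the individual and locus
#' counts the data file satisfies.
#'
#' @param input Path to an SDAT file (non-empty matrix).
#' @param output Path for the Structure data file.
#' @param mainparam,extraparam Paths for the two parameter files.
#' @return `output`, invisibly.
#' @export
sdat_to_structure <- function(input, output,
                              mainparam = paste0(output, ".mainparam"),
                              extraparam = paste0(output, ".extraparam")) {
  tab <- read_sdat(input)
  if (!length(tab$samples) || !nrow(tab$sites)) {
    pg_stop("pg_validation_error", "empty genotype matrix: nothing to convert")
  }
  rows <- character(2L * length(tab$samples))
  for (i in seq_along(tab$samples)) {
    c1 <- allele_int(tab$a1[i, ]); c2 <- allele_int(tab$a2[i, ])
    lo <- pmin(c1, c2); hi <- pmax(c1, c2)
    lo[is.na(lo)] <- -9L; hi[is.na(hi)] <- -9L
    rows[2L * i - 1L] <- paste(c(tab$samples[i], lo), collapse = "\t")
    rows[2L * i] <- paste(c(tab$samples[i], hi), collapse = "\t")
  }
  writeLines(rows, output)
  writeLines(c(sprintf("#define NUMINDS %d", length(tab$samples)),
               sprintf("#define NUMLOCI %d", nrow(tab$sites)),
               "#define PLOIDY 2",
               "#define MISSING -9",
               "#define ONEROWPERIND 0",
               "#define LABEL 1",
               "#define MARKERNAMES 0"), mainparam)
  writeLines(c("#define NOADMIX 0",
               "#define LINKAGE 0",
               "#define USEPOPINFO 0"), extraparam)
  invisible(output)
}

check_shared_sites <- function(tabs) {
  ref <- tabs[[1]]$sites$id
  for (k in seq_along(tabs)[-1]) {
    ids <- tabs[[k]]$sites$id
    if (!identical(ids, ref)) {
      off <- union(setdiff(ids, ref), setdiff(ref, ids))
      if (!length(off)) off <- "(same sites, different order)"
      pg_stop("pg_validation_error",
              sprintf("population %d disagrees on sites: %s", k,
                      paste(off, collapse = ", ")))
    }
  }
}

write_hierfstat_table <- function(tabs, output) {
  header <- paste(c("pop", tabs[[1]]$sites$id), collapse = "\t")
  rows <- character()
  for (k in seq_along(tabs)) {
    tab <- tabs[[k]]
    for (i in seq_along(tab$samples)) {
      codes <- genotype_code(tab$a1[i, ], tab$a2[i, ])
      rows <- c(rows, paste(c(k, ifelse(is.na(codes), "NA", codes)),
                            collapse = "\t"))
    }
  }
  writeLines(c(header, rows), output)
  invisible(output)
}

#' SDAT to hierfstat table
#'
#' Combines one SDAT file per population into a single hierfstat-style
#' genotype table: a population-index column (populations numbered in file
#' order, the main input being population 1) followed by per-locus two-digit
#' genotype codes (`10 * allele1 + allele2` on the A=1..T=4 recode, smaller
#' allele first; missing calls become `NA`). All files must share the same
#' site list; at most five populations in total are accepted.
#'
#' @param input Path to the main SDAT file (population 1).
#' @param output Path for the hierfstat table.
#' @param extra_pops Paths of 1 or more further SDAT files, one population
#'   each.
#' @return `output`, invisibly.
#' @export
sdat_to_rhierfstat <- function(input, output, extra_pops = character()) {
  if (length(extra_pops) < 1L) {
    pg_stop("pg_validation_error",
            "at least one extra population file is required")
  }
  if (1L + length(extra_pops) > MAX_POPULATIONS) {
    pg_stop("pg_validation_error",
            sprintf("%d populations supplied; at most %d are supported",
                    1L + length(extra_pops), MAX_POPULATIONS))
  }
  tabs <- lapply(c(input, extra_pops), read_sdat)
  check_shared_sites(tabs)
  write_hierfstat_table(tabs, output)
}

#' PHASE output to FASTA haplotypes
#'
#' Rebuilds full haplotype sequences from PHASE best-pairs output: each
#' individual contributes two FASTA records equal to the reference sequence
#' with its phased alleles substituted at the mapped site positions. The
#' site-map ("fragments") file assigns, in order, a reference position to
#' each polymorphic site of the PHASE output.
#'
#' @param input Path to the PHASE best-pairs output.
#' @param fragments Path to the site-map table (`Site`, `Position`).
#' @param refseq Path to the reference FASTA (single record spanning all
#'   mapped positions).
#' @param output Path for the FASTA file (2 records per individual, named
#'   `<id>_1` / `<id>_2`).
#' @return `output`, invisibly.
#' @export
phase_to_fasta <- function(input, fragments, refseq, output) {
  ph <- read_phase_out(input)
  frag <- read_fragments(fragments)
  ref <- read_refseq(refseq)
  if (!length(ph$samples)) {
    pg_stop("pg_validation_error", "PHASE output holds no individuals")
  }
  nsites <- ncol(ph$h1)
  if (nrow(frag) != nsites) {
    pg_stop("pg_validation_error",
            sprintf("site map lists %d site(s) but PHASE output carries %d",
                    nrow(frag), nsites))
  }
  if (nrow(frag) && max(frag$Position) > nchar(ref)) {
    pg_stop("pg_validation_error",
            sprintf("site position %d beyond reference length %d",
                    max(frag$Position), nchar(ref)))
  }
  seqs <- list(); nms <- character()
  for (i in seq_along(ph$samples)) {
    for (h in 1:2) {
      hap <- if (h == 1) ph$h1[i, ] else ph$h2[i, ]
      s <- strsplit(ref, "")[[1]]
      if (nrow(frag)) s[frag$Position] <- hap
      seqs <- c(seqs, list(s))
      nms <- c(nms, paste0(ph$samples[i], "_", h))
    }
  }
  seqinr::write.fasta(seqs, names = nms, file.out = output)
  invisible(output)
}

#' SDAT to NEXUS
#'
#' Renders the genotype matrix as a NEXUS `DATA` block with one taxon per
#' allele row (`NTAX = 2 * samples`, taxa named `<sample>_1`/`<sample>_2`,
#' `NCHAR = sites`, missing `N`). Site IDs are preserved in a `[sites: ...]`
#' comment that this package's NEXUS reader recovers; standard NEXUS readers
#' skip it.
#'
#' @param input Path to an SDAT file.
#' @param output Path for the NEXUS file.
#' @return `output`, invisibly.
#' @export
sdat_to_nexus <- function(input, output) {
  tab <- read_sdat(input)
  write_nexus_genotypes(tab, output)
}

#' @rdname dialect_io
#' @export
write_nexus_genotypes <- function(tab, path) {
  n <- length(tab$samples)
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", 2L * n, nrow(tab$sites)),
             "  FORMAT DATATYPE=DNA MISSING=N GAP=-;",
             sprintf("  [sites: %s]", paste(tab$sites$id, collapse = " ")),
             "  MATRIX")
  for (i in seq_len(n)) {
    p <- sorted_pair(tab$a1[i, ], tab$a2[i, ])
    lines <- c(lines,
               sprintf("    %s_1 %s", tab$samples[i],
                       paste(ifelse(is.na(p$a1), "N", p$a1), collapse = "")),
               sprintf("    %s_2 %s", tab$samples[i],
                       paste(ifelse(is.na(p$a2), "N", p$a2), collapse = "")))
  }
  writeLines(c(lines, "  ;", "END;"), path)
  invisible(path)
}

#' @rdname dialect_io
#' @export
read_nexus_genotypes <- function(path) {
  dat <- tryCatch(ape::read.nexus.data(path),
                  error = function(e) {
                    pg_stop("pg_parse_error",
                            sprintf("not a readable NEXUS DATA block: %s",
                                    conditionMessage(e)))
                  })
  if (!length(dat)) pg_stop("pg_parse_error", "NEXUS DATA block holds no taxa")
  if (length(dat) %% 2L != 0L) {
    pg_stop("pg_parse_error",
            sprintf("odd taxon count (%d): cannot pair haplotype rows",
                    length(dat)))
  }
  taxa <- names(dat)
  if (!all(grepl("_[12]$", taxa))) {
    pg_stop("pg_parse_error",
            "taxa must be named <sample>_1 / <sample>_2 haplotype pairs")
  }
  stems <- sub("_[12]$", "", taxa)
  odd <- seq(1L, length(dat), by = 2L)
  if (!identical(stems[odd], stems[odd + 1L])) {
    pg_stop("pg_parse_error", "haplotype taxa are not in consecutive pairs")
  }
  nchar_ <- unique(vapply(dat, length, integer(1)))
  if (length(nchar_) != 1L) {
    pg_stop("pg_parse_error", "taxa differ in sequence length")
  }
  site_line <- grep("\\[sites:", readLines(path), value = TRUE)
  site_ids <- if (length(site_line)) {
    strsplit(trimws(sub("\\]", "", sub(".*\\[sites:", "", site_line[1]))),
             "[\t ]+")[[1]]
  } else paste0("loc", seq_len(nchar_))
  if (length(site_ids) != nchar_) {
    pg_stop("pg_parse_error", "site-label comment disagrees with NCHAR")
  }
  clean <- function(v) {
    v <- toupper(v)
    v[v == "N" | v == "-" | v == "?"] <- NA_character_
    v
  }
  a1 <- do.call(rbind, lapply(dat[odd], clean))
  a2 <- do.call(rbind, lapply(dat[odd + 1L], clean))
  genotype_table(stems[odd],
                 data.frame(id = site_ids, pos = seq_len(nchar_)), a1, a2)
}

#' NEXUS to hierfstat table
#'
#' Same output dialect as [sdat_to_rhierfstat()], reading populations from
#' NEXUS files with paired haplotype taxa instead. Composing
#' [sdat_to_nexus()] with this converter yields the same table as the direct
#' SDAT route on identical inputs.
#'
#' @param input Path to the main NEXUS file (population 1).
#' @param output Path for the hierfstat table.
#' @param extra_pops Paths of 0 or more further NEXUS files.
#' @return `output`, invisibly.
#' @export
nexus_to_rhierfstat <- function(input, output, extra_pops = character()) {
  if (1L + length(extra_pops) > MAX_POPULATIONS) {
    pg_stop("pg_validation_error",
            sprintf("%d populations supplied; at most %d are supported",
                    1L + length(extra_pops), MAX_POPULATIONS))
  }
  tabs <- lapply(c(input, extra_pops), read_nexus_genotypes)
  check_shared_sites(tabs)
  write_hierfstat_table(tabs, output)
}
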