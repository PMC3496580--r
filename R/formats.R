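# Genotype container and on-disk dialect I/O for the population-genetics
# conversion suite. All dialects are plain text. Diploid data only; missing
# calls propagate (never imputed). Allele integer recode throughout:
# A=1, C=2, G=3, T=4; missing is N (text dialects) / -9 (Structure) /
# NA (hierfstat codes).

ALLELE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Diploid genotype table
#'
#' The in-memory container behind every converter: an ordered set of samples,
#' an ordered set of polymorphic sites (IDs plus strictly increasing 1-based
#' positions) and, per (sample, site), a pair of alleles from {A,C,G,T} or
#' missing (`NA`). The pair is stored as two matrices `a1`/`a2`; when
#' `phased` is `TRUE` the two matrices are the two haplotypes, otherwise the
#' pair is unordered.
#'
#' @param samples Character vector of sample IDs.
#' @param sites Data frame with columns `id` and `pos` (strictly increasing).
#' @param a1,a2 Character matrices (samples x sites) of alleles, `NA` for
#'   missing; a call is missing as a whole (both alleles `NA`).
#' @param phased Logical flag; haplotype order is meaningful only if `TRUE`.
#' @param refseq Optional reference sequence (single string) covering all
#'   site positions; used when rendering PHASE/FASTA companions.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(samples, sites, a1, a2, phased = FALSE,
                           refseq = NULL) {
  stopifnot(is.character(samples), is.data.frame(sites),
            all(c("id", "pos") %in% names(sites)))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!all(dim(a1) == c(length(samples), nrow(sites))) ||
      !all(dim(a2) == dim(a1))) {
    pg_stop("pg_validation_error",
            "allele matrices must be samples x sites and congruent")
  }
  if (nrow(sites) > 1 && any(diff(sites$pos) <= 0)) {
    pg_stop("pg_validation_error", "site positions must be strictly increasing")
  }
  dimnames(a1) <- dimnames(a2) <- list(samples, sites$id)
  structure(list(samples = samples, sites = sites, a1 = a1, a2 = a2,
                 phased = phased, refseq = refseq),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d sample(s) x %d site(s)%s, %d missing call(s)\n",
              length(x$samples), nrow(x$sites),
              if (x$phased) ", phased" else "", sum(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$samples), nrow(x$sites))

# canonical unordered rendering of a call: alleles in A<C<G<T order
sorted_pair <- function(a1, a2) {
  swap <- !is.na(a1) & !is.na(a2) & ALLELE_CODE[a2] < ALLELE_CODE[a1]
  list(a1 = ifelse(swap, a2, a1), a2 = ifelse(swap, a1, a2))
}

## ---- PrettyBase: one tab-separated line per (site, sample) call ----------

#' @rdname dialect_io
#' @export
write_prettybase <- function(tab, path) {
  lines <- character()
  for (j in seq_len(nrow(tab$sites))) {
    for (i in seq_along(tab$samples)) {
      p <- sorted_pair(tab$a1[i, j], tab$a2[i, j])
      lines <- c(lines, paste(tab$sites$id[j], tab$samples[i],
                              ifelse(is.na(p$a1), "N", p$a1),
                              ifelse(is.na(p$a2), "N", p$a2), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Dialect readers and writers
#'
#' Plain-text I/O for each supported dialect. `write_*` functions take a
#' [genotype_table()] and a path; `read_*` functions reconstruct a
#' `genotype_table` (positions are taken as the site rank when the dialect
#' does not carry them). Dialects: PrettyBase (`site sample allele1 allele2`,
#' tab-separated), SDAT (header of site IDs, one row per sample, genotypes
#' `X/Y`, missing `N/N`), PolyPhred genotype section (`BEGIN GENOTYPES` /
#' `END GENOTYPES` with `site sample allele1 allele2` rows), PHASE best-pairs
#' output (`BEGIN BESTPAIRS`, per individual a `#id` line and two haplotype
#' lines), site-map ("fragments") tables (`Site`, `Position`) and reference
#' FASTA.
#'
#' @param tab A `genotype_table`.
#' @param path File to write/read.
#' @name dialect_io
#' @export
read_prettybase <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(k) {
    f <- strsplit(trimws(lines[k]), "[\t ]+")[[1]]
    if (length(f) != 4L) {
      pg_stop("pg_parse_error",
              sprintf("line %d: expected 4 fields (site sample allele1 allele2), got %d",
                      k, length(f)))
    }
    f
  })
  m <- do.call(rbind, recs)
  if (is.null(m)) {
    return(genotype_table(character(),
                          data.frame(id = character(), pos = integer()),
                          matrix(character(), 0, 0), matrix(character(), 0, 0)))
  }
  key <- paste(m[, 1], m[, 2])
  if (anyDuplicated(key)) {
    norm <- apply(m, 1, function(r) {
      p <- sorted_pair(r[3], r[4]); paste(p$a1, p$a2)
    })
    nvariants <- tapply(norm, key, function(v) length(unique(v)))
    clash <- names(nvariants)[nvariants > 1L]
    if (length(clash)) {
      pg_stop("pg_consistency_error",
              sprintf("conflicting duplicate records for (site, sample): %s",
                      paste(clash, collapse = "; ")))
    }
    m <- m[!duplicated(key), , drop = FALSE]
  }
  site_ids <- sort(unique(m[, 1]))
  sample_ids <- sort(unique(m[, 2]))
  a1 <- a2 <- matrix(NA_character_, length(sample_ids), length(site_ids),
                     dimnames = list(sample_ids, site_ids))
  for (k in seq_len(nrow(m))) {
    i <- m[k, 2]; j <- m[k, 1]
    a1[i, j] <- if (m[k, 3] == "N") NA_character_ else m[k, 3]
    a2[i, j] <- if (m[k, 4] == "N") NA_character_ else m[k, 4]
  }
  genotype_table(sample_ids,
                 data.frame(id = site_ids, pos = seq_along(site_ids)),
                 a1, a2)
}

## ---- SDAT: sample-by-site genotype matrix --------------------------------

#' @rdname dialect_io
#' @export
write_sdat <- function(tab, path) {
  header <- paste(c("Sample", tab$sites$id), collapse = "\t")
  rows <- vapply(seq_along(tab$samples), function(i) {
    gts <- vapply(seq_len(nrow(tab$sites)), function(j) {
      p <- sorted_pair(tab$a1[i, j], tab$a2[i, j])
      paste0(ifelse(is.na(p$a1), "N", p$a1), "/", ifelse(is.na(p$a2), "N", p$a2))
    }, character(1))
    paste(c(tab$samples[i], gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname dialect_io
#' @export
read_sdat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) pg_stop("pg_parse_error", "empty SDAT file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 1L || header[1] != "Sample") {
    pg_stop("pg_parse_error", "SDAT header must start with 'Sample'")
  }
  site_ids <- header[-1]
  body <- lines[-1]
  samples <- character(length(body))
  a1 <- a2 <- matrix(NA_character_, length(body), length(site_ids))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(site_ids) + 1L) {
      pg_stop("pg_parse_error",
              sprintf("SDAT line %d: expected %d genotype column(s), got %d",
                      i + 1L, length(site_ids), length(f) - 1L))
    }
    samples[i] <- f[1]
    for (j in seq_along(site_ids)) {
      al <- strsplit(f[j + 1L], "/", fixed = TRUE)[[1]]
      if (length(al) != 2L) {
        pg_stop("pg_parse_error",
                sprintf("SDAT line %d, site %s: genotype '%s' is not diploid 'X/Y'",
                        i + 1L, site_ids[j], f[j + 1L]))
      }
      a1[i, j] <- if (al[1] == "N") NA_character_ else al[1]
      a2[i, j] <- if (al[2] == "N") NA_character_ else al[2]
    }
  }
  genotype_table(samples, data.frame(id = site_ids, pos = seq_along(site_ids)),
                 a1, a2)
}

## ---- PolyPhred: genotype section of a PolyPhred-style report -------------

#' @rdname dialect_io
#' @export
write_polyphred <- function(tab, path) {
  lines <- c("POLYPHRED GENOTYPE REPORT", "BEGIN GENOTYPES")
  for (j in seq_len(nrow(tab$sites))) {
    for (i in seq_along(tab$samples)) {
      p <- sorted_pair(tab$a1[i, j], tab$a2[i, j])
      lines <- c(lines, paste(tab$sites$id[j], tab$samples[i],
                              ifelse(is.na(p$a1), "N", p$a1),
                              ifelse(is.na(p$a2), "N", p$a2)))
    }
  }
  writeLines(c(lines, "END GENOTYPES"), path)
  invisible(path)
}

# returns the genotype-section records as a character matrix, in file order
read_polyphred_records <- function(path) {
  lines <- readLines(path)
  beg <- which(trimws(lines) == "BEGIN GENOTYPES")
  fin <- which(trimws(lines) == "END GENOTYPES")
  if (!length(beg) || !length(fin) || fin[1] <= beg[1]) {
    pg_stop("pg_parse_error", "no BEGIN GENOTYPES .. END GENOTYPES section found")
  }
  sect <- if (fin[1] - beg[1] > 1L) seq(beg[1] + 1L, fin[1] - 1L) else integer()
  sect <- sect[nzchar(trimws(lines[sect]))]
  recs <- lapply(sect, function(k) {
    f <- strsplit(trimws(lines[k]), "[\t ]+")[[1]]
    if (length(f) != 4L) {
      pg_stop("pg_parse_error",
              sprintf("line %d: expected 4 fields (site sample allele1 allele2), got %d",
                      k, length(f)))
    }
    f
  })
  if (!length(recs)) return(matrix(character(), 0, 4))
  do.call(rbind, recs)
}

## ---- PHASE best-pairs output + site map + reference ----------------------

#' @rdname dialect_io
#' @export
write_phase_out <- function(tab, path) {
  if (!tab$phased) {
    pg_stop("pg_validation_error",
            "PHASE output requires a phased genotype table")
  }
  lines <- "BEGIN BESTPAIRS"
  for (i in seq_along(tab$samples)) {
    lines <- c(lines, paste0("#", tab$samples[i]),
               paste(ifelse(is.na(tab$a1[i, ]), "N", tab$a1[i, ]), collapse = " "),
               paste(ifelse(is.na(tab$a2[i, ]), "N", tab$a2[i, ]), collapse = " "))
  }
  writeLines(c(lines, "END BESTPAIRS"), path)
  invisible(path)
}

#' @rdname dialect_io
#' @export
read_phase_out <- function(path) {
  lines <- readLines(path)
  beg <- which(trimws(lines) == "BEGIN BESTPAIRS")
  fin <- which(trimws(lines) == "END BESTPAIRS")
  if (!length(beg) || !length(fin) || fin[1] <= beg[1]) {
    pg_stop("pg_parse_error", "no BEGIN BESTPAIRS .. END BESTPAIRS section found")
  }
  body <- if (fin[1] - beg[1] > 1L) lines[seq(beg[1] + 1L, fin[1] - 1L)] else character()
  if (length(body) %% 3L != 0L) {
    pg_stop("pg_parse_error",
            "BESTPAIRS section must hold #id plus two haplotype lines per individual")
  }
  ids <- character(); h1 <- list(); h2 <- list()
  for (b in seq(1L, length(body), by = 3L)) {
    if (!startsWith(trimws(body[b]), "#")) {
      pg_stop("pg_parse_error",
              sprintf("expected '#individual' line, got '%s'", body[b]))
    }
    id <- sub("^#", "", trimws(body[b]))
    hp1 <- strsplit(trimws(body[b + 1L]), "[\t ]+")[[1]]
    hp2 <- strsplit(trimws(body[b + 2L]), "[\t ]+")[[1]]
    hp1 <- hp1[nzchar(hp1)]; hp2 <- hp2[nzchar(hp2)]
    if (any(grepl("[()]", c(hp1, hp2)))) {
      pg_stop("pg_parse_error",
              sprintf("individual %s carries unphased (parenthesised) markers", id))
    }
    if (length(hp1) != length(hp2)) {
      pg_stop("pg_parse_error",
              sprintf("individual %s: haplotypes differ in length", id))
    }
    ids <- c(ids, id); h1 <- c(h1, list(hp1)); h2 <- c(h2, list(hp2))
  }
  nl <- unique(vapply(h1, length, integer(1)))
  if (length(nl) > 1L) {
    pg_stop("pg_parse_error", "haplotype lengths differ across individuals")
  }
  nsites <- if (length(nl)) nl else 0L
  list(samples = ids,
       h1 = matrix(unlist(h1), nrow = length(ids), ncol = nsites, byrow = TRUE),
       h2 = matrix(unlist(h2), nrow = length(ids), ncol = nsites, byrow = TRUE))
}

#' @rdname dialect_io
#' @export
write_fragments <- function(tab, path) {
  utils::write.table(data.frame(Site = tab$sites$id, Position = tab$sites$pos),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dialect_io
#' @export
read_fragments <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("Site", "Position") %in% names(df))) {
    pg_stop("pg_parse_error", "site map must have columns Site and Position")
  }
  df$Position <- as.integer(df$Position)
  df
}

#' @rdname dialect_io
#' @export
write_refseq <- function(tab, path) {
  if (is.null(tab$refseq)) {
    pg_stop("pg_validation_error", "genotype table carries no reference sequence")
  }
  seqinr::write.fasta(strsplit(tab$refseq, "")[[1]], names = "reference",
                      file.out = path)
  invisible(path)
}

read_refseq <- function(path) {
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  if (!length(seqs)) pg_stop("pg_parse_error", "reference FASTA holds no record")
  toupper(as.character(seqs[[1]]))
}

## ---- integer recodes shared by Structure / hierfstat writers -------------

allele_int <- function(x) {
  out <- unname(ALLELE_CODE[x])
  if (any(is.na(out) & !is.na(x))) {
    bad <- unique(x[is.na(out) & !is.na(x)])
    pg_stop("pg_parse_error",
            sprintf("allele(s) outside {A,C,G,T}: %s", paste(bad, collapse = ", ")))
  }
  out
}

# two-digit genotype code 10*min + max on the A=1..T=4 recode; NA if missing
genotype_code <- function(a1, a2) {
  c1 <- allele_int(a1); c2 <- allele_int(a2)
  ifelse(is.na(c1) | is.na(c2), NA_integer_,
         10L * pmin(c1, c2) + pmax(c1, c2))
}
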