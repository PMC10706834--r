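# Duplex assay definitions and in-silico PCR.

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# compatibility matrix: rows = primer/probe IUPAC code, cols = template base.
# Template N matches nothing (unknown base never counts as a match).
.iupac_compat <- local({
  codes <- names(IUPAC_CODES)
  tbases <- c("A", "C", "G", "T", "N")
  m <- matrix(FALSE, length(codes), length(tbases),
              dimnames = list(codes, tbases))
  for (cd in codes) m[cd, IUPAC_CODES[[cd]]] <- TRUE
  m[, "N"] <- FALSE
  m
})

.check_iupac <- function(x, what) {
  ch <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(ch, names(IUPAC_CODES))
  if (length(bad))
    stop(sprintf("invalid nucleotide characters in %s: %s", what,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  invisible(ch)
}

#' Define a duplex ddPCR assay
#'
#' An assay bundles the species-specific primer pair and hydrolysis probe
#' targeting the single-copy myoglobin (MB) gene, together with the reporter
#' dye used to read it in a duplex well.
#'
#' @param species_label Species name, e.g. `"Atlantic salmon"`.
#' @param gene Target gene name.
#' @param accession GenBank accession of the target transcript.
#' @param fwd_primer,rev_primer Primer sequences, 5'->3', IUPAC codes allowed.
#' @param probe Probe sequence, 5'->3'.
#' @param reporter_dye Reporter fluorophore, `"FAM"` or `"HEX"`.
#' @param expected_amplicon_bp Expected product length in bp, or `NA`.
#'
#' @return An object of class `"ddpcr_assay"`.
#' @examples
#' a <- ddpcr_assay("test sp", "MB", "XX_000000",
#'                  "ACGTACGTAC", "TTGCAAGGTT", "ACCGGTTAAC", "FAM", 90)
#' print(a)
#' @export
ddpcr_assay <- function(species_label, gene, accession,
                        fwd_primer, rev_primer, probe,
                        reporter_dye = c("FAM", "HEX"),
                        expected_amplicon_bp = NA_integer_) {
  fwd_primer <- toupper(fwd_primer)
  rev_primer <- toupper(rev_primer)
  probe <- toupper(probe)
  for (s in c(fwd_primer, rev_primer, probe))
    if (!nzchar(s)) stop("primers and probe must be non-empty", call. = FALSE)
  .check_iupac(fwd_primer, "forward primer")
  .check_iupac(rev_primer, "reverse primer")
  .check_iupac(probe, "probe")
  if (identical(fwd_primer, rev_primer))
    stop("forward and reverse primers must differ", call. = FALSE)
  reporter_dye <- match.arg(reporter_dye)
  structure(list(
    species_label = species_label, gene = gene, accession = accession,
    fwd_primer = fwd_primer, rev_primer = rev_primer, probe = probe,
    reporter_dye = reporter_dye,
    expected_amplicon_bp = as.integer(expected_amplicon_bp)
  ), class = "ddpcr_assay")
}

#' @export
print.ddpcr_assay <- function(x, ...) {
  cat(sprintf("ddPCR assay: %s (%s, %s; %s)\n", x$species_label, x$gene,
              x$accession, x$reporter_dye))
  cat(sprintf("  fwd:   %s\n  rev:   %s\n  probe: %s\n",
              x$fwd_primer, x$rev_primer, x$probe))
  if (!is.na(x$expected_amplicon_bp))
    cat(sprintf("  expected amplicon: %d bp\n", x$expected_amplicon_bp))
  invisible(x)
}

#' Published trout/salmon myoglobin assays
#'
#' The duplex assay pair used throughout the package: a HEX-labelled Atlantic
#' salmon assay (93 bp product on NM_001140642) and a FAM-labelled rainbow
#' trout assay (141 bp product on NM_001171862), both targeting the
#' single-copy nuclear myoglobin gene.
#'
#' @return Named list of two [ddpcr_assay()] objects, `salmon` and `trout`.
#' @export
salmonid_mb_assays <- function() {
  list(
    salmon = ddpcr_assay(
      "Atlantic salmon", "myoglobin", "NM_001140642",
      fwd_primer = "GAGAGGTCACAGGGATAGGA",
      rev_primer = "CAAACCAGCACTTAGAATTTAC",
      probe = "AACTGGAAACTTACATTTGAAGCAG",
      reporter_dye = "HEX", expected_amplicon_bp = 93L),
    trout = ddpcr_assay(
      "Rainbow trout", "myoglobin", "NM_001171862",
      fwd_primer = "TTGCTTGTGACTTCCAGA",
      rev_primer = "AGAGGAACAACGCACATT",
      probe = "ACTGGAAAAGTGTATGAGGCAAAGC",
      reporter_dye = "FAM", expected_amplicon_bp = 141L)
  )
}

#' Synthetic myoglobin template stand-ins
#'
#' Synthetic DNA templates carrying the published primer and probe binding
#' sites of the two myoglobin assays at spacings that reproduce the expected
#' 93 bp and 141 bp products. The sequence between and around the binding
#' sites is random, fixed at package build time; these are *not* the GenBank
#' records, only stand-ins for exercising the in-silico PCR machinery
#' offline. Cross-assay binding sites are absent by construction (each
#' template yields no product for the other species' assay at up to two
#' mismatches).
#'
#' @return Named character vector of two sequences,
#'   `synthetic_NM_001140642` (salmon) and `synthetic_NM_001171862` (trout).
#' @export
synthetic_mb_templates <- function() {
  c(synthetic_NM_001140642 = paste0(
      "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGA",
      "GAGAGGTCACAGGGATAGGAACCCCCTGCACGCAACTGGAAACTTACATTTGAAGCAGCC",
      "TAAAGTACAATGTAAATTCTAAGTGCTGGTTTGTAGGATATTCATCCCTACACTGTATAT",
      "GCCGAACGTTCTAATAAACGACTTAGCAACAAG"),
    synthetic_NM_001171862 = paste0(
      "TCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGA",
      "TTGCTTGTGACTTCCAGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTAC",
      "TGGAAAAGTGTATGAGGCAAAGCTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCG",
      "TCGAATGTGCGTTGTTCCTCTGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACA",
      "CACTAGTCGCCCTTGAGAGCA"))
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Mismatch counts of `pattern` (IUPAC) against every placement on `tpl_chars`
# (template character vector, ACGTN). Returns integer vector over 1-based
# start positions 1..(n-L+1); empty if the template is shorter than pattern.
.scan_mismatches <- function(pattern, tpl_chars) {
  p <- strsplit(pattern, "")[[1]]
  L <- length(p)
  n <- length(tpl_chars)
  if (n < L) return(integer(0))
  starts <- seq_len(n - L + 1L)
  mm <- integer(length(starts))
  for (k in seq_len(L)) {
    mm <- mm + !.iupac_compat[p[k], tpl_chars[starts + k - 1L]]
  }
  mm
}

.check_template <- function(template) {
  if (!nzchar(template)) stop("empty template", call. = FALSE)
  ch <- strsplit(toupper(template), "")[[1]]
  bad <- setdiff(ch, c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop(sprintf("invalid nucleotide characters in template: %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  ch
}

#' In-silico PCR: locate amplicons of an assay on a template
#'
#' Scans the plus strand of `template` for placements of the forward primer
#' and, downstream, of the reverse complement of the reverse primer, allowing
#' up to `max_mismatches` Hamming mismatches per primer (no indels). The
#' 3'-terminal base of each primer must match exactly, mimicking the
#' requirement for polymerase extension. IUPAC ambiguity codes in primers and
#' probe match their expansion sets; templates may contain `N`, which matches
#' no primer base.
#'
#' @param template Template DNA sequence (character scalar), `ACGTN` only.
#' @param assay A [ddpcr_assay()].
#' @param max_mismatches Maximum mismatches per primer (and for the probe).
#' @param max_len Maximum product length searched.
#' @param template_id Identifier recorded in the output.
#' @param check_probe If `TRUE`, `probe_present` reports whether the probe
#'   (either orientation) occurs inside the product; hits without probe are
#'   kept, not dropped.
#'
#' @return A data.frame with one row per product, sorted by `start`:
#'   `template_id`, `start` (0-based, forward primer 5' end), `end`
#'   (0-based exclusive, one past the reverse primer 5' end on the plus
#'   strand), `length_bp`, `mismatches_fwd`, `mismatches_rev`,
#'   `probe_present`.
#' @examples
#' tpl <- synthetic_mb_templates()
#' find_amplicons(tpl[["synthetic_NM_001140642"]],
#'                salmonid_mb_assays()$salmon)
#' @export
find_amplicons <- function(template, assay, max_mismatches = 2L,
                           max_len = 2000L, template_id = "template",
                           check_probe = TRUE) {
  stopifnot(inherits(assay, "ddpcr_assay"))
  tpl <- .check_template(template)
  fwd <- assay$fwd_primer
  rev_rc <- .revcomp(assay$rev_primer)
  Lf <- nchar(fwd)
  Lr <- nchar(rev_rc)
  if (length(tpl) < Lf + Lr)
    stop("template shorter than combined primer length", call. = FALSE)

  mm_f <- .scan_mismatches(fwd, tpl)
  mm_r <- .scan_mismatches(rev_rc, tpl)
  # 3' base of fwd primer = last base of pattern; 3' base of rev primer =
  # first base of its reverse complement on the plus strand.
  f3 <- substr(fwd, Lf, Lf)
  r3 <- substr(rev_rc, 1L, 1L)
  f_starts <- which(mm_f <= max_mismatches &
                      .iupac_compat[f3, tpl[seq_along(mm_f) + Lf - 1L]])
  r_starts <- which(mm_r <= max_mismatches &
                      .iupac_compat[r3, tpl[seq_along(mm_r)]])

  hits <- list()
  for (f in f_starts) {
    for (r in r_starts) {
      start0 <- f - 1L
      end0 <- r - 1L + Lr
      len <- end0 - start0
      if (len < Lf + Lr || len > max_len) next
      probe_present <- FALSE
      if (check_probe) {
        inner <- tpl[f:(end0)]
        probe_present <-
          any(.scan_mismatches(assay$probe, inner) <= max_mismatches) ||
          any(.scan_mismatches(.revcomp(assay$probe), inner) <= max_mismatches)
      }
      hits[[length(hits) + 1L]] <- data.frame(
        template_id = template_id, start = start0, end = end0,
        length_bp = len, mismatches_fwd = mm_f[f], mismatches_rev = mm_r[r],
        probe_present = probe_present, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length_bp = integer(0),
                      mismatches_fwd = integer(0), mismatches_rev = integer(0),
                      probe_present = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assay x template specificity matrix
#'
#' Cross-reactivity screen: each cell is `TRUE` iff the assay yields at least
#' one amplicon with its probe present on the template.
#'
#' @param assays List of [ddpcr_assay()] objects.
#' @param templates Named character vector (or list) of template sequences.
#' @param max_mismatches Per-primer mismatch tolerance.
#' @return Logical matrix, assays in rows, templates in columns.
#' @export
specificity_matrix <- function(assays, templates, max_mismatches = 2L) {
  if (!length(assays) || !length(templates))
    stop("assays and templates must be non-empty", call. = FALSE)
  templates <- unlist(templates)
  anames <- names(assays)
  if (is.null(anames))
    anames <- vapply(assays, function(a) a$species_label, character(1))
  tnames <- names(templates)
  if (is.null(tnames)) tnames <- paste0("template", seq_along(templates))
  m <- matrix(FALSE, length(assays), length(templates),
              dimnames = list(anames, tnames))
  for (i in seq_along(assays)) {
    for (j in seq_along(templates)) {
      h <- find_amplicons(templates[[j]], assays[[i]],
                          max_mismatches = max_mismatches,
                          template_id = tnames[j])
      m[i, j] <- any(h$probe_present)
    }
  }
  m
}

#' Read template sequences from a FASTA file
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_templates <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
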