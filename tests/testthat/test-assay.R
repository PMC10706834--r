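# In-silico PCR: primer site scanning, amplicon coordinates, specificity.

rc <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("assay constructor validates primer/probe content", {
  expect_error(ddpcr_assay("x", "g", "acc", "", "ACGT", "ACGT", "FAM"),
               "non-empty")
  expect_error(ddpcr_assay("x", "g", "acc", "ACXT", "ACGT", "ACGT", "FAM"),
               "invalid nucleotide")
  expect_error(ddpcr_assay("x", "g", "acc", "ACGT", "ACGT", "ACGA", "FAM"),
               "must differ")
})

test_that("a planted primer pair yields exactly one product of designed length", {
  a <- salmonid_mb_assays()$salmon
  lead <- random_seq(10, 11)
  gap <- random_seq(93 - nchar(a$fwd_primer) - nchar(a$rev_primer), 12)
  tail <- random_seq(300 - 10 - 93, 13)
  tpl <- paste0(lead, a$fwd_primer, gap, rc(a$rev_primer), tail)
  hits <- find_amplicons(tpl, a, max_mismatches = 0, check_probe = FALSE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 10L)
  expect_equal(hits$length_bp, 93L)
  expect_equal(hits$end - hits$start, hits$length_bp)
})

test_that("both published assays find their expected single amplicon on the stand-in templates", {
  tpl <- synthetic_mb_templates()
  a <- salmonid_mb_assays()
  h_ss <- find_amplicons(tpl[["synthetic_NM_001140642"]], a$salmon)
  h_om <- find_amplicons(tpl[["synthetic_NM_001171862"]], a$trout)
  expect_equal(h_ss$length_bp, 93L)
  expect_equal(h_om$length_bp, 141L)
  expect_true(h_ss$probe_present)
  expect_true(h_om$probe_present)
  # templates are cross-clean by construction
  expect_equal(nrow(find_amplicons(tpl[[1]], a$trout)), 0L)
  expect_equal(nrow(find_amplicons(tpl[[2]], a$salmon)), 0L)
})

test_that("template validation rejects bad input", {
  a <- salmonid_mb_assays()$salmon
  expect_error(find_amplicons("", a), "empty template")
  expect_error(find_amplicons("ACGTXACGT", a), "invalid nucleotide")
  expect_error(find_amplicons("ACGT", a), "shorter than combined")
})

test_that("zero-mismatch scanning equals the brute-force placement oracle", {
  tpl <- synthetic_mb_templates()
  assays <- salmonid_mb_assays()
  for (t in tpl) {
    for (a in assays) {
      hits <- find_amplicons(t, a, max_mismatches = 0, check_probe = FALSE)
      expect_equal(sort(hits$length_bp),
                   oracle_product_lengths(t, a$fwd_primer, a$rev_primer))
    }
  }
  # and on a template with several planted sites
  a <- assays$trout
  t2 <- paste0(random_seq(30, 21), a$fwd_primer, random_seq(40, 22),
               rc(a$rev_primer), random_seq(25, 23), a$fwd_primer,
               random_seq(55, 24), rc(a$rev_primer), random_seq(30, 25))
  hits <- find_amplicons(t2, a, max_mismatches = 0, max_len = 5000,
                         check_probe = FALSE)
  expect_equal(sort(hits$length_bp),
               oracle_product_lengths(t2, a$fwd_primer, a$rev_primer,
                                      max_len = 5000))
  expect_gte(nrow(hits), 3L)  # cross products of 2 fwd x 2 rev sites
})

test_that("reverse-complementing the template and swapping primers preserves product lengths", {
  tpl <- synthetic_mb_templates()
  a <- salmonid_mb_assays()$salmon
  swapped <- ddpcr_assay(a$species_label, a$gene, a$accession,
                         fwd_primer = a$rev_primer, rev_primer = a$fwd_primer,
                         probe = a$probe, reporter_dye = a$reporter_dye)
  h1 <- find_amplicons(tpl[[1]], a, check_probe = FALSE)
  h2 <- find_amplicons(rc(tpl[[1]]), swapped, check_probe = FALSE)
  expect_equal(sort(h1$length_bp), sort(h2$length_bp))
})

test_that("IUPAC codes in primers expand; template N matches nothing", {
  # R in the primer matches A and G templates at the same position
  a <- ddpcr_assay("x", "g", "acc", "ACGTACGTRC", "GGTTGGTTGG",
                   "ACGTACGTAC", "FAM")
  base <- function(mid) paste0("TTTTT", "ACGTACGT", mid, "C",
                               random_seq(20, 31), rc("GGTTGGTTGG"), "TTTTT")
  for (mid in c("A", "G"))
    expect_equal(nrow(find_amplicons(base(mid), a, max_mismatches = 0,
                                     check_probe = FALSE)), 1L)
  # N in the template counts as a mismatch even against N-tolerant positions
  expect_equal(nrow(find_amplicons(base("N"), a, max_mismatches = 0,
                                   check_probe = FALSE)), 0L)
})

test_that("3'-terminal primer base must match exactly regardless of budget", {
  a <- salmonid_mb_assays()$salmon
  fwd <- a$fwd_primer
  # mutate the template base under the fwd primer's 3' end
  gap <- random_seq(51, 41)
  tpl_ok <- paste0(random_seq(10, 42), fwd, gap, rc(a$rev_primer),
                   random_seq(10, 43))
  mut <- strsplit(tpl_ok, "")[[1]]
  pos <- 10 + nchar(fwd)           # 1-based position of the 3' base
  mut[pos] <- setdiff(c("A", "C", "G", "T"), mut[pos])[1]
  tpl_bad <- paste(mut, collapse = "")
  expect_equal(nrow(find_amplicons(tpl_ok, a, max_mismatches = 2,
                                   check_probe = FALSE)), 1L)
  expect_equal(nrow(find_amplicons(tpl_bad, a, max_mismatches = 2,
                                   check_probe = FALSE)), 0L)
})

test_that("specificity matrix is identity-patterned on own templates and empty on random sequence", {
  tpl <- synthetic_mb_templates()
  assays <- salmonid_mb_assays()
  m <- specificity_matrix(assays, tpl)
  expect_equal(unname(m), diag(2) == 1)
  rand <- random_seq(10000, 99)
  m2 <- specificity_matrix(assays, c(rand = rand), max_mismatches = 0)
  expect_false(any(m2))
  expect_error(specificity_matrix(list(), tpl), "non-empty")
})

test_that("FASTA fixture round-trips through read_templates", {
  path <- system.file("extdata", "synthetic_mb_templates.fasta",
                      package = "salmoquant")
  tpl <- read_templates(path)
  expect_equal(tpl, synthetic_mb_templates())
})
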