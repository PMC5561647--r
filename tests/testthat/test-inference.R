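toy_psms <- function() {
  # 6 proteins: P1 fails the protein E-value, P2 has one peptide at the
  # boundary E-value plus one good one (so only one retained peptide ->
  # excluded), P3..P6 pass.
  mk <- function(acc, pep, pe, prote) {
    data.frame(peptide_sequence = pep, peptide_evalue = pe,
               protein_accession = acc, protein_evalue = prote,
               sample_id = "S1", spectra = 2L, stringsAsFactors = FALSE)
  }
  rbind(
    mk("P1", c("a1", "a2"), 1e-4, 1e-3),          # protein E too high
    mk("P2", c("b1", "b2"), c(1e-4, 0.01), 1e-6), # b2 at boundary -> out
    mk("P3", c("c1", "c2"), 1e-4, 1e-6),
    mk("P4", c("d1", "d2", "d3"), 1e-4, 1e-6),
    mk("P5", c("e1", "e2"), 1e-4, 1e-6),
    mk("P6", c("f1", "f2"), 1e-4, 1e-6)
  )
}

test_that("identification filters apply strict thresholds and the two-peptide rule", {
  filt <- filter_identifications(toy_psms())
  expect_setequal(unique(filt$protein_accession),
                  c("P3", "P4", "P5", "P6"))
  # boundary peptide E-value 0.01 is excluded (strict inequality)
  expect_false("b2" %in% filt$peptide_sequence)
  # a protein left with one retained peptide is excluded entirely
  expect_false("P2" %in% filt$protein_accession)

  # contaminants are removed by accession or prefix
  psms <- toy_psms()
  psms$protein_accession[psms$protein_accession == "P3"] <- "CON_TRYP"
  filt2 <- filter_identifications(psms, contaminant_prefix = "CON_")
  expect_false(any(startsWith(filt2$protein_accession, "CON_")))

  expect_warning(
    out <- filter_identifications(toy_psms(), pep_e_max = 1e-10),
    "no PSMs")
  expect_equal(nrow(out), 0)
})

test_that("filtering its own output is a fixed point", {
  filt <- filter_identifications(toy_psms())
  expect_identical(filter_identifications(filt), filt)
})

test_that("shared peptides group proteins; specific peptides define subgroups", {
  psms <- data.frame(
    peptide_sequence = c("p1", "p1", "p2", "x1", "x2", "y1", "y2"),
    peptide_evalue = 1e-4,
    protein_accession = c("A", "B", "A", "A", "B", "B", "A"),
    protein_evalue = 1e-6, sample_id = "S1", spectra = 1L,
    stringsAsFactors = FALSE)
  gr <- group_proteins(psms)
  expect_equal(length(unique(gr$groups$group_id)), 1)
  a <- gr$groups[gr$groups$accession == "A", ]
  b <- gr$groups[gr$groups$accession == "B", ]
  expect_true(a$is_subgroup)   # p2, x1, y2 specific to A
  expect_true(b$is_subgroup)   # x2, y1 specific to B
  expect_equal(a$n_specific_peptides, 3L)

  # a member with no specific peptide is not a subgroup
  psms2 <- psms[psms$peptide_sequence %in% c("p1", "p2", "x1"), ]
  gr2 <- group_proteins(psms2)
  expect_true(gr2$groups$is_subgroup[gr2$groups$accession == "A"])
  expect_false(gr2$groups$is_subgroup[gr2$groups$accession == "B"])
})

test_that("grouping matches a union-find oracle on random fixtures", {
  for (seed in 1:8) {
    psms <- random_psm_fixture(n_proteins = sample(5:50, 1),
                               n_peptides = 60, seed = seed)
    gr <- group_proteins(psms)
    got <- split(gr$groups$accession, gr$groups$group_id)
    want <- oracle_components(psms)
    norm <- function(l) unname(lapply(l, sort))[order(vapply(l, min, ""))]
    expect_equal(norm(got), norm(want))
  }
})

test_that("grouping is order-independent and idempotent", {
  psms <- random_psm_fixture(25, 40, seed = 99)
  gr1 <- group_proteins(psms)
  set.seed(1)
  gr2 <- group_proteins(psms[sample(nrow(psms)), ])
  expect_equal(gr1$groups, gr2$groups)
})

test_that("count matrix sums spectra per subgroup and sample", {
  mk <- function(acc, pep, sample, spectra) {
    data.frame(peptide_sequence = pep, peptide_evalue = 1e-4,
               protein_accession = acc, protein_evalue = 1e-6,
               sample_id = sample, spectra = spectra,
               stringsAsFactors = FALSE)
  }
  psms <- rbind(mk("A", "a1", c("S1", "S3"), c(3L, 5L)),
                mk("A", "a2", "S1", 0L)[0, ],  # no zero rows in input
                mk("B", "b1", c("S1", "S2"), c(2L, 4L)),
                mk("B", "b2", "S2", 1L),
                mk("A", "a2", "S2", 0L)[0, ])
  design <- data.frame(sample_id = c("S1", "S2", "S3"),
                       group = c("CORT/V", "CORT/Flx-R", "CORT/Flx-NR"))
  gr <- group_proteins(psms)
  cm <- build_count_matrix(psms, gr, design)
  expect_equal(unname(cm$counts["A", ]), c(3L, 0L, 5L))
  expect_equal(unname(cm$counts["B", ]), c(2L, 5L, 0L))
  # conservation: total equals total spectra of specific peptides
  expect_equal(sum(cm$counts), sum(psms$spectra))

  design_bad <- design[1:2, ]
  expect_error(build_count_matrix(psms, gr, design_bad), "group label")
})

test_that("unique-only mode never counts a shared spectrum twice", {
  psms <- data.frame(
    peptide_sequence = c("sh", "sh", "a1", "a2", "b1", "b2"),
    peptide_evalue = 1e-4,
    protein_accession = c("A", "B", "A", "A", "B", "B"),
    protein_evalue = 1e-6, sample_id = "S1",
    spectra = c(10L, 10L, 1L, 2L, 3L, 4L), stringsAsFactors = FALSE)
  design <- data.frame(sample_id = "S1", group = "CORT/V")
  gr <- group_proteins(psms)
  cm <- build_count_matrix(psms, gr, design)
  expect_equal(unname(cm$counts["A", "S1"]), 3L)
  expect_equal(unname(cm$counts["B", "S1"]), 7L)

  # group-level mode adds one group row counting the shared spectra once
  cmg <- build_count_matrix(psms, gr, design, shared = "group-level")
  grow <- cmg$counts[startsWith(rownames(cmg$counts), "group:"), ]
  expect_equal(unname(grow), 3L + 7L + 10L)
})

test_that("matrix construction agrees with direct per-protein sums", {
  sim <- simulate_psms(proteome_sim_config(n_proteins = 30, seed = 31))
  filt <- filter_identifications(sim$psms)
  gr <- group_proteins(filt)
  cm <- build_count_matrix(filt, gr, sim$design)
  # recompute one protein x sample cell by hand
  spec_peps <- names(which(table(unique(filt[, c("peptide_sequence",
                                                 "protein_accession")])$peptide_sequence) == 1))
  acc <- rownames(cm$counts)[5]
  s <- colnames(cm$counts)[3]
  manual <- sum(filt$spectra[filt$protein_accession == acc &
                               filt$sample_id == s &
                               filt$peptide_sequence %in% spec_peps])
  expect_equal(unname(cm$counts[acc, s]), manual)
})
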