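# Phosphosite catalog: loading, validation, summaries, differential and
# novelty classification, m/z concordance.

test_that("catalog loading parses the packaged site table", {
  cat1 <- table1()
  expect_equal(nrow(cat1), 73)
  first <- cat1[cat1$row == 1, ]
  expect_identical(first$accession, "P02511")
  expect_equal(first$frag_start, 12L)
  expect_equal(first$frag_end, 22L)
  expect_identical(first$designation, "Ser-19")
  expect_identical(first$peptide, "RPFFPFHSPSR")
})

test_that("fragment ranges accept hyphen or en-dash and reject inversions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tprotein_name\tfragment\tpeptide\tdesignation",
               "P02511\tAlpha-crystallin B\t12–22\tRPFFPFHSPSR\tSer-19",
               "P02511\tAlpha-crystallin B\t57-69\tAPSWFDTGLSEMR\tSer-59"),
             path)
  cat <- load_catalog(path)
  expect_equal(cat$frag_start, c(12L, 57L))
  expect_equal(cat$frag_end, c(22L, 69L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tprotein_name\tfragment\tpeptide\tdesignation",
               "P02511\tAlpha-crystallin B\t22-12\tRPFFPFHSPSR\tSer-19"),
             bad)
  expect_error(load_catalog(bad), "inverted fragment range.*1")

  nofrag <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tprotein_name\tpeptide",
               "P02511\tAlpha-crystallin B\tRPFFPFHSPSR"), nofrag)
  expect_error(load_catalog(nofrag), "missing mandatory column")
})

test_that("validation reports in-table inconsistencies without dropping rows", {
  report <- validate_catalog(table1())
  warns <- report[report$status == "warn", ]
  # the aldolase C row designates a position outside its printed fragment
  expect_equal(nrow(warns), 1)
  expect_identical(warns$accession, "P09972")
  expect_identical(warns$designation, "Ser-26")
  expect_identical(warns$check, "designation_in_fragment")

  # residue mismatch: position 20 of the 12-22 fragment is P, not S
  cat <- table1()[1, ]
  cat$designation <- "Ser-20"
  rep2 <- validate_catalog(cat)
  mism <- rep2[rep2$check == "designation_residue", ]
  expect_identical(mism$status, "warn")
  expect_match(mism$detail, "'P', expected 'S'")
})

test_that("validation checks peptides against protein sequences when given", {
  prot <- c(SYN1 = "AAARPFFPFHSPSRGGG")
  cat <- tibble::tibble(row = 1:2, accession = "SYN1", protein_name = "syn",
                        is_crystallin = FALSE,
                        frag_start = c(4L, 4L), frag_end = c(14L, 14L),
                        peptide = c("RPFFPFHSPSR", "RPFFPFHSPSX"),
                        designation = c("Ser-11", "Ser-11"))
  rep <- validate_catalog(cat, prot)
  pp <- rep[rep$check == "peptide_in_protein", ]
  expect_identical(pp$status, c("pass", "warn"))
})

test_that("summary counts sites, proteins and residue distribution", {
  toy <- tibble::tibble(
    row = 1:4, accession = "P1", protein_name = "toy protein",
    is_crystallin = FALSE, frag_start = 1L, frag_end = 20L,
    peptide = "SASATAYAAAAAAAAAAAAA",
    designation = c("Ser-1", "Ser-3", "Thr-5", "Tyr-7"))
  s <- summarize_catalog(toy)
  expect_equal(s$n_sites, 4)
  expect_equal(s$residues$pct, c(50, 25, 25))

  s1 <- summarize_catalog(table1())
  expect_equal(s1$n_sites, 73)
  expect_equal(s1$n_proteins, 32)
  expect_equal(s1$n_crystallin, 9)
  expect_equal(s1$n_noncrystallin, 23)
  expect_equal(s1$residues$n, c(52L, 18L, 3L))
  expect_equal(s1$residues$pct, c(71.2, 24.7, 4.1))
  expect_equal(s1$residues$pct_int, c(71L, 25L, 4L))
  expect_error(summarize_catalog(table1()[0, ]), "empty")
})

test_that("summary counts each site once regardless of observation multiplicity", {
  cat1 <- table1()
  dup <- dplyr::bind_rows(cat1, cat1[rep(1:10, 3), ])
  s <- summarize_catalog(dup)
  expect_equal(s$n_sites, 73)
  expect_equal(s$residues$n, c(52L, 18L, 3L))
})

test_that("differential classification uses median aggregation and a strict boundary", {
  toy <- tibble::tibble(
    row = 1:3, accession = c("A", "B", "C"), protein_name = "p",
    is_crystallin = FALSE, frag_start = 1L, frag_end = 9L,
    peptide = "SAAAAAAAK", designation = "Ser-1",
    pn_ratio = c(2.0, 0.5, 1.0))
  d <- classify_differential(toy, 2)
  expect_equal(d$counts$increased, 1)
  expect_equal(d$counts$decreased, 1)
  expect_equal(d$counts$unchanged, 1)

  d2 <- classify_differential(table2(), 2)
  expect_equal(d2$counts$n_sites, 28)
  expect_equal(d2$counts$n_proteins, 19)
  expect_equal(d2$counts$increased, 14)
  expect_equal(d2$counts$decreased, 12)
  expect_equal(d2$counts$unchanged, 2)

  # the two multi-observation sites aggregate by median
  sites <- d2$sites
  expect_equal(sites$ratio[sites$accession == "P53674" &
                             sites$designation == "Ser-81"],
               median(c(0.40, 0.46)))
  expect_equal(sites$ratio[sites$accession == "P07320" &
                             sites$designation == "Ser-75"],
               median(c(0.47, 0.21)))
  expect_error(classify_differential(table1()), "pn_ratio")
  expect_error(classify_differential(table2(), fold_threshold = 1), "> 1")
})

test_that("differential classification is invariant to row order and duplication", {
  cat2 <- table2()
  base <- classify_differential(cat2, 2)$counts
  shuf <- classify_differential(cat2[rev(seq_len(nrow(cat2))), ], 2)$counts
  dup <- classify_differential(dplyr::bind_rows(cat2, cat2), 2)$counts
  expect_identical(shuf, base)
  expect_identical(dup[c("n_sites", "increased", "decreased", "unchanged")],
                   base[c("n_sites", "increased", "decreased", "unchanged")])
})

test_that("novelty comparison against the known-site list", {
  cat2 <- table2()
  nv <- compare_novelty(cat2, fixture_path("known_sites_synthetic.tsv"))
  expect_equal(nv$counts$n_sites, 28)
  expect_equal(nv$counts$n_novel, 20)
  expect_equal(nv$counts$n_novel_crystallin, 14)
  expect_equal(nv$counts$n_crystallin_proteins_with_novel, 7)

  # agrees with the table's own novelty column, site by site
  printed <- dplyr::distinct(cat2, accession, designation, novel)
  merged <- dplyr::inner_join(nv$records, printed,
                              by = c("accession", "designation"),
                              suffix = c("_computed", "_printed"))
  expect_equal(nrow(merged), 28)
  expect_identical(merged$novel_computed, merged$novel_printed)

  all_novel <- compare_novelty(cat2, tibble::tibble(accession = character(),
                                                    designation = character()))
  expect_equal(all_novel$counts$n_novel, 28)
})

test_that("m/z concordance against printed observed values", {
  conc <- mz_concordance(table2())
  expect_equal(nrow(conc), 30)
  expect_true(all(abs(conc$delta_th) < 0.05))
  s <- attr(conc, "summary")
  expect_lt(s$median_abs_delta, 0.02)

  target <- conc[conc$peptide == "RPFFPFHSPSR", ]
  expect_lt(abs(target$delta_th), 0.02)

  # Met-containing peptides may match with variable oxidation states
  ox <- conc[conc$n_oxidation > 0, ]
  expect_true(all(grepl("M", ox$peptide)))
  expect_true(all(abs(mz_concordance(table2(), variable_oxidation = FALSE) |>
                        dplyr::filter(!grepl("M", .data$peptide)) |>
                        dplyr::pull(delta_th)) < 0.05))
})

test_that("m/z concordance is exact for records built from theory, and skips chargeless rows", {
  pep <- "GSKAAR"
  mz_theo <- mass_to_mz(peptide_mass(pep) + mod_phospho()$delta, 2)
  cat <- tibble::tibble(row = 1:2, accession = "SYN1", protein_name = "syn",
                        is_crystallin = FALSE, frag_start = 1L, frag_end = 6L,
                        peptide = pep, designation = "Ser-2",
                        mz = c(mz_theo, mz_theo), charge = c(2L, NA))
  expect_message(conc <- mz_concordance(cat), "skipping 1")
  expect_equal(nrow(conc), 1)
  expect_equal(conc$delta_th, 0, tolerance = 1e-12)
  expect_identical(attr(conc, "skipped"), 2L)
})
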