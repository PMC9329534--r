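test_that("insert mass and octanol hydrophobicity are additive and match the published insert table", {
  # (label, repeats, mass Da, pI, WW octanol kcal/mol) for the six inserts
  rows <- list(
    list("SPLAT", 1L, 469.54, 5.24, 0.10),
    list("SPLAT", 2L, 939.08, 5.24, 0.20),
    list("SPLAT", 4L, 1878.16, 5.24, 0.40),
    list("AGPGA", 1L, 353.38, 5.57, 3.44),
    list("AGPGA", 2L, 706.76, 5.57, 6.88),
    list("AGPGA", 4L, 1413.52, 5.57, 13.76)
  )
  for (r in rows) {
    expect_equal(round(insert_mass(r[[1]], r[[2]]), 2), r[[3]])
    expect_equal(round(isoelectric_point(strrep(r[[1]], r[[2]])), 2), r[[4]])
    expect_equal(round(ww_octanol(r[[1]], r[[2]]), 2), r[[5]])
  }
  # exact linearity in repeats
  for (s in c("SPLAT", "AGPGA", "WYDEK")) {
    for (n in c(2L, 3L, 7L)) {
      expect_identical(insert_mass(s, n), n * insert_mass(s))
      expect_identical(ww_octanol(s, n), n * ww_octanol(s))
    }
  }
  # single residue equals its scale entry; leucine pentamer by hand
  expect_equal(insert_mass("G"), 57.05)
  expect_equal(ww_octanol("LLLLL"), -6.25)
})

test_that("unknown residue codes are rejected by name", {
  expect_error(insert_mass("SPLAXT"), "'X'")
  expect_error(ww_octanol("AGB"), "'B'")
  expect_error(isoelectric_point(""), "non-empty")
})

test_that("pI bisection agrees with a dense pH-grid scan of the same charge function", {
  peptides <- c("SPLAT", "AGPGA", "DAK", "KKDDE", "HRCY", "GGDG", "MKTAYIAK")
  for (p in peptides) {
    expect_equal(isoelectric_point(p), grid_pi(p), tolerance = 0.005)
  }
  # the net-charge function is strictly decreasing in pH
  for (p in peptides) {
    q <- peptide_charge(p, seq(0, 14, by = 0.25))
    expect_true(all(diff(q) < 0))
  }
  # pI is invariant under concatemerization without ionizable side chains
  expect_equal(isoelectric_point("SPLATSPLAT"), isoelectric_point("SPLAT"),
               tolerance = 0.005)
})

test_that("extinction coefficient follows the Trp/Tyr/cystine counting rule", {
  expect_identical(extinction_coefficient("WY"), 6990L)
  expect_identical(extinction_coefficient("AGPLST"), 0L)
  expect_identical(extinction_coefficient("CC", n_cystine = 1L), 125L)
  # packaged mature OmpX: 148 residues, 2 Trp + 16 Tyr, no Cys
  seq <- ompx_mature()
  res <- strsplit(seq, "")[[1]]
  expect_identical(nchar(seq), 148L)
  expect_identical(sum(res == "W"), 2L)
  expect_identical(sum(res == "Y"), 16L)
  expect_identical(sum(res == "C"), 0L)
  expect_identical(extinction_coefficient(seq), 34840L)
})

test_that("construct building inserts after the loop midpoints and preserves flanks", {
  base <- ompx_mature()
  wt <- build_construct(base)
  expect_identical(as.character(wt), base)

  one <- build_construct(base, tibble::tibble(loop = 2, insert = "SPLAT",
                                              repeats = 1))
  spans1 <- attr(one, "loop_spans")
  expect_identical(spans1$`2`, 49:64)
  expect_identical(spans1$`3`, 96:108)
  one <- as.character(one)
  expect_identical(nchar(one), nchar(base) + 5L)
  expect_identical(substr(one, 1, 54), substr(base, 1, 54))
  expect_identical(substr(one, 55, 59), "SPLAT")
  expect_identical(substr(one, 60, nchar(one)), substr(base, 55, nchar(base)))

  both <- build_construct(base, tibble::tibble(loop = c(2, 3),
                                               insert = "AGPGA", repeats = 4))
  expect_identical(nchar(both), nchar(base) + 40L)
  spans <- attr(both, "loop_spans")
  expect_identical(spans$`2`, 49:79)       # 11 + 20 inserted residues
  expect_identical(spans$`3`, (91:123) + 20L)

  expect_error(build_construct(base, tibble::tibble(loop = 4, insert = "A",
                                                    repeats = 1)), "loop")
  expect_error(build_construct(base, tibble::tibble(loop = c(2, 2),
                                                    insert = "A",
                                                    repeats = 1)),
               "one insert block")
})

test_that("insert property tables and FASTA round-trips work end to end", {
  tab <- insert_properties(tibble::tibble(insert = c("SPLAT", "AGPGA"),
                                          repeats = c(2L, 2L)))
  expect_equal(tab$mass_da, c(939.08, 706.76))
  expect_equal(tab$ww_octanol_kcal_mol, c(0.20, 6.88))

  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(WT = ompx_mature(), SPLATx2_L3 = as.character(
    build_construct(inserts = tibble::tibble(loop = 3, insert = "SPLAT",
                                             repeats = 2))))
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_identical(unname(back), unname(seqs))
  expect_identical(names(back), names(seqs))
})
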