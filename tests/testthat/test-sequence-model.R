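test_that("mutation strings parse into ordered mutation sets", {
  m <- parseMutations("E6Q_Q13K_K94R", "H")
  expect_equal(m$position, c("6", "13", "94"))
  expect_equal(m$wt, c("E", "Q", "K"))
  expect_equal(m$mut, c("Q", "K", "R"))
  expect_equal(m$chain, rep("H", 3))

  m2 <- parseMutations("D52aN_K94R", "H")
  expect_equal(m2$position, c("52a", "94"))

  ## insertion codes are case-insensitive
  expect_equal(parseMutations("d52AN", "H")$position, "52a")

  ## chain aliases resolve to an empty mutation set
  a <- parseMutations("AB-001_LC", "L")
  expect_equal(nrow(a), 0L)
  expect_equal(attr(a, "alias"), "AB-001_LC")

  expect_error(parseMutations("E6", "H"), "malformed")
  expect_error(parseMutations("E6Q_??", "H"), "malformed")
  expect_error(parseMutations("E6E", "H"), "wild-type equals mutant")
})

test_that("parse/format round-trips and mutation inversion restores chains", {
  specs <- c("E6Q_Q13K_K94R", "D52aN_K94R", "N53K", "Q100bR_K94R")
  for (s in specs) {
    m <- parseMutations(s, "H")
    expect_identical(formatMutations(m), s)
    expect_identical(formatMutations(parseMutations(formatMutations(m), "H")),
                     s)
  }
  vl <- par_chains$VL
  m <- parseMutations("E3V_T18R_N53K", "L")
  mutated <- applyMutations(vl, m)
  restored <- applyMutations(mutated, invertMutations(m))
  expect_identical(chainSequence(restored), chainSequence(vl))
  expect_identical(positionLabels(restored), positionLabels(vl))
})

test_that("applyMutations validates the wild type and preserves labels", {
  vl <- par_chains$VL
  out <- applyMutations(vl, parseMutations("N53K", "L"))
  expect_equal(residueAt(out, "53"), "K")
  expect_equal(length(out), length(vl))
  expect_identical(positionLabels(out), positionLabels(vl))
  ## untouched elsewhere
  same <- positionLabels(vl) != "53"
  expect_identical(residueAt(out, positionLabels(vl)[same]),
                   residueAt(vl, positionLabels(vl)[same]))

  ## identity on the empty set
  expect_identical(chainSequence(applyMutations(vl, parseMutations("AB-001_LC", "L"))),
                   chainSequence(vl))

  ## the guard that validates the numbering fixture
  expect_error(applyMutations(vl, parseMutations("D53K", "L")),
               "expected D, found N")
  expect_error(applyMutations(vl, parseMutations("N999K", "L")),
               "unknown position")
})

test_that("region annotation partitions the chain at Kabat boundaries", {
  for (ch in par_chains) {
    reg <- annotateRegions(ch)
    expect_identical(reg$position, positionLabels(ch))  # exactly once each
    expect_setequal(unique(reg$region),
                    c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"))
  }
  regL <- annotateRegions(par_chains$VL)
  cdr2 <- regL[regL$region == "CDR2", ]
  expect_equal(cdr2$position, as.character(50:56))
  expect_equal(cdr2$residue, c("D", "D", "S", "N", "R", "P", "S"))

  regH <- annotateRegions(par_chains$VH)
  expect_equal(regH$region[regH$position == "52a"], "CDR2")
  expect_equal(regH$residue[regH$position == "52a"], "D")
  expect_equal(regH$region[regH$position == "100b"], "CDR3")
  expect_equal(regH$residue[regH$position == "100b"], "Q")
  ## CDR-H2 spans 17 residues, CDR-H3 11, via the insertion codes
  expect_equal(sum(regH$region == "CDR2"), 17L)
  expect_equal(sum(regH$region == "CDR3"), 11L)
})

test_that("framework-1 germline swap yields the four documented changes", {
  vl <- par_chains$VL
  fw1 <- swapFramework1(vl, germlineFR1())
  expect_equal(nrow(fw1), 4L)
  ## linear positions 3, 13, 16, 19; Kabat labels shift by the gap at 10
  expect_equal(fw1$wt, c("E", "S", "Q", "S"))
  expect_equal(fw1$mut, c("V", "A", "K", "R"))
  expect_equal(fw1$position, c("3", "14", "17", "20"))

  ## self-swap is empty; length mismatch is an error
  reg <- annotateRegions(vl)
  own_fr1 <- paste(reg$residue[reg$region == "FR1"], collapse = "")
  expect_equal(nrow(swapFramework1(vl, own_fr1)), 0L)
  expect_error(swapFramework1(vl, substr(germlineFR1(), 1, 10)), "length")
})

test_that("every panel variant builds with zero wild-type mismatches", {
  ## one property that certifies the whole numbering fixture against the
  ## published mutation table
  for (nm in panel$name) {
    v <- buildVariant(nm, panel)
    expect_s4_class(v$VH, "NumberedChain")
    expect_equal(length(v$VH), 120L)
    expect_equal(length(v$VL), 106L)
  }
  ## spot-check resolved residues
  v <- buildVariant("R1-016", panel)
  expect_equal(residueAt(v$VH, c("6", "13", "94")), c("Q", "K", "R"))
  expect_equal(residueAt(v$VL, "53"), "K")
  v2 <- buildVariant("R2-006", panel)
  expect_equal(residueAt(v2$VL, "52"), "K")
  expect_equal(residueAt(v2$VL, "3"), "V")    # carries the FR1 swap
  expect_error(buildVariant("R9-999", panel), "unknown variant")
})

test_that("parental fixture loader checks sequences and numbering", {
  p <- parentalChains()
  expect_equal(residueAt(p$VH, "52a"), "D")
  expect_equal(residueAt(p$VL, "53"), "N")
  expect_equal(residueAt(p$VL, "18"), "T")   # lambda gap at position 10
  expect_false("10" %in% positionLabels(p$VL))
  expect_equal(chainRole(p$VH), "VH")
})

test_that("FASTA round-trip preserves sequences and roles", {
  tmp <- tempfile(fileext = ".fasta")
  writeChainFasta(list(`AB-001_VH` = par_chains$VH,
                       `AB-001_VL` = par_chains$VL), tmp)
  back <- readChainFasta(tmp)
  expect_equal(chainSequence(back$`AB-001_VH`), chainSequence(par_chains$VH))
  expect_equal(chainRole(back$`AB-001_VL`), "VL")
  unlink(tmp)
})
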