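test_that("variant tokens parse to normalized variants", {
  v <- parseVariantToken("129", "HVRI")
  expect_equal(v$position, 16129L)
  expect_equal(v$kind, "substitution")
  expect_equal(v$alleles, "")

  v <- parseVariantToken("309.2", "HVRII")
  expect_equal(v$position, 309L)
  expect_equal(v$insertIndex, 2L)
  expect_equal(v$kind, "insertion")
  expect_equal(v$alleles, "C")

  v <- parseVariantToken("318A/C", "HVRI")
  expect_equal(v$position, 16318L)
  expect_equal(v$alleles, "A/C")
  # allele order is canonicalised
  expect_equal(parseVariantToken("318C/A", "HVRI")$alleles, "A/C")

  # both deletion dialects and explicit insertions
  expect_equal(parseVariantToken("193del", "HVRI")$position, 16193L)
  expect_equal(parseVariantToken("193d", "HVRI")$kind, "deletion")
  vi <- parseVariantToken("196insT", "HVRII")
  expect_equal(vi$kind, "insertion")
  expect_equal(vi$alleles, "T")

  expect_error(parseVariantToken("16570", "HVRII"), "range")
  expect_error(parseVariantToken("abc", "HVRI"), "malformed")
})

test_that("haplotype rows parse with '0' meaning rCRS identity", {
  h <- hap("J1", "0", "263 309.1 315.1")
  v <- variantTable(h)
  expect_equal(sum(v$region == "HVRI"), 0L)
  expect_equal(sum(v$region == "HVRII"), 3L)

  h4 <- hap("J4", "0", "263 315.1", "3010")
  v4 <- variantTable(h4)
  expect_equal(v4$position[v4$region == "CODING"], 3010L)

  expect_error(hap("X", "129 129", ""), "duplicate")
})

test_that("canonical rendering round-trips through the parser", {
  ej <- loadElJadida()
  v <- variantTable(ej)
  for (i in seq_len(nrow(v))) {
    tok <- renderVariant(v[i, , drop = FALSE])
    re <- parseVariantToken(tok, v$region[i])
    expect_equal(re$position, v$position[i])
    expect_equal(re$insertIndex, v$insertIndex[i])
    expect_equal(re$kind, v$kind[i])
    expect_equal(re$alleles, v$alleles[i])
  }
})

test_that("the HVRI 16000 offset restoration is an involution", {
  toks <- c("129", "304", "318A/C", "193del", "355")
  for (tok in toks) {
    v <- parseVariantToken(tok, "HVRI")
    expect_equal(renderVariant(v), tok)
    # absolute coordinates pass through untouched
    va <- parseVariantToken(as.character(v$position), NA_character_)
    expect_equal(va$position, v$position)
  }
})

test_that("population table IO round-trips the fixture", {
  ej <- loadElJadida()
  tmp <- tempfile(fileext = ".tsv")
  writePopulationTable(ej, tmp, header = "round-trip test")
  back <- readPopulationTable(tmp)
  expect_equal(sampleIDs(back), sampleIDs(ej))
  expect_equal(haplogroups(back), haplogroups(ej))
  vo <- variantTable(ej); vb <- variantTable(back)
  o <- order(vo$sample_id, vo$region, vo$position, vo$insertIndex)
  b <- order(vb$sample_id, vb$region, vb$position, vb$insertIndex)
  expect_equal(vo[o, ], vb[b, ], ignore_attr = TRUE)
})

test_that("the packaged survey loads with 81 labelled haplotypes", {
  ej <- loadElJadida()
  expect_equal(length(ej), 81L)
  expect_equal(sampleIDs(ej)[1L], "J1")
  expect_true(all(!is.na(haplogroups(ej))))
  expect_true(all(nzchar(haplogroups(ej))))
})

test_that("haplotype distance matches hand counts from the survey", {
  ej <- loadElJadida()
  pol <- defaultPolicy()
  # J5 HVRI "0" vs J9 HVRI "209": one difference
  expect_equal(haplotypeDistance(ej["J5"], ej["J9"], pol), 1L)
  # J2 "129 184" vs J3 "304": symmetric difference of size 3
  expect_equal(haplotypeDistance(ej["J2"], ej["J3"], pol), 3L)
  # identity
  expect_equal(haplotypeDistance(ej["J7"], ej["J7"], pol), 0L)
})

test_that("distance is a pseudo-metric on the survey", {
  ej <- loadElJadida()
  d <- distanceMatrix(ej)
  expect_true(all(d == t(d)))
  expect_true(all(diag(d) == 0))
  # triangle inequality over all 81^3 triples
  for (k in seq_len(nrow(d))) {
    expect_true(all(d <= outer(d[, k], d[k, ], `+`) + 1e-9))
  }
})

test_that("policy toggles change what is counted", {
  a <- hap("a", "189 193del", "0")
  b <- hap("b", "189", "0")
  expect_equal(haplotypeDistance(a, b, distancePolicy(countIndels = FALSE)), 0L)
  expect_equal(haplotypeDistance(a, b, distancePolicy(countIndels = TRUE)), 1L)
  # heteroplasmies count against rCRS and unlike states, not identical ones
  x <- hap("x", "183A/C", "0"); y <- hap("y", "0", "0")
  z <- hap("z", "183A/C", "0"); w <- hap("w", "183", "0")
  expect_equal(haplotypeDistance(x, y, defaultPolicy()), 1L)
  expect_equal(haplotypeDistance(x, z, defaultPolicy()), 0L)
  expect_equal(haplotypeDistance(x, w, defaultPolicy()), 1L)
  expect_equal(haplotypeDistance(x, y, distancePolicy(countAmbiguous = FALSE)),
               0L)
  # excluded positions are removed before counting
  expect_equal(haplotypeDistance(x, y,
               distancePolicy(excludedPositions = 16183L)), 0L)
})
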