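test_that("CSV parsing canonicalizes heterozygous calls and accepts shorthand", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,m1,m2", "s1,AA,AG", "s2,GA,GG"), f)
  g <- read_genotype_csv(f)
  expect_equal(g$calls["s1", "m2"], "AG")
  expect_equal(g$calls["s2", "m1"], "AG")  # GA stored canonically

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,m1", "s1,A", "s2,G"), f2)
  expect_equal(unname(read_genotype_csv(f2)$calls[, 1]), c("AA", "GG"))
  expect_error(read_genotype_csv(f2, homozygous_shorthand = FALSE), "shorthand")
})

test_that("invalid genotype matrices are rejected with informative errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,m1,m2", "s1,AA,NA", "s2,AG,GG"), f)
  expect_error(read_genotype_csv(f), "missing genotype at \\(s1, m2\\)")

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,m1", "s1,AC", "s2,GG"), f2)
  expect_error(read_genotype_csv(f2), "marker m1 has more than 2 alleles")

  f3 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,m1", "s1,AA", "s1,AG"), f3)
  expect_error(read_genotype_csv(f3), "duplicate sample id")
})

test_that("CSV write/read round-trips random fixtures exactly", {
  for (seed in 1:3) {
    g <- simulate_genotypes(5 + seed, 3 + 2 * seed, seed = seed)
    g2 <- read_genotype_csv(write_fixture_csv(g))
    expect_equal(g2$calls, g$calls)
    expect_equal(g2$sample_ids, g$sample_ids)
    expect_equal(g2$marker_ids, g$marker_ids)
  }
})

test_that("PLINK text parsing follows the PED/MAP conventions", {
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  writeLines("FAM1 IND1 0 0 0 -9 A A G T", ped)
  writeLines(c("1 mk1 0 100", "1 mk2 0 200"), map)
  g <- read_genotype_plink(ped, map)
  expect_equal(dim(g), c(1L, 2L))
  expect_equal(g$sample_ids, "IND1")
  expect_equal(unname(g$calls[1, ]), c("AA", "GT"))
  expect_equal(g$chrom_pos$pos, c(100, 200))

  writeLines("FAM1 IND1 0 0 0 -9 A A 0 T", ped)
  expect_error(read_genotype_plink(ped, map), "missing genotype not allowed")

  writeLines(c("1 mk1 0 100", "1 mk2 0 200", "1 mk3 0 300"), map)
  writeLines("FAM1 IND1 0 0 0 -9 A A G T", ped)
  expect_error(read_genotype_plink(ped, map), "mismatch")
})

test_that("PLINK write/read round-trips a random fixture", {
  g <- simulate_genotypes(8, 6, seed = 11)
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  write_genotype_plink(g, ped, map)
  g2 <- read_genotype_plink(ped, map)
  expect_equal(g2$calls, g$calls)
  expect_equal(g2$marker_ids, g$marker_ids)
})

test_that("phenotype traits are typed by the discrete/continuous rule", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,disease,yield",
               "s1,0,1.2", "s2,1,3.4", "s3,0,2.2", "s4,1,9.0"), f)
  ph <- read_phenotype_csv(f)
  expect_equal(unname(trait_types(ph)), c("discrete", "continuous"))
  expect_equal(trait_types(ph)[["disease"]], "discrete")
  expect_error(read_phenotype_csv(f, traits = "height"),
               "height.*Available traits.*yield")
  # many distinct integer levels exceed the class-count limit
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,t", paste0("s", 1:20, ",", 1:20)), f2)
  expect_equal(unname(trait_types(read_phenotype_csv(f2))), "continuous")
  expect_equal(unname(trait_types(read_phenotype_csv(f2, max_discrete_levels = 25))),
               "discrete")
})
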