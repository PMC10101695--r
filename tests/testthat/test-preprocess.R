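test_that("MAF matches hand allele counts and the brute-force oracle", {
  g <- raw_genotype(matrix(c("AA", "AG", "GG", "GG", "AG"), ncol = 1),
                    paste0("s", 1:5), "m1")
  expect_equal(unname(compute_maf(g)), 0.4)   # G dosage 6/10, A 4/10

  const <- raw_genotype(matrix(rep("AA", 4), ncol = 1), paste0("s", 1:4), "m1")
  expect_equal(unname(compute_maf(const)), 0)

  for (seed in 1:3) {
    g <- simulate_genotypes(25, 50, maf_range = c(0.01, 0.5), seed = seed)
    expect_equal(unname(compute_maf(g)), brute_force_maf(g))
  }
})

test_that("MAF filtering is strict and monotone in the threshold", {
  # markers engineered to MAF 0.0, 0.05, 0.25 over 10 samples
  calls <- cbind(rep("AA", 10),
                 c("AG", rep("AA", 9)),
                 c(rep("AG", 5), rep("AA", 5)))
  g <- raw_genotype(calls, paste0("s", 1:10), paste0("m", 1:3))
  expect_equal(unname(compute_maf(g)), c(0, 0.05, 0.25))
  expect_equal(sum(maf_filter(g, 0.1)$keep), 1L)
  expect_equal(unname(maf_filter(g, 0)$keep), c(FALSE, TRUE, TRUE))
  expect_equal(sum(maf_filter(g, 0.5)$keep), 0L)
  expect_equal(sum(maf_filter(g, 0.05)$keep), 1L)  # strict: MAF == t is dropped
  expect_error(maf_filter(g, 0.6), "0, 0.5")

  g2 <- simulate_genotypes(50, 80, seed = 7)
  thresholds <- c(0, 0.05, 0.1, 0.2, 0.3)
  masks <- lapply(thresholds, function(t) maf_filter(g2, t)$keep)
  for (i in seq_len(length(masks) - 1L)) {
    # a marker surviving the higher threshold must survive every lower one
    expect_true(all(which(masks[[i + 1L]]) %in% which(masks[[i]])))
  }
})

test_that("additive encoding counts minor-allele copies with the stated tie-break", {
  calls <- matrix(c("AA", "AA", "AG", "GG"), ncol = 1)
  g <- raw_genotype(calls, paste0("s", 1:4), "m1")   # A freq 5/8, G minor
  enc <- encode_additive(g)
  expect_equal(unname(enc$matrix[, 1]), c(0, 0, 1, 2))
  expect_equal(unname(enc$minor_allele), "G")

  tie <- raw_genotype(matrix(c("CC", "TT"), ncol = 1), c("s1", "s2"), "m1")
  enc_tie <- encode_additive(tie)
  expect_equal(unname(enc_tie$minor_allele), "C")    # lexicographic tie-break
  expect_equal(unname(enc_tie$matrix[, 1]), c(2, 0))

  const <- raw_genotype(matrix(rep("AA", 3), ncol = 1), paste0("s", 1:3), "m1")
  expect_equal(unname(encode_additive(const)$matrix[, 1]), c(0, 0, 0))
})

test_that("additive encoding is invertible given the stored polarity", {
  g <- simulate_genotypes(30, 20, seed = 9)
  enc <- encode_additive(g)
  # decode: dosage + minor/major alleles reconstruct the canonical call
  for (j in seq_len(20)) {
    minor <- enc$minor_allele[j]; major <- enc$major_allele[j]
    decoded <- vapply(enc$matrix[, j], function(d) {
      alleles <- c(rep(major, 2 - d), rep(minor, d))
      paste(sort(alleles), collapse = "")
    }, character(1))
    expect_equal(unname(decoded), unname(g$calls[, j]))
  }
  # re-encoding new data with the stored polarity reproduces the matrix
  expect_equal(encode_additive_with_polarity(g, enc$minor_allele), enc$matrix)
})

test_that("one-hot blocks are indicators with the fixed class order", {
  calls <- matrix(c("AA", "AG", "GG", "AA"), ncol = 1)
  g <- raw_genotype(calls, paste0("s", 1:4), "m1")
  oh <- encode_onehot(g)
  expect_equal(colnames(oh$matrix), c("m1__homMaj", "m1__het", "m1__homMin"))
  expect_equal(unname(oh$matrix[2, ]), c(0, 1, 0))

  # no heterozygote observed -> 2-column block
  g2 <- raw_genotype(matrix(c("AA", "GG", "GG"), ncol = 1), paste0("s", 1:3), "m1")
  expect_equal(ncol(encode_onehot(g2)$matrix), 2L)

  g3 <- simulate_genotypes(40, 15, seed = 2)
  oh3 <- encode_onehot(g3)
  expect_equal(nrow(oh3$feature_map), ncol(oh3$matrix))
  for (mk in g3$marker_ids) {
    block <- oh3$matrix[, oh3$feature_map$marker_id == mk, drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, 40))
  }
})

test_that("sample matching intersects ids, drops missing phenotypes, keeps order", {
  calls <- matrix(rep(c("AA", "AG", "GG"), 2), ncol = 2)
  g <- raw_genotype(calls, c("a", "b", "c"), c("m1", "m2"))
  enc <- encode_additive(g)
  pheno <- tibble::tibble(sample_id = c("b", "c", "d"), y = c(1.5, NA, 2.0))
  suppressMessages(ds <- match_samples(enc, pheno, "y"))
  expect_equal(ds$sample_ids, "b")
  expect_equal(ds$y, 1.5)

  pheno_full <- tibble::tibble(sample_id = c("a", "b", "c"), y = c(1, 2, 3))
  ds2 <- match_samples(enc, pheno_full, "y")
  expect_equal(ds2$sample_ids, c("a", "b", "c"))

  disjoint <- tibble::tibble(sample_id = c("x", "y"), y = c(1, 2))
  expect_error(match_samples(enc, disjoint, "y"), "no shared sample ids")
  expect_error(match_samples(enc, pheno_full, "z"), "not found")
})
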