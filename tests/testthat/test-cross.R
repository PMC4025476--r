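test_that("monohybrid and dihybrid crosses give the classic exact ratios", {
  r1 <- cross("Aa", "Aa", locus_set(1))
  geno <- setNames(r1$genotype_ratio$ratio, r1$genotype_ratio$genotype)
  expect_equal(geno[c("AA", "Aa", "aa")], c(AA = 1L, Aa = 2L, aa = 1L))
  phen <- setNames(r1$phenotype_ratio$ratio, r1$phenotype_ratio$phenotype)
  expect_equal(phen, c(A = 3L, a = 1L))

  r2 <- cross("AaBb", "AaBb", locus_set(2))
  phen2 <- setNames(r2$phenotype_ratio$ratio, r2$phenotype_ratio$phenotype)
  expect_equal(phen2[c("AB", "Ab", "aB", "ab")],
               c(AB = 9L, Ab = 3L, aB = 3L, ab = 1L))
  # exact probabilities: 9/16 etc.
  expect_identical(sum(r2$phenotype_dist$num), r2$phenotype_dist$den[1])
})

test_that("X-linked crosses separate sons and daughters correctly", {
  lx <- locus_set(names = "A", x_linked = TRUE)
  res <- cross("Aa", "A-", lx)
  pd <- res$phenotype_dist
  daughters <- pd[pd$sex == "female", ]
  expect_equal(daughters$phenotype, "A")           # all daughters dominant
  expect_equal(sum(daughters$prob), 0.5)
  sons <- pd[pd$sex == "male", ]
  expect_setequal(sons$phenotype, c("A", "a"))     # sons 1:1
  expect_true(all(sons$prob == 0.25))
})

test_that("cross() matches brute-force gamete-pair enumeration for up to 3 loci", {
  set.seed(402)
  for (rep in 1:15) {
    k <- sample(1:3, 1)
    xl <- sample(c(TRUE, FALSE), k, replace = TRUE)
    loci <- locus_set(k, x_linked = xl)
    mg <- random_genotype(loci, "female")
    fg <- random_genotype(loci, "male")
    res <- cross(mg, fg, loci)
    oracle <- oracle_cross(genotype_to_alleles(mg, loci, "female"),
                           genotype_to_alleles(fg, loci, "male"), loci)
    got <- res$genotype_dist[order(paste(res$genotype_dist$sex,
                                         res$genotype_dist$genotype)), ]
    expect_equal(paste(got$sex, got$genotype),
                 paste(oracle$sex, oracle$genotype))
    expect_equal(got$prob, oracle$prob)
  }
})

test_that("autosomal crosses are symmetric in the parental genotypes", {
  set.seed(403)
  loci <- locus_set(3)
  for (rep in 1:5) {
    g1 <- random_genotype(loci, "female")
    g2 <- random_genotype(loci, "female")
    a <- cross(g1, g2, loci)
    b <- cross(g2, g1, loci)
    expect_equal(a$genotype_dist, b$genotype_dist)
    expect_equal(a$phenotype_ratio, b$phenotype_ratio)
  }
})

test_that("distributions always conserve probability exactly", {
  set.seed(404)
  for (rep in 1:10) {
    k <- sample(1:3, 1)
    xl <- sample(c(TRUE, FALSE), k, replace = TRUE)
    loci <- locus_set(k, x_linked = xl)
    res <- cross(random_genotype(loci, "female"), random_genotype(loci, "male"), loci)
    expect_identical(sum(res$genotype_dist$num), res$genotype_dist$den[1])
    expect_identical(sum(res$phenotype_dist$num), res$phenotype_dist$den[1])
    expect_equal(gcd_test(res$phenotype_ratio$ratio), 1L)
  }
})

test_that("sampled broods conserve n and track expectations", {
  res <- cross("Aa", "Aa", locus_set(1))
  b <- sample_brood(res, 10, seed = 1)
  expect_equal(sum(b$count), 10)
  expect_identical(b, sample_brood(res, 10, seed = 1))

  big <- sample_brood(res, 1e5, seed = 2)
  merged <- tapply(big$count, big$genotype, sum)
  expected <- c(AA = 0.25, Aa = 0.5, aa = 0.25) * 1e5
  sds <- sqrt(expected * (1 - c(0.25, 0.5, 0.25)))
  expect_true(all(abs(merged[names(expected)] - expected) < 4 * sds))

  # single-outcome distribution: everything lands in it
  fixed <- cross("AA", "AA", locus_set(1))
  b2 <- sample_brood(fixed, 7, seed = 3)
  expect_equal(sum(b2$count[b2$genotype == "AA"]), 7)
  expect_error(sample_brood(res, 0), "positive")
})

test_that("next_generation crosses the selected pair and enforces one of each sex", {
  loci <- locus_set(1)
  f2 <- next_generation(data.frame(sex = c("female", "male"),
                                   genotype = c("AA", "aa")), loci)
  expect_equal(unique(f2$genotype_dist$genotype), "Aa")
  expect_equal(f2$genotype_dist$prob, c(0.5, 0.5))  # Aa daughters and sons

  direct <- cross("Aa", "Aa", loci)
  chained <- next_generation(data.frame(sex = c("female", "male"),
                                        genotype = c("Aa", "Aa")), loci)
  expect_equal(chained$genotype_dist, direct$genotype_dist)

  expect_error(next_generation(data.frame(sex = c("female", "female"),
                                          genotype = c("Aa", "Aa")), loci),
               "one female and one male")
  expect_error(cross(multi_genotype("Aa", "female", loci),
                     multi_genotype("Aa", "female", loci), loci), "male")
})

test_that("the default cross is a single-locus heterozygote pairing with a 3:1 ratio", {
  d <- default_cross()
  expect_equal(nrow(d$loci), 1)
  expect_equal(d$parents$mother$label, "Aa")
  expect_equal(d$parents$father$label, "Aa")
  expect_equal(d$phenotype_ratio$ratio, c(3L, 1L))
})

test_that("tidy and glance expose the cross result as tables", {
  r <- cross("AaBb", "AaBb", locus_set(2))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(sort(td$ratio), c(1L, 3L, 3L, 9L))
  gl <- glance(r)
  expect_equal(gl$n_loci, 2)
  expect_equal(gl$n_phenotype_classes, 4)
  expect_s3_class(autoplot(r), "ggplot")
})
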