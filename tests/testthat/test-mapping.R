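worked_counts <- c(ABC = 360, abc = 360, aBC = 40, Abc = 40,
                   ABc = 90, abC = 90, AbC = 10, aBc = 10)

test_that("the classic three-point example is solved exactly", {
  sol <- solve_threepoint(mapping_problem(worked_counts))
  expect_equal(sol$order, c("A", "B", "C"))
  expect_equal(unname(sol$r), c(0.10, 0.20))
  expect_equal(names(sol$r), c("A-B", "B-C"))
  expect_equal(unname(sol$cM), c(10, 20))
  expect_equal(sol$coincidence, 1.0)
  expect_equal(sol$interference, 0.0)
  expect_equal(sol$phase, "ABC/abc")
  expect_false(sol$ambiguous)
  expect_false(any(sol$unlinked))
})

test_that("the solver is invariant to the presented locus order", {
  # same counts with columns written B, A, C
  relabeled <- setNames(worked_counts, vapply(names(worked_counts), function(cl) {
    ch <- strsplit(cl, "")[[1]]
    paste(ch[c(2, 1, 3)], collapse = "")
  }, character(1)))
  sol <- solve_threepoint(mapping_problem(relabeled, loci = c("B", "A", "C")))
  expect_equal(sol$order, c("A", "B", "C"))
  expect_equal(unname(sol$r), c(0.10, 0.20))
})

test_that("phase is read off the parental classes, including repulsion", {
  repulsion <- c(AbC = 360, aBc = 360, ABc = 40, abC = 40,
                 Abc = 90, aBC = 90, ABC = 10, abc = 10)
  sol <- solve_threepoint(mapping_problem(repulsion))
  expect_equal(sol$phase, "AbC/aBc")
  expect_equal(unname(sol$r), c(0.10, 0.20))
})

test_that("two-point problems recover r and phase, and detect independence", {
  sol <- solve_twopoint(mapping_problem(c(AB = 450, ab = 450, Ab = 50, aB = 50)))
  expect_equal(unname(sol$r), 0.10)
  expect_equal(sol$phase, "AB/ab")
  expect_false(any(sol$unlinked))

  ind <- solve_twopoint(mapping_problem(c(AB = 250, ab = 250, Ab = 250, aB = 250)))
  expect_equal(unname(ind$r), 0.5)
  expect_true(all(ind$unlinked))
  expect_true(ind$ambiguous)
  expect_equal(ind$independence$chi2, 0)

  expect_error(mapping_problem(c(AB = 0, ab = 0, Ab = 0, aB = 0)), "positive")
  expect_error(mapping_problem(c(AB = 1, ab = 1)), "classes")
})

test_that("exact-expectation problems round-trip through the solver to machine precision", {
  set.seed(301)
  for (rep in 1:20) {
    r1 <- runif(1, 0.02, 0.4)
    r2 <- runif(1, 0.02, 0.4)
    while (abs(r1 - r2) < 0.02) r2 <- runif(1, 0.02, 0.4)
    ex <- generate_mapping_problem(k = 3, n = 1000, exact = TRUE,
                                   r_range = sort(c(r1, r2)),
                                   seed = sample.int(1e6, 1))
    sol <- solve_threepoint(ex$problem)
    expect_equal(sol$order, ex$key$order)
    expect_equal(sol$phase, ex$key$phase)
    expect_equal(sol$r, ex$key$r, tolerance = 1e-12)
    expect_equal(sol$coincidence, ex$key$coincidence, tolerance = 1e-9)
  }
})

test_that("sampled problems recover order and r within binomial error", {
  n <- 2000
  ok_order <- 0
  ok_r <- 0
  n_r <- 0
  seeds <- genevolve:::derive_seeds(1234, 500)
  for (s in seeds) {
    ex <- generate_mapping_problem(k = 3, n = n, r_range = c(0.05, 0.35), seed = s)
    sol <- solve_threepoint(ex$problem)
    if (identical(sol$order, ex$key$order)) {
      ok_order <- ok_order + 1
      for (iv in names(ex$key$r)) {
        n_r <- n_r + 1
        tol <- 4 * sqrt(ex$key$r[[iv]] * (1 - ex$key$r[[iv]]) / n)
        if (abs(sol$r[[iv]] - ex$key$r[[iv]]) <= tol) ok_r <- ok_r + 1
      }
    }
  }
  expect_gte(ok_order / 500, 0.99)
  expect_gte(ok_r / n_r, 0.99)
})

test_that("class probabilities are a proper distribution with equal complementary pairs", {
  set.seed(302)
  for (rep in 1:10) {
    ex <- generate_mapping_problem(k = 3, n = 100000, exact = TRUE,
                                   r_range = c(0.05, 0.4),
                                   coincidence = runif(1, 0, 1),
                                   seed = sample.int(1e6, 1))
    cls <- ex$problem$classes
    expect_equal(sum(cls$count), 100000)
    comp <- vapply(cls$class, function(x) {
      cls$count[cls$class == chartr("ABCabc", "abcABC", x)]
    }, numeric(1))
    expect_equal(unname(comp), cls$count)  # complementary classes equally likely
  }
})

test_that("generation is deterministic under a seed and honours p_unlinked", {
  a <- generate_mapping_problem(k = 3, n = 500, seed = 77)
  b <- generate_mapping_problem(k = 3, n = 500, seed = 77)
  expect_identical(a$problem$classes, b$problem$classes)
  expect_identical(a$key$r, b$key$r)

  u <- generate_mapping_problem(k = 3, n = 500, p_unlinked = 1, seed = 5)
  expect_true(all(u$key$unlinked))
  expect_true(all(u$key$r == 0.5))

  expect_error(generate_mapping_problem(k = 4), "2 or 3")
  expect_error(generate_mapping_problem(r_range = c(0.1, 0.6)), "r_range")
})

test_that("estimated recombination fractions are capped at one half", {
  # extreme counts that would naively give r > 0.5
  sol <- solve_twopoint(mapping_problem(c(AB = 10, ab = 10, Ab = 490, aB = 490)))
  expect_lte(sol$r[[1]], 0.5)
  set.seed(303)
  for (rep in 1:20) {
    ex <- generate_mapping_problem(k = 3, n = 50, p_unlinked = 0.5,
                                   seed = sample.int(1e6, 1))
    expect_true(all(solve_threepoint(ex$problem)$r <= 0.5))
  }
})

test_that("count ties set the ambiguity flag instead of silently guessing", {
  tied <- c(ABC = 200, abc = 200, aBC = 200, Abc = 200,
            ABc = 90, abC = 90, AbC = 10, aBc = 10)
  sol <- solve_threepoint(mapping_problem(tied))
  expect_true(sol$ambiguous)
})
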