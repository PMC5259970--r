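test_that("split level minimizes 2^a + 2^(n-a) with ties to the smaller level", {
  expect_identical(find_alpha_m(45)$alpha_m, 5L)   # n = 10
  expect_identical(find_alpha_m(28)$alpha_m, 4L)   # n = 8
  plan2 <- find_alpha_m(1)                         # n = 2
  expect_identical(plan2$alpha_m, 1L)
  expect_identical(plan2$m_min, "16")
  expect_error(find_alpha_m(7), class = "pdp_nontriangular_error")
})

test_that("split level agrees with an exhaustive scan for n up to 64", {
  for (n in 2:64) {
    M <- n^2 * (2^(1:n) + 2^(n - (1:n)))
    expect_identical(find_alpha_m(pair_count(n))$alpha_m,
                     as.integer(which.min(M)),
                     info = paste("n =", n))
    # first strict minimum of the symmetric curve: n/2, rounded down
    expect_identical(find_alpha_m(pair_count(n))$alpha_m, as.integer(n %/% 2),
                     info = paste("n =", n))
  }
})

test_that("worst-case memory score is computed exactly", {
  for (n in c(3L, 8L, 10L, 17L, 20L)) {
    plan <- find_alpha_m(pair_count(n))
    a <- plan$alpha_m
    expect_identical(plan$m_min,
                     sprintf("%.0f", n^2 * (2^a + 2^(n - a))))
  }
  # beyond double precision: n = 100 -> 100^2 * 2^51
  expect_identical(find_alpha_m(pair_count(100L))$m_min,
                   "22517998136852480000")
})

test_that("two-stage search returns the same solutions as the single-stage solvers", {
  expect_same_solutions(solve_bbb2(worked_example, validate = TRUE),
                        worked_solutions)
  expect_same_solutions(solve_bbb2(luciferase_multiset()),
                        luciferase_solutions)
  expect_same_solutions(solve_bbb2(5L), list(c(0L, 5L)))
  set.seed(77)
  for (rep in 1:10) {
    gen <- random_instance(sample(4:10, 1), sample(c(25, 200), 1))
    ref <- canon_sols(solve_bbd(gen$D)$solutions)
    expect_identical(canon_sols(solve_bbb2(gen$D, validate = TRUE)$solutions), ref)
    # arbitrary split-level overrides must not change the answer
    for (a in unique(c(1L, 2L, length(gen$points)))) {
      got <- solve_bbb2(gen$D, alpha = a)
      expect_identical(canon_sols(got$solutions), ref)
    }
  }
})

test_that("splitting the search never enlarges the peak frontier", {
  for (sd in 1:3) {
    z <- zhang_instance(3, seed = sd)
    b <- solve_bbb(z$D)
    b2 <- solve_bbb2(z$D)
    expect_identical(canon_sols(b2$solutions), canon_sols(b$solutions))
    expect_lte(b2$stats$peak_frontier, b$stats$peak_frontier)
  }
})
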