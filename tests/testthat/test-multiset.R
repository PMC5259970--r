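test_that("multiset difference clamps counts at zero", {
  expect_identical(dms_elements(dms_difference(worked_example, 10L)),
                   c(1L, 2L, 2L, 3L, 5L, 6L, 7L, 8L, 8L))
  D <- dms(c(2L, 2L, 3L))
  expect_true(dms_equal(dms_difference(D, integer()), D))
  expect_identical(dms_size(dms_difference(D, D)), 0L)
  expect_identical(dms_elements(dms_difference(D, c(2L, 5L))), c(2L, 3L))
})

test_that("disjoint union adds multiplicities", {
  expect_identical(dms_elements(dms_union(dms(), 7L)), 7L)
  expect_identical(dms_elements(dms_union(2L, 2L)), c(2L, 2L))
  expect_identical(dms_elements(dms_union(c(1L, 3L), c(3L, 5L))),
                   c(1L, 3L, 3L, 5L))
})

test_that("delta_point gives distances from one point to a set", {
  expect_identical(dms_elements(delta_point(8, c(0, 10))), c(2L, 8L))
  expect_identical(dms_elements(delta_point(5, 5)), 0L)
  expect_identical(dms_elements(delta_point(0, c(0, 2, 8, 10))),
                   c(0L, 2L, 8L, 10L))
  expect_identical(dms_size(delta_point(3, c(0, 2, 8, 10))), 4L)
})

test_that("delta_set reproduces known difference multisets", {
  expect_identical(dms_elements(delta_set(c(0, 2, 7, 8, 10))),
                   sort(worked_example))
  expect_identical(dms_elements(delta_set(c(0, 7))), 7L)
  expect_identical(dms_size(delta_set(5L)), 0L)
  # the bundled luciferase fixture is exactly the difference multiset of the
  # published TaqI map
  expect_true(dms_equal(delta_set(c(0L, luciferase_sites, 2009L)),
                        luciferase_multiset()))
})

test_that("sub-multiset test compares per-element counts", {
  big <- c(1L, 2L, 2L, 3L, 5L, 6L, 7L, 8L, 8L)
  expect_true(dms_is_subset(c(2L, 8L), big))
  expect_false(dms_is_subset(c(0L, 1L), c(1L, 1L)))
  expect_false(dms_is_subset(c(2L, 2L, 2L), big))
  expect_true(dms_is_subset(integer(), big))
  expect_true(dms_is_subset(integer(), integer()))
})

test_that("instance validation recovers n and rejects bad input", {
  inst <- pdp_instance(worked_example)
  expect_identical(inst$n, 5L)
  expect_identical(inst$width, 10L)
  expect_identical(pdp_instance(luciferase_multiset())$n, 8L)
  expect_error(pdp_instance(rep(1L, 7L)), class = "pdp_nontriangular_error")
  expect_error(pdp_instance(c(0L, 1L, 2L)), class = "pdp_nonpositive_error")
  expect_error(pdp_instance(integer()), class = "pdp_empty_input_error")
  expect_error(dms(c(1, 3.5)), class = "pdp_parse_error")
  expect_error(dms(c(-1L, 2L)), class = "pdp_nonpositive_error")
})

test_that("pair count inversion is exact, including large N", {
  expect_identical(n_from_pair_count(10), 5L)
  expect_identical(n_from_pair_count(28), 8L)
  expect_true(is.na(n_from_pair_count(7)))
  for (n in c(2L, 3L, 17L, 1000L, 2000L, 50000L)) {
    expect_identical(n_from_pair_count(pair_count(n)), n)
    expect_true(is.na(n_from_pair_count(pair_count(n) + 1)))
  }
})

test_that("difference composes as D \\ (L u+ Z) on random multisets", {
  set.seed(42)
  for (rep in 1:60) {
    d <- sample(0:8, sample(0:12, 1), replace = TRUE)
    l <- sample(0:8, sample(0:6, 1), replace = TRUE)
    z <- sample(0:8, sample(0:6, 1), replace = TRUE)
    lhs <- dms_difference(dms_difference(d, l), z)
    rhs <- dms_difference(d, dms_union(l, z))
    expect_true(dms_equal(lhs, rhs))
    # and both agree with the one-occurrence-at-a-time count model
    expect_identical(dms_elements(lhs), oracle_vec_diff(oracle_vec_diff(d, l), z))
  }
})

test_that("difference multisets are reflection-invariant and sized n(n-1)/2", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:9, 1)
    X <- sort(sample(0:200, n))
    DX <- delta_set(X)
    expect_identical(dms_size(DX), as.integer(n * (n - 1) / 2))
    expect_identical(dms_elements(DX), oracle_delta(X))
    cc <- max(X) + sample(0:10, 1)
    expect_true(dms_equal(DX, delta_set(cc - X)))
  }
})

test_that("delta_set equals the disjoint union of per-point distance fans", {
  set.seed(11)
  for (rep in 1:20) {
    X <- sort(sample(0:100, sample(2:8, 1)))
    n <- length(X)
    acc <- dms()
    for (i in seq_len(n - 1L))
      acc <- dms_union(acc, delta_point(X[i], X[(i + 1L):n]))
    expect_true(dms_equal(acc, delta_set(X)))
  }
})
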