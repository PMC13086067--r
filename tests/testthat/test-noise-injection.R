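test_that("every mechanism spends its exact cell budget and records it", {
  X <- rand_binary(40, 15, p = 0.3, seed = 2)
  for (mech in c("NCAR", "NAR", "NNAR")) {
    for (p in c(0.05, 0.17, 0.30)) {
      spec <- noise_spec(mech, p, seed = 7)
      out <- inject_noise(X, spec)
      B <- round(p * 40 * 15)
      expect_identical(sum(out$mask), as.integer(B))
      # the mask is exactly the cellwise disagreement
      expect_identical(out$mask, X != out$noisy)
      expect_equal(realized_noise(X, out$noisy), B / (40 * 15))
      # determinism: same spec, same result
      again <- inject_noise(X, spec)
      expect_identical(again$noisy, out$noisy)
      expect_identical(again$mask, out$mask)
      # binary output
      expect_true(all(out$noisy %in% c(0L, 1L)))
    }
    # zero budget is the identity
    none <- inject_noise(X, noise_spec(mech, 0, seed = 7))
    expect_identical(none$noisy, X)
    expect_false(any(none$mask))
  }
})

test_that("NCAR flips exactly round(p n m) uniformly chosen cells", {
  X <- matrix(0L, 10, 10)
  out <- inject_ncar(X, noise_spec("NCAR", 0.05, seed = 3))
  expect_identical(sum(out$noisy), 5L)
  expect_error(inject_ncar(matrix(2L, 3, 3), noise_spec("NCAR", 0.1)),
               "non-binary")
})

test_that("NCAR cell choice is uniform across seeds", {
  X <- matrix(0L, 4, 5)
  counts <- matrix(0, 4, 5)
  for (s in 1:10000) {
    counts <- counts + inject_ncar(X, noise_spec("NCAR", 0.15, seed = s))$mask
  }
  # B = 3 of 20 cells; chi-square goodness of fit against uniformity
  expected <- 10000 * 3 / 20
  stat <- sum((counts - expected)^2 / expected)
  expect_lt(stat, qchisq(0.99, df = 19))
})

test_that("NAR flips changeable columns of the highest unchangeable-sum instances", {
  X <- rand_binary(8, 10, p = 0.5, seed = 5)
  # c = 0.5 -> 5 changeable columns; p = 0.25 -> B = 20 = 4 full instances
  spec <- noise_spec("NAR", 0.25, seed = 9, changeable_fraction = 0.5)
  out <- inject_nar(X, spec)
  flipped_rows <- which(rowSums(out$mask) > 0)
  expect_length(flipped_rows, 4L)
  changeable <- which(colSums(out$mask) > 0)
  expect_length(changeable, 5L)
  # independent re-ranking by the unchangeable sums, ties by index
  usum <- rowSums(X[, -changeable, drop = FALSE])
  ranking <- order(-usum, seq_len(8))
  expect_setequal(flipped_rows, ranking[1:4])
  # every flip lies in a changeable column
  expect_true(all(which(colSums(out$mask) > 0) %in% changeable))
  # a partial budget touches a prefix plus one partially flipped instance
  spec2 <- noise_spec("NAR", 0.10, seed = 9, changeable_fraction = 0.5)
  out2 <- inject_nar(X, spec2)  # B = 8 = one full instance + 3 cells
  expect_identical(sum(out2$mask), 8L)
  expect_identical(unname(rowSums(out2$mask)[ranking[1:2]]), c(5, 3))
})

test_that("infeasible NAR budgets are refused", {
  expect_error(noise_spec("NAR", 0.6, changeable_fraction = 0.5),
               "exceeds changeable_fraction")
})

test_that("NNAR only creates ones and fails without enough zeros", {
  X <- rand_binary(30, 10, p = 0.2, seed = 6)
  out <- inject_nnar(X, noise_spec("NNAR", 0.2, seed = 4))
  diff <- out$noisy - X
  expect_true(all(diff >= 0))
  expect_identical(sum(diff), as.integer(round(0.2 * 300)))
  expect_error(
    inject_nnar(matrix(1L, 5, 5), noise_spec("NNAR", 0.05, seed = 1)),
    "infeasible")
})

test_that("realized_noise measures the Hamming fraction", {
  X <- rand_binary(6, 6, seed = 8)
  expect_identical(realized_noise(X, X), 0)
  expect_identical(realized_noise(X, 1L - X), 1)
  expect_error(realized_noise(X, X[1:3, ]), "shapes")
})

test_that("the outcome is never perturbed", {
  coh <- small_cohort(n = 50, m = 8)
  out <- inject_cohort(coh, noise_spec("NCAR", 0.3, seed = 2))
  expect_identical(out$cohort$outcome, coh$outcome)
  expect_false(identical(out$cohort$features, coh$features))
})
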