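test_that("copula_normalize: rank transform to normal marginals", {
  set.seed(1)
  x <- rexp(1000)
  cx <- copula_normalize(x)
  expect_lt(abs(mean(cx)), 0.05)
  # invariance under strictly monotone transforms, bit-equal
  expect_identical(cx, copula_normalize(exp(x)))
  expect_identical(cx, copula_normalize(rank(x) * 2))
  # order preserved
  xs <- sort(x)
  expect_false(is.unsorted(copula_normalize(xs)))
  expect_error(copula_normalize(rep(1, 50)), "constant")
  expect_error(copula_normalize(rnorm(5)), "10 samples")
  expect_warning(copula_normalize(rep(1:3, 100)), "ties")
})

test_that("mi_gaussian_copula: oracles and invariances", {
  set.seed(2)
  n <- 1e4
  expect_lt(mi_gaussian_copula(rnorm(n), rnorm(n)), 0.01)

  n <- 1e5
  x <- rnorm(n); y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n)
  expect_lt(abs(mi_gaussian_copula(x, y) - gaussian_mi_oracle(0.9)), 0.02)

  # monotone transform invariance (bit-equal after the copula step)
  expect_identical(mi_gaussian_copula(x, y),
                   mi_gaussian_copula(exp(x), y^3))

  # rank-degenerate deterministic case: finite, large, no crash
  expect_true(is.finite(mi_gaussian_copula(x[1:1000], exp(x[1:1000]))))

  # discrete-target model: for two well-separated classes the copula
  # estimator saturates at its half-normal ceiling 0.5*log2(pi/(pi-2))
  # ~ 0.73 bits (the rank transform fixes the overall marginal)
  cls <- rep(0:1, each = 5000)
  xd <- rnorm(10000, mean = 6 * cls)
  expect_gt(mi_gaussian_copula(xd, cls), 0.7)
  expect_lt(mi_gaussian_copula(rnorm(10000), cls), 0.01)

  expect_error(mi_gaussian_copula(cbind(x, x), y), "collinear")
})

test_that("binned_mi: plugin MI over equipopulated bins", {
  set.seed(3)
  n <- 1e4
  cls <- sample(4, n, replace = TRUE)
  expect_lt(binned_mi(rnorm(n), cls, 4), 3 * plugin_mi_bias(n, 4, 4))

  # perfect 4-way separation carries H(class) = 2 bits
  cls_eq <- rep(1:4, each = n / 4)
  x_sep <- cls_eq + runif(n, 0, 0.1)
  expect_lt(abs(binned_mi(x_sep, cls_eq, 4) - 2), 0.01)

  expect_equal(binned_mi(rnorm(100), rep(1:2, 50), n_bins = 1), 0)
  expect_error(binned_mi(rep(c(1, 2), 500), rep(1:2, 500), 4), "distinct")

  # Miller-Madow correction shifts the null estimate toward zero
  mi_plug <- binned_mi(rnorm(n), cls, 4)
  mi_mm <- binned_mi(rnorm(n), cls, 4, miller_madow = TRUE)
  expect_lt(abs(mi_mm), abs(mi_plug) + 1e-12)
})

test_that("pid_ccs: lattice identities hold by construction", {
  set.seed(4)
  for (str in c("redundant", "unique_x", "synergistic")) {
    tr <- simulate_pid_triplet(5000, str, 0.7, seed = 11)
    p <- pid_ccs(tr$x, tr$y, tr$t, n_mc = 1e4, seed = 1)
    expect_lt(abs(p$mi_x - (p$redundancy + p$unique_x)), 1e-9)
    expect_lt(abs(p$mi_y - (p$redundancy + p$unique_y)), 1e-9)
    expect_lt(abs(p$mi_joint -
                    (p$redundancy + p$unique_x + p$unique_y + p$synergy)),
              1e-9)
  }
})

test_that("pid_ccs: designed structures are classified correctly", {
  tr <- simulate_pid_triplet(1e5, "redundant", 0.9, seed = 21)
  p <- pid_ccs(tr$x, tr$y, tr$t, n_mc = 1e5, seed = 2)
  expect_lt(abs(p$unique_x), 0.01)
  expect_lt(abs(p$unique_y), 0.01)
  expect_lt(abs(p$synergy), 0.01)
  expect_lt(abs(p$redundancy - p$mi_x), 0.01)

  tu <- simulate_pid_triplet(1e5, "unique_x", 0.7, seed = 22)
  pu <- pid_ccs(tu$x, tu$y, tu$t, n_mc = 1e5, seed = 3)
  expect_lt(pu$redundancy, 0.02)
  expect_lt(abs(pu$unique_y), 0.02)
  expect_gt(pu$unique_x, 0.2)

  ts <- simulate_pid_triplet(1e5, "synergistic", 0.9, seed = 23)
  ps <- pid_ccs(ts$x, ts$y, ts$t, n_mc = 1e5, seed = 4)
  expect_gt(ps$synergy, ps$redundancy)
})

test_that("pid_ccs Monte-Carlo error shrinks with n_mc", {
  tr <- simulate_pid_triplet(5000, "redundant", 0.6, seed = 31)
  red <- function(nmc, s)
    pid_ccs(tr$x, tr$y, tr$t, n_mc = nmc, seed = s)$redundancy
  v_small <- var(vapply(1:20, function(s) red(1000, s), numeric(1)))
  v_large <- var(vapply(1:20, function(s) red(8000, s), numeric(1)))
  expect_gt(v_small / v_large, 2)   # ~8x expected under 1/sqrt(n_mc)
})

test_that("coinformation equals redundancy minus synergy", {
  set.seed(5)
  x <- rnorm(3000); y <- 0.5 * x + rnorm(3000) * 0.8
  t <- 0.4 * x + 0.4 * y + rnorm(3000)
  p <- pid_ccs(x, y, t, n_mc = 5000, seed = 6)
  expect_lt(abs(p$redundancy - p$synergy - (p$mi_x + p$mi_y - p$mi_joint)),
            1e-9)
  expect_lt(abs(coinformation(x, y, t) - (p$mi_x + p$mi_y - p$mi_joint)),
            1e-6)

  # y = x: CoI = MI(x;t) up to the duplicated-channel degeneracy handling
  # (the joint term is regularized and bias-corrected at d = 2, not d = 1)
  expect_lt(abs(coinformation(x, x, t) - mi_gaussian_copula(x, t)), 0.01)
  expect_lt(abs(coinformation(rnorm(5000), rnorm(5000), rnorm(5000))), 0.01)
})

test_that("normalize_pid scales all components", {
  tr <- simulate_pid_triplet(20000, "redundant", 0.8, seed = 41)
  p <- pid_ccs(tr$x, tr$y, tr$t, n_mc = 2e4, seed = 7)
  np <- normalize_pid(p, p$mi_x)
  expect_lt(abs(np$redundancy - 1), 0.02)
  expect_equal(np$mi_x, 1)

  half <- normalize_pid(p, 2 * p$mi_joint)
  expect_equal(half$mi_joint, 0.5)

  # negative unique information in the normalizing source can push the
  # normalized redundancy above 1
  if (p$unique_x < 0) expect_gt(np$redundancy, 1)
  expect_error(normalize_pid(p, 0), "reference_mi")
})

test_that("permutation_threshold: determinism and degenerate stat", {
  set.seed(8)
  x <- rnorm(1000); y <- rnorm(1000)
  cst <- permutation_threshold(x, y, function(a, b) 1.5, n_perm = 50,
                               min_shift = 100, seed = 9)
  expect_equal(cst, 1.5)
  t1 <- permutation_threshold(x, y, function(a, b) cor(a, b), n_perm = 100,
                              min_shift = 100, seed = 10)
  t2 <- permutation_threshold(x, y, function(a, b) cor(a, b), n_perm = 100,
                              min_shift = 100, seed = 10)
  expect_identical(t1, t2)
  expect_error(permutation_threshold(x[1:300], y[1:300],
                                     function(a, b) cor(a, b),
                                     min_shift = 200), "too short")
})
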