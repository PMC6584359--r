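test_that("epoch_events: window arithmetic and index exactness", {
  ev <- event_table(c(0.5, 2, 5), rep("AH", 3), rep("vowel", 3))
  sig <- rnorm(400)
  ep <- epoch_events(sig, ev, c(-0.1, 0.6), 40)
  expect_identical(ncol(ep$epochs), 29L)   # -4..24 inclusive at 40 Hz
  expect_equal(ep$times[1], -0.1)

  # event at t = 0 under-runs the window and is dropped
  ev0 <- event_table(c(0, 2), c("AH", "AH"), c("vowel", "vowel"))
  expect_message(ep0 <- epoch_events(sig, ev0, c(-0.1, 0.6), 40), "dropped")
  expect_identical(nrow(ep0$epochs), 1L)

  cst <- epoch_events(rep(3.14, 400), ev, c(-0.1, 0.6), 40)
  expect_true(all(apply(cst$epochs, 2, sd) == 0))

  # delta train recovers deltas exactly at the onset-aligned sample
  delta <- numeric(400)
  onset_idx <- ceiling(ev$onset_s * 40 - 0.5) + 1L
  delta[onset_idx] <- 1
  epd <- epoch_events(delta, ev, c(-0.1, 0.6), 40)
  t0 <- which(ep$times == 0)
  expect_true(all(epd$epochs[, t0] == 1))
  expect_equal(sum(epd$epochs[, -t0] == 1), 0)

  expect_error(epoch_events(rnorm(10), ev, c(-0.1, 0.6), 40), "zero events")
})

test_that("class_average recovers group means", {
  ev <- event_table(seq(1, 40, by = 1), rep("AH", 40),
                    rep(c("vowel", "nasal", "plosive", "fricative"), 10))
  sig <- numeric(2000)
  ep <- epoch_events(sig, ev, c(-0.1, 0.6), 40)
  # inject distinct constants per class
  for (cl in unique(ep$classes))
    ep$epochs[ep$classes == cl, ] <- match(cl, unique(ep$classes))
  pr <- class_average(ep)
  expect_identical(nrow(pr), 4L)
  for (cl in unique(ep$classes))
    expect_true(all(pr[cl, ] == match(cl, unique(ep$classes))))

  # brute-force oracle on random epochs
  ep$epochs <- matrix(rnorm(length(ep$epochs)), nrow(ep$epochs))
  pr2 <- class_average(ep)
  for (cl in rownames(pr2))
    expect_equal(pr2[cl, ],
                 colMeans(ep$epochs[ep$classes == cl, , drop = FALSE]))
})

test_that("mi_timecourse: class-independent data sits at bias level", {
  set.seed(1)
  ev <- simulate_events(300, 10, 0.03, seed = 2)
  sig <- rnorm(300 * 40)
  ep <- epoch_events(sig, ev, c(-0.1, 0.6), 40)
  mi <- mi_timecourse(ep)
  expect_length(mi, 29L)
  n_ev <- nrow(ep$epochs)
  expect_lt(max(mi), 3 * plugin_mi_bias(n_ev, 4, 4))
})

test_that("mi_timecourse: class-specific gains produce a post-onset peak", {
  w <- phoneme_world(duration = 300, snr = 4, seed = 3)
  ep <- epoch_events(w$observed, w$events, c(-0.1, 0.6), 40)
  mi <- mi_timecourse(ep)
  pre <- mean(mi[ep$times < 0])
  expect_gte(max(mi[ep$times >= 0]), 5 * pre)
  # summing the time course gives the scalar selection objective
  expect_true(is.finite(sum(mi)))
})

test_that("pid_timecourse: observed vs predicted epochs", {
  w <- phoneme_world(duration = 300, snr = 2, seed = 4)
  obs <- epoch_events(w$observed, w$events, c(-0.1, 0.6), 40)
  prd <- epoch_events(w$clean, w$events, c(-0.1, 0.6), 40)

  # identical sources: redundancy = marginal MI, unique ~ 0 everywhere
  same <- pid_timecourse(prd, prd, n_mc = 3e4, seed = 5)
  expect_true(all(abs(same$unique_observed) < 0.01))
  expect_true(all(abs(same$unique_predicted) < 0.01))
  expect_true(all(abs(same$redundancy - same$mi_observed) < 0.01))

  # observed = predicted + noise: nothing unique to the observed side
  tc <- pid_timecourse(obs, prd, n_mc = 2e4, seed = 6)
  expect_true(all(tc$unique_observed <= 0.01))

  # redundancy <= min(marginal MI) on symmetric Gaussian fixtures. The
  # bound is deliberately NOT asserted for nested sources (obs = pred +
  # noise): there unique-to-observed is negative — misinformation unique
  # to the noisy copy — and redundancy legitimately exceeds the observed
  # marginal MI (the same mechanism that lets normalized redundancy
  # ratios exceed 1).
  set.seed(60)
  n_ev <- nrow(obs$epochs)
  mu <- c(vowel = 0, nasal = 0.5, plosive = 1, fricative = 1.5)
  gcl <- obs$classes
  gobs <- rnorm(n_ev, mu[gcl])
  gpred <- rnorm(n_ev, mu[gcl])     # class-conditionally independent
  gep <- function(v) {
    e <- obs
    e$epochs <- matrix(v, n_ev, 3)   # 3 identical time points suffice
    e$times <- e$times[1:3]
    e
  }
  gtc <- pid_timecourse(gep(gobs), gep(gpred), n_mc = 2e4, seed = 61)
  expect_true(all(gtc$redundancy <= pmin(gtc$mi_observed, gtc$mi_predicted)
                  + 0.01))

  # class-uninformative predictions carry no redundancy
  set.seed(7)
  noise_ep <- prd
  noise_ep$epochs <- matrix(rnorm(length(prd$epochs)), nrow(prd$epochs))
  tc0 <- pid_timecourse(obs, noise_ep, n_mc = 5000, seed = 8)
  expect_true(all(abs(tc0$redundancy) < 0.01))

  bad <- prd; bad$classes <- rev(bad$classes)
  expect_error(pid_timecourse(obs, bad), "match")
})
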