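test_that("neighborhood mask is the inclusive modular range", {
  # each input node feeds floor(n/2) nodes either side of itself, inclusive
  mask <- lesionsim:::neighborhood_mask(500L, 100L)
  expect_true(all(colSums(mask) == 101L))
  expect_true(all(rowSums(mask) == 101L))
  # wraps modulo N: node 0 feeds nodes N-n/2 .. n/2
  m2 <- lesionsim:::neighborhood_mask(10L, 2L)
  expect_equal(which(m2[, 1]), c(1L, 2L, 10L))
})

test_that("build_network respects bounds, mask, and determinism", {
  p <- three_layer_params(N = 10L, n = 2L)
  st <- build_network(p, 99L)
  expect_true(all(st$W_im >= 0 & st$W_im <= 10.3))
  expect_true(all(st$W_mo >= 0 & st$W_mo <= 10.3))
  expect_true(all(st$W_im[!st$mask] == 0))
  expect_true(all(st$W_mo[!st$mask] == 0))
  expect_true(all(st$alive))
  expect_equal(sum(st$input_pattern), 5L)
  expect_equal(sum(st$desired_output), 5L)
  st2 <- build_network(p, 99L)
  expect_identical(tl_state_fields(st), tl_state_fields(st2))
  st3 <- build_network(p, 100L)
  expect_false(identical(st$W_im, st3$W_im))
})

test_that("middle-layer firing probability matches the sigmoid law", {
  expect_equal(activation_probability(5.54, 0.25, 5.54), 0.5)
  # hand-evaluated against an independent logistic implementation
  set.seed(4)
  x <- runif(5, -20, 40)
  expect_equal(activation_probability(x, 0.25, 5.54),
               plogis(0.25 * (x - 5.54)), tolerance = 1e-12)
  # sharp-threshold (Heaviside) limit
  expect_equal(activation_probability(5.55, 1e6, 5.54), 1, tolerance = 1e-9)
  expect_equal(activation_probability(5.53, 1e6, 5.54), 0, tolerance = 1e-9)
})

test_that("middle_step silences dead nodes and uses Bernoulli firing", {
  p <- tiny_tl_params(beta = 1e9)  # near-deterministic middle layer
  st <- build_network(p, 1L)
  apply_removal(st, 0:4)
  M <- middle_step(st, p)
  expect_true(all(M[1:5] == 0L))
  # with huge beta, firing equals the deterministic threshold rule elsewhere
  X <- drop(st$W_im %*% st$input_pattern)
  alive <- st$alive
  expect_equal(M[alive], as.integer(X[alive] > p$theta_ml))
})

test_that("output_step is a deterministic Heaviside layer (tie fires)", {
  p <- three_layer_params(N = 10L, n = 2L)
  st <- build_network(p, 7L)
  expect_equal(output_step(st, integer(10), p), rep(0L, 10))
  st$W_mo[st$mask] <- 0
  st$W_mo[1, 2] <- 10.3     # single strong afferent above threshold
  st$W_mo[2, 3] <- 5.54     # exactly at threshold: counts as firing
  m <- integer(10); m[2] <- 1L; m[3] <- 1L
  o <- output_step(st, m, p)
  expect_equal(o[1], 1L)
  expect_equal(o[2], 1L)
  expect_equal(o[3:10], rep(0L, 8))
  expect_identical(o, output_step(st, m, p))
  expect_error(output_step(st, integer(5), p), "length")
})

test_that("hamming counts mismatches and is a metric", {
  expect_equal(hamming(c(1, 0, 1, 1, 0), c(1, 1, 1, 0, 0)), 2L)
  expect_equal(hamming(rep(1L, 500), rep(1L, 500)), 0L)
  expect_equal(hamming(rep(1L, 500), rep(0L, 500)), 500L)
  expect_error(hamming(c(1, 0), c(1, 0, 1)), "equal lengths")
  set.seed(11)
  for (k in 1:50) {
    a <- rbinom(20, 1, 0.5); b <- rbinom(20, 1, 0.5); c <- rbinom(20, 1, 0.5)
    expect_equal(hamming(a, b), sum(vapply(1:20, function(i) a[i] != b[i], logical(1))))
    expect_equal(hamming(a, b), hamming(b, a))
    expect_equal(hamming(a, a), 0L)
    expect_lte(hamming(a, c), hamming(a, b) + hamming(b, c))
  }
})

test_that("eta_of_H follows the disability-dependent law", {
  fx <- eta_policy("fixed", eta0 = 0.01)
  expect_equal(eta_of_H(c(0, 10, 1000), fx), rep(0.01, 3))
  md <- eta_policy("modified", eta0 = 0.01, H0 = 5, Hc = 25)
  expect_equal(eta_of_H(0, md), 0.01)
  expect_equal(eta_of_H(25, md), 0)
  expect_equal(eta_of_H(400, md), 0)
  # hand evaluation at an interior point: 0.01 * sqrt(1 - (10/20)^2)
  expect_equal(eta_of_H(15, md), 0.01 * sqrt(0.75), tolerance = 1e-12)
  # continuous and nonincreasing on a dense grid
  h <- seq(0, 30, by = 0.01)
  e <- eta_of_H(h, md)
  expect_true(all(diff(e) <= 1e-12))
  expect_lt(max(abs(diff(e))), 0.01 * 0.05)  # no jumps
  expect_error(eta_of_H(-1, md), ">= 0")
  expect_error(eta_policy("modified", Hc = NA), "Hc")
})

test_that("hebbian_delta reproduces the +/- eta/2 truth table", {
  p <- three_layer_params()
  expect_equal(hebbian_delta(1, 1, 0.01, p), 0.005)
  expect_equal(hebbian_delta(1, 0, 0.01, p), -0.005)
  expect_equal(hebbian_delta(0, 1, 0.01, p), -0.005)
  expect_equal(hebbian_delta(0, 0, 0.01, p), 0)
})

test_that("train_step gates on H, clips weights, and freezes at eta=0", {
  p <- tiny_tl_params()
  pol <- eta_policy("fixed", eta0 = 0.01)
  st <- build_network(p, 5L)
  # force H = 0: set desired to the output the upcoming middle draw produces
  rng <- lesionsim:::get_rng_state()
  M <- middle_step(lesionsim:::clone_state(st), p)
  st$desired_output <- output_step(st, M, p)
  lesionsim:::set_rng_state(rng)  # train_step re-draws the same middle states
  w1 <- st$W_im; w2 <- st$W_mo
  res <- train_step(st, p, pol)
  expect_equal(res$H, 0L)
  expect_identical(st$W_im, w1)
  expect_identical(st$W_mo, w2)

  # eta = 0 (modified policy beyond Hc) also freezes weights despite H > 0
  st2 <- build_network(p, 6L)
  st2$desired_output <- 1L - st2$desired_output  # guarantee many errors
  md <- eta_policy("modified", eta0 = 0.01, H0 = 0, Hc = 1)
  w1 <- st2$W_im; w2 <- st2$W_mo
  res2 <- train_step(st2, p, md)
  expect_gt(res2$H, 0)
  expect_identical(st2$W_im, w1)
  expect_identical(st2$W_mo, w2)

  # bounds hold across a trajectory with learning active
  st3 <- build_network(p, 7L)
  lo <- Inf; hi <- -Inf
  for (k in 1:300) {
    train_step(st3, p, pol)
    lo <- min(lo, st3$W_im[st3$mask], st3$W_mo[st3$mask])
    hi <- max(hi, st3$W_im, st3$W_mo)
  }
  expect_gte(lo, p$w_min)
  expect_lte(hi, p$w_max)
})

test_that("pre-lesion training composes over durations and is not worse than chance", {
  p <- tiny_tl_params()
  pol <- eta_policy("fixed")
  # duration 0 leaves the state untouched
  st <- build_network(p, 3L)
  f0 <- tl_state_fields(st)
  pre_lesion_train(st, p, pol, 0L)
  expect_identical(tl_state_fields(st), f0)

  # streamed composition: 30 steps == 10 then 20 with a continuing stream
  stA <- build_network(p, 8L)
  rng <- lesionsim:::get_rng_state()
  stB <- lesionsim:::clone_state(stA)
  pre_lesion_train(stA, p, pol, 30L)
  lesionsim:::set_rng_state(rng)
  pre_lesion_train(stB, p, pol, 10L)
  pre_lesion_train(stB, p, pol, 20L)
  expect_identical(tl_state_fields(stA), tl_state_fields(stB))

  # terminal disability <= initial disability in at least 90% of 20 seeds
  improved <- 0L
  for (s in 1:20) {
    stS <- build_network(p, 1000L + s)
    h_first <- train_step(stS, p, pol)$H
    h_last <- NA
    for (k in 1:300) h_last <- train_step(stS, p, pol)$H
    if (h_last <= h_first) improved <- improved + 1L
  }
  expect_gte(improved, 18L)
})
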