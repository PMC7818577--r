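test_that("zero iterations leave the weights at the zero sharing", {
  d <- synth_lr_data(20, 4, seed = 901)
  fit <- train_lr_secure(d$data, 0.1, 0, seed = 901)
  expect_equal(tidy(fit)$estimate, rep(0, 5))
})

test_that("secure training replays bit-identically in the fixed-point simulator", {
  fmt <- fmt64
  d <- synth_lr_data(48, 10, seed = 902)
  fit <- train_lr_secure(d$data, 0.125, 8, fmt, seed = 902, record_truncations = TRUE)
  replay <- train_lr_fixed(d$data, 0.125, 8, fmt, trunc_model = fit$trunc_splits)
  opened <- open_shares(fit$shared_weights)
  expect_true(all(ring_eq(as.numeric(opened), replay$ring_weights, fmt)))
})

test_that("secure weights track the seeded fixed-point oracle within the truncation budget", {
  fmt <- fmt64
  d <- synth_lr_data(64, 16, seed = 903)
  n_iter <- 20
  fit <- train_lr_secure(d$data, 0.125, n_iter, fmt, seed = 903)
  oracle <- train_lr_fixed(d$data, 0.125, n_iter, fmt, trunc_model = "split", seed = 9031)
  # three truncation events per iteration, each within one LSB per path
  budget <- n_iter * 3 * 2^-fmt$a
  expect_lt(max(abs(tidy(fit)$estimate - tidy(oracle)$estimate)), budget)
})

test_that("secure training matches the float trainer's held-out accuracy", {
  d <- synth_lr_data(80, 16, seed = 904)
  train <- d$data[1:64, ]; test <- d$data[65:80, ]
  fit_s <- train_lr_secure(train, 0.125, 20, seed = 904)
  fit_f <- train_lr_clear(train, 0.125, 20)
  expect_lte(abs(accuracy(fit_s, test) - accuracy(fit_f, test)), 0.01 + 1e-9)
})

test_that("partitioning mode does not change the trained model bits", {
  fmt <- fmt64
  d <- synth_lr_data(24, 5, seed = 905)
  fits <- lapply(c("horizontal", "vertical", "arbitrary"), function(mode) {
    run_end_to_end(d$data, n_owners = 3, partition = mode,
                   learning_rate = 0.1, iterations = 4, seed = 905)
  })
  hexes <- lapply(fits, function(f) ring_hex(as.numeric(open_shares(f$shared_weights)), fmt))
  expect_identical(hexes[[1]], hexes[[2]])
  expect_identical(hexes[[1]], hexes[[3]])
  # a single owner holding everything reduces to the same model
  solo <- run_end_to_end(d$data, n_owners = 1, partition = "horizontal",
                         learning_rate = 0.1, iterations = 4, seed = 905)
  expect_identical(ring_hex(as.numeric(open_shares(solo$shared_weights)), fmt), hexes[[1]])
})

test_that("inconsistent owner shards are rejected", {
  d <- synth_lr_data(10, 3, seed = 906)
  shards <- shard_table(d$data, 2, "horizontal")
  expect_s3_class(shards[[1]], "tbl_df")
  expect_equal(sum(vapply(shards, nrow, numeric(1))), 10 * 4)
})

test_that("the closed-form multiplication tally matches a live instrumented run", {
  fmt <- fmt64
  d <- synth_lr_data(32, 8, seed = 907)
  for (variant in c("ripple", "lookahead")) {
    fit <- train_lr_secure(d$data, 0.1, 5, fmt, variant = variant, seed = 907)
    live <- session_tally(fit$session)
    pred <- count_secure_multiplications(32, 8, 5, fmt, variant)
    tot <- pred[pred$phase == "total", ]
    expect_equal(sum(live$ring_mults), tot$ring_mults)
    expect_equal(sum(live$and_gates), tot$and_gates)
    expect_equal(sum(live$masked_bits), tot$masked_bits)
    expect_equal(sum(live$matrix_triples), tot$matrix_triples)
    expect_equal(sum(live$elem_triples), tot$elem_triples)
  }
})

test_that("the tally is a hand-checkable trace for one tiny iteration and scales linearly", {
  fmt <- fmt64
  k <- fmt$a + fmt$b + 1  # 28 decomposed positions
  one <- count_secure_multiplications(1, 1, 1, fmt, "ripple")
  tot <- one[one$phase == "total", ]
  # hand count, n = 1 sample, m = 1 feature (2 columns with bias):
  #   inner product 1x2 * 2x1 = 2 ring mults; activation 2; gradient 2x1 * 1x1 = 2
  expect_equal(tot$ring_mults, 2 + 2 + 2)
  #   decomposition: (2k - 3) ANDs; OR tree over b = 15 bits: 14 ANDs
  expect_equal(tot$and_gates, (2 * k - 3) + 14)
  expect_equal(tot$masked_bits, 2)
  expect_equal(tot$matrix_triples, 2)
  ten <- count_secure_multiplications(1, 1, 10, fmt, "ripple")
  expect_equal(ten[ten$phase == "total", ]$and_gates, 10 * tot$and_gates)
})

test_that("message transcripts depend only on the public dimensions", {
  fmt <- fmt64
  d1 <- synth_lr_data(20, 6, seed = 908)
  d2 <- synth_lr_data(20, 6, seed = 909, separable = FALSE, label_noise = 0.3)
  f1 <- train_lr_secure(d1$data, 0.1, 3, fmt, seed = 1)
  f2 <- train_lr_secure(d2$data, 0.05, 3, fmt, seed = 2)
  expect_identical(f1$session$transcript, f2$session$transcript)
  expect_equal(f1$session$rounds, f2$session$rounds)
})

test_that("correlated randomness is consumed exactly once and depletes loudly", {
  fmt <- fmt64
  d <- synth_lr_data(16, 4, seed = 910)
  fit <- train_lr_secure(d$data, 0.1, 3, fmt, seed = 910)
  r <- fit$session$rand
  # every pooled stream is consumed exactly to its planned size
  expect_equal(r$et_cursor, length(r$et$uA))
  expect_equal(r$bt_cursor, length(r$bt$uA))
  expect_equal(r$mb_cursor, length(r$mb$r2A))
  expect_equal(r$mt_cursor, length(r$mt))
  # and the depleted session cannot run further protocol steps
  x <- share_secret(ring_from_int(1:4, fmt), 64)
  expect_error(securelr:::secure_mul_elem(x, x, fit$session), "depleted")
})

test_that("glance and autoplot expose the protocol cost and the weight comparison", {
  d <- synth_lr_data(16, 4, seed = 911)
  fit <- train_lr_secure(d$data, 0.1, 2, seed = 911)
  g <- glance(fit)
  expect_equal(g$n, 16)
  expect_gt(g$rounds, 0)
  ref <- train_lr_clear(d$data, 0.1, 2)
  p <- autoplot(fit, ref)
  expect_s3_class(p, "ggplot")
})
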