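test_that("min-max normalization maps extrema to 0/1 and rejects flat channels", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  for (seed in 1:5) {
    set.seed(seed)
    u <- rnorm(50, sd = runif(1, 0.1, 10))
    v <- minmax_normalize(u)
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
    expect_identical(order(u), order(v))   # order-preserving
  }
  expect_error(minmax_normalize(c(5, 5, 5)), "degenerate")
  expect_error(minmax_normalize(3), "length")
})

test_that("orthogonalize: forced examples and error cases", {
  expect_equal(orthogonalize(c(1, 1), list(c(1, 0))), c(0, 1))
  # signal already orthogonal to the basis is unchanged
  expect_equal(orthogonalize(c(0, 0, 3), list(c(1, 0, 0), c(0, 1, 0))),
               c(0, 0, 3))
  # empty basis: unchanged (first selected channel is never orthogonalized)
  expect_identical(orthogonalize(c(2, 5, 1)), c(2, 5, 1))
  expect_error(orthogonalize(c(1, 2), list(c(1, 0, 0))), "shape")
  expect_error(orthogonalize(c(1, 2), list(c(0, 0))), "zero vector")
})

test_that("Gram-Schmidt residual equals the normal-equations projection oracle", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(16:64, 1)
    k <- sample(1:3, 1)
    raw <- replicate(k, rnorm(n), simplify = FALSE)
    # build an orthogonal basis sequentially, as the pipeline does
    basis <- list()
    for (b in raw) basis[[length(basis) + 1L]] <- orthogonalize(b, basis)
    u <- rnorm(n)
    v <- orthogonalize(u, basis)
    oracle <- projection_residual_oracle(u, raw)
    expect_lt(max(abs(v - oracle)) / max(abs(oracle), 1e-12), 1e-9)
    # pairwise orthogonality of the accumulated basis
    all_vec <- c(basis, list(v))
    for (a in seq_along(all_vec)) {
      for (b in seq_len(a - 1L)) {
        va <- all_vec[[a]]; vb <- all_vec[[b]]
        expect_lt(abs(sum(va * vb)) / (sqrt(sum(va^2)) * sqrt(sum(vb^2))),
                  1e-8)
      }
    }
  }
})

test_that("window_gamma reproduces the tuned span and simple identities", {
  expect_identical(window_gamma(window_params(T = 160, delta = 4, eta = 20)),
                   236L)
  expect_identical(window_gamma(window_params(T = 50, delta = 7, eta = 1)), 50L)
  expect_identical(window_gamma(window_params(T = 3, delta = 1, eta = 2)), 4L)
  expect_error(window_params(T = 10, delta = 10), "delta")
})

test_that("sliding_segments slices exactly as index arithmetic dictates", {
  p <- window_params(T = 3, delta = 1, eta = 2)
  expect_equal(sliding_segments(c(10, 20, 30, 40), p),
               rbind(c(10, 20, 30), c(20, 30, 40)))
  p1 <- window_params(T = 4, delta = 2, eta = 1)
  expect_equal(sliding_segments(1:9, p1), matrix(1:4, nrow = 1))
  expect_error(sliding_segments(1:3, p), "insufficient")

  # brute-force slice enumeration at the full-size parameters
  set.seed(4)
  sig <- rnorm(300)
  p2 <- window_params(T = 160, delta = 4, eta = 20)
  seg <- sliding_segments(sig, p2)
  for (r in seq_len(p2$eta)) {
    expect_identical(seg[r, ], sig[((r - 1) * p2$delta + 1):((r - 1) * p2$delta + p2$T)])
  }
})

test_that("enumerate_input_offsets matches the published count and brute force", {
  p <- window_params()                       # T=160, delta=4, eta=20, Delta=8
  offs <- enumerate_input_offsets(9600, p)   # 60 s at 160 Hz
  expect_length(offs, 1171)
  expect_identical(offs[1], 0L)

  expect_identical(enumerate_input_offsets(window_gamma(p), p), 0L)
  expect_identical(enumerate_input_offsets(250, p), c(0L, 8L))
  expect_error(enumerate_input_offsets(235, p), "insufficient")

  # count property against a brute-force loop, 100 random parameter draws
  set.seed(11)
  for (i in 1:100) {
    T <- sample(4:40, 1); delta <- sample(seq_len(T - 1), 1)
    eta <- sample(1:6, 1); Delta <- sample(1:20, 1)
    pp <- window_params(T, delta, eta, Delta)
    gam <- window_gamma(pp)
    n <- gam + sample(0:200, 1)
    brute <- c()
    off <- 0
    while (off + gam <= n) { brute <- c(brute, off); off <- off + Delta }
    expect_identical(enumerate_input_offsets(n, pp), as.integer(brute))
  }
})

test_that("build_inputs produces the documented shapes and depth ordering", {
  rec <- random_recording(n_channels = 3L, n_samples = 9600L, seed = 1,
                          channel_names = c("Oz", "T7", "Cz"))
  p <- window_params()
  inputs <- build_inputs(rec, c("Oz", "T7", "Cz"), p, orthogonalize = TRUE)
  expect_length(inputs, 1171)
  expect_identical(dim(inputs[[1]]), c(20L, 160L, 3L))

  # depth slice k of the first input equals the preprocessed channel slice
  sig <- brainprint:::preprocess_channels(rec, c("Oz", "T7", "Cz"), ortho = TRUE)
  for (k in 1:3) {
    expect_equal(inputs[[1]][, , k], sliding_segments(sig[[k]][1:236], p))
  }
  expect_error(build_inputs(rec, c("Oz", "Pz"), p), "lookup")
})

test_that("single-channel orthogonalization is a no-op and duplicates project to zero", {
  rec <- random_recording(n_channels = 1L, n_samples = 800L, seed = 2,
                          channel_names = "Oz")
  p <- tiny_params()
  on_ <- build_inputs(rec, "Oz", p, orthogonalize = TRUE)
  off_ <- build_inputs(rec, "Oz", p, orthogonalize = FALSE)
  expect_equal(on_, off_)

  # duplicate channel: depth slice 2 is the zero signal
  base <- random_recording(n_channels = 1L, n_samples = 800L, seed = 3,
                           channel_names = "Oz")
  dup <- eeg_recording(rbind(base$data[1, ], base$data[1, ]), 160,
                       c("Oz", "T7"))
  inp <- build_inputs(dup, c("Oz", "T7"), p, orthogonalize = TRUE)
  expect_lt(max(abs(inp[[1]][, , 2])), 1e-10)
})

test_that("orthogonalization preserves the channel span", {
  rec <- random_recording(n_channels = 4L, n_samples = 400L, seed = 8)
  chans <- rec$channel_names
  norm_sig <- brainprint:::preprocess_channels(rec, chans, ortho = FALSE)
  orth_sig <- brainprint:::preprocess_channels(rec, chans, ortho = TRUE)
  A <- do.call(cbind, norm_sig)
  B <- do.call(cbind, orth_sig)
  expect_identical(qr(cbind(A, B))$rank, qr(A)$rank)
  expect_identical(qr(A)$rank, 4L)
})

test_that("max_inputs thins offsets evenly without changing content", {
  rec <- random_recording(n_channels = 1L, n_samples = 1600L, seed = 9,
                          channel_names = "Oz")
  p <- tiny_params()
  full <- build_inputs(rec, "Oz", p)
  sub <- build_inputs(rec, "Oz", p, max_inputs = 10)
  expect_length(sub, 10)
  offs_full <- vapply(full, attr, numeric(1), "offset")
  offs_sub <- vapply(sub, attr, numeric(1), "offset")
  expect_true(all(offs_sub %in% offs_full))
  i <- match(offs_sub[4], offs_full)
  expect_equal(sub[[4]], full[[i]])
})
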