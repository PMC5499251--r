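test_that("the frequency slice function has its closed-form properties", {
  expect_identical(fsf(0), 1)
  expect_equal(fsf(2), exp(-2))
  xs <- seq(0.1, 6, by = 0.1)
  expect_equal(fsf(-xs), fsf(xs)) # even
  expect_true(all(diff(fsf(xs)) < 0)) # strictly decreasing in |x|
  expect_true(all(fsf(c(xs, -xs, 0)) > 0 & fsf(c(xs, -xs, 0)) <= 1))
})

test_that("the scale function follows the spectral slope around delta", {
  # 16-bin toy spectrum rising to a max at 10 Hz then falling
  u <- 0:15
  mag <- c(0.1, seq(0.2, 1, length.out = 10), seq(0.9, 0.5, length.out = 5))
  q <- scale_q(mag, u, q_min = 0.5)
  expect_equal(u[which.max(mag)], 10)
  expect_true(all(q[2:10] == 11)) # rising limb: delta + 1
  expect_true(all(q[12:15] == 9)) # falling limb: delta - 1
  # constant magnitude: sign(0) = 0, q = delta everywhere
  qc <- scale_q(rep(1, 16), u, q_min = 0.5)
  expect_true(all(qc == qc[1]))
  expect_error(scale_q(rep(0, 16), u), "degenerate")
  # pure tone: delta is the tone frequency
  fs <- 128; n <- 128
  tone <- sin(2 * pi * 10 * (0:(n - 1)) / fs)
  half <- Mod(stats::fft(tone))[1:(n / 2 + 1)]
  u2 <- (0:(n / 2)) * fs / n
  expect_equal(u2[which.max(half[-1]) + 1], 10)
})

test_that("the forward transform localizes tones and is linear at fixed q", {
  fs <- 128; n <- 64
  t <- (0:(n - 1)) / fs
  tone <- sin(2 * pi * 10 * t)
  sg <- mfswt(tone, fs)
  expect_true(all(Mod(mfswt(rep(0, 64), fs)$values) == 0))
  row_energy <- rowSums(Mod(sg$values)^2)
  expect_equal(abs(sg$w_grid[which.max(row_energy)]), 10)
  # linearity at a fixed scale function
  set.seed(8)
  x <- rnorm(n); y <- rnorm(n)
  q <- rep(2, n)
  lhs <- mfswt(3 * x - 2 * y, fs, q = q)$values
  rhs <- 3 * mfswt(x, fs, q = q)$values - 2 * mfswt(y, fs, q = q)$values
  expect_lt(max(Mod(lhs - rhs)), 1e-10)
  # scaling the signal scales the adaptive transform (q is scale-invariant)
  expect_lt(max(Mod(mfswt(2 * x, fs)$values - 2 * mfswt(x, fs)$values)),
            1e-10)
})

test_that("real inputs give conjugate-symmetric spectrogram rows", {
  fs <- 360
  seg <- clean_segments(rep("N", 3))
  # odd length: the signed DFT grid pairs every nonzero frequency exactly
  # (an even length leaves the unpaired Nyquist bin, which breaks exact
  # symmetry by its one-sided window term)
  x <- seg$segments[1, 1:63]
  sg <- mfswt(x, fs)
  w <- sg$w_grid
  for (j in which(w > 0)) {
    jneg <- which(w == -w[j])
    expect_length(jneg, 1)
    expect_lt(max(Mod(sg$values[jneg, ] - Conj(sg$values[j, ]))), 1e-10)
  }
})

test_that("reconstruction from the full-grid spectrogram is exact", {
  seg <- clean_segments(rep(c("N", "V"), 3))
  x <- seg$segments[1, ]
  expect_lt(prd(x, mfswt_inverse(mfswt(x, 360))), 1e-6)
  # zero spectrogram reconstructs to zero
  sg <- mfswt(x, 360)
  sg$values[] <- 0i
  expect_true(all(mfswt_inverse(sg) == 0))
  # partial grid warns
  part <- mfswt(x, 360, w_grid = c(0, 5, 10))
  expect_warning(mfswt_inverse(part), "full DFT")
})

test_that("FFT path matches the direct-summation reference", {
  seg <- clean_segments(rep("V", 2))
  x <- seg$segments[1, 1:64]
  a <- mfswt(x, 360)
  b <- mfswt_direct(x, 360)
  expect_lt(max(Mod(a$values - b$values)), 1e-8)
  expect_lt(max(abs(mfswt_inverse(a) - mfswt_inverse_direct(b))), 1e-8)
})

test_that("PRD matches hand-computed values", {
  x <- c(1, 2, 3)
  expect_identical(prd(x, x), 0)
  expect_identical(prd(x, rep(0, 3)), 100)
  expect_equal(prd(c(3, 4), c(3, 0)), 80)
  expect_error(prd(c(0, 0), c(1, 1)), "zero energy")
})

test_that("images are [0,1]-normalized and scale-invariant", {
  seg <- clean_segments(rep("N", 2))
  x <- seg$segments[1, ]
  img <- tf_image(mfswt(x, 360), n_freq = 20, n_time = 30, f_max = 64)
  expect_equal(dim(img$pixels), c(20, 30))
  expect_identical(min(img$pixels), 0)
  expect_identical(max(img$pixels), 1)
  # constant-magnitude spectrogram maps to all zeros
  sg <- mfswt(x, 360)
  sg$values[] <- 1 + 0i
  expect_true(all(tf_image(sg, 10, 10, 64)$pixels == 0))
  # doubling the input leaves the normalized image unchanged
  i1 <- tf_image(mfswt(x, 360), 20, 30, 64)$pixels
  i2 <- tf_image(mfswt(2 * x, 360), 20, 30, 64)$pixels
  expect_lt(max(abs(i1 - i2)), 1e-10)
  expect_error(tf_image(mfswt(x, 360), 10, 10, f_max = 500), "ceiling")
})

test_that("beat image matrices are valid classifier inputs", {
  seg <- clean_segments(rep(c("N", "V"), 2))
  imgs <- beat_images(seg$segments, 360, n_freq = 12, n_time = 16)
  expect_equal(dim(imgs), c(4, 12 * 16))
  expect_true(all(imgs >= 0 & imgs <= 1))
  expect_true(all(apply(imgs, 1, max) == 1))
})
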