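# dither-modulation watermarking: schedule, dither, quantizer, embed/extract

test_that("zigzag schedule is deterministic, DC-free, and capacity-checked", {
  expect_equal(wm_schedule(1, 4, 4), matrix(c(0L, 1L), 1, dimnames = list(NULL, c("n", "m"))))
  s3 <- wm_schedule(3, 8, 8)
  expect_equal(unname(s3), rbind(c(0L, 1L), c(1L, 0L), c(0L, 2L)))
  s <- wm_schedule(40, 8, 8)
  expect_equal(nrow(unique(s)), 40)
  expect_false(any(s[, 1] == 0 & s[, 2] == 0))
  expect_true(all(diff(rowSums(s)) >= 0)) # ascending total order
  # full capacity works, one past it fails
  expect_equal(nrow(wm_schedule(63, 8, 8)), 63)
  expect_error(wm_schedule(64, 8, 8), "capacity")
  # non-square: orders stay within each axis range
  sn <- wm_schedule(30, 4, 16)
  expect_true(all(sn[, 1] < 4 & sn[, 2] < 16))
})

test_that("dither vectors are uniform, seeded, and offset by exactly delta/2", {
  d <- wm_dither(10000, 100, seed = 11)
  expect_true(all(d$d0 >= 0 & d$d0 < 100))
  expect_true(all(d$d1 >= 0 & d$d1 < 100))
  expect_equal((d$d1 - d$d0) %% 100, rep(50, 10000))
  expect_gt(mean(d$d0), 45); expect_lt(mean(d$d0), 55)
  expect_identical(d, wm_dither(10000, 100, seed = 11))
  expect_false(identical(d$d0, wm_dither(10000, 100, seed = 12)$d0))
})

test_that("the quantizer matches the hand-worked example and its bound", {
  expect_equal(wm_quantize(10.3, 1, 4, d0 = 1, d1 = 3), 11)
  # lattice points are fixed points
  expect_equal(wm_quantize(3 * 7 + 2.5, 0, 7, d0 = 2.5, d1 = 6), 3 * 7 + 2.5)
  set.seed(4)
  K <- runif(500, -1e4, 1e4)
  bits <- sample(0:1, 500, replace = TRUE)
  d <- wm_dither(500, 60, seed = 2)
  Kt <- wm_quantize(K, bits, 60, d$d0, d$d1)
  expect_true(all(abs(Kt - K) <= 30 + 1e-9))
  # scalar bit against vector dithers recycles correctly
  expect_equal(wm_quantize(K[1:3], 0, 60, d$d0[1:3], d$d1[1:3]),
               wm_quantize(K[1:3], c(0, 0, 0), 60, d$d0[1:3], d$d1[1:3]))
})

test_that("embedding snaps carrier moments onto their lattices and nothing else", {
  img <- phantom_image(64, 1, seed = 5)
  keys <- wm_keys(0.3, 0.7, 120, seed = 9)
  bits <- random_message(30, seed = 9)
  emb <- wm_embed(img, bits, keys)
  bx <- kraw_basis(0.3, 64); by <- kraw_basis(0.7, 64)
  after <- kraw_moments(emb$watermarked, bx, by, orders = emb$schedule)$values
  expect_lt(max(abs(after - emb$moments_modified)), 1e-6)
  # modified moments are exactly on the bit's lattice
  d <- wm_dither(30, 120, seed = 9)
  dd <- ifelse(bits == 1, d$d1, d$d0)
  expect_equal((emb$moments_modified - dd) / 120,
               round((emb$moments_modified - dd) / 120), tolerance = 1e-9)
  # non-carrier moments untouched
  K0 <- matrix(kraw_moments(img, bx, by)$values, 64, 64)
  K1 <- matrix(kraw_moments(emb$watermarked, bx, by)$values, 64, 64)
  carrier <- cbind(emb$schedule[, 1] + 1, emb$schedule[, 2] + 1)
  K0[carrier] <- 0; K1[carrier] <- 0
  expect_lt(max(abs(K1 - K0)), 1e-6)
})

test_that("extraction inverts embedding across strengths, lengths and localities", {
  img <- phantom_image(128, 0, seed = 21)
  for (delta in c(50, 100, 200, 300)) for (L in c(10, 100, 200)) for (p in c(0.1, 0.5, 0.9)) {
    keys <- wm_keys(p, p, delta, seed = 31)
    bits <- random_message(L, seed = L + delta)
    emb <- wm_embed(img, bits, keys)
    expect_equal(bit_error_rate(bits, wm_extract(emb$watermarked, keys, L)), 0)
    expect_equal(bit_error_rate(bits, wm_extract(emb$exported, keys, L)), 0)
  }
})

test_that("decoder decision regions behave like QIM codebooks", {
  img <- phantom_image(64, 2, seed = 13)
  delta <- 80
  keys <- wm_keys(0.4, 0.4, delta, seed = 3)
  bits <- random_message(40, seed = 3)
  emb <- wm_embed(img, bits, keys)
  bx <- kraw_basis(0.4, 64)
  A <- bx$values[emb$schedule[, 1] + 1, , drop = FALSE]
  B <- bx$values[emb$schedule[, 2] + 1, , drop = FALSE]
  shift_carriers <- function(img, eps) img + crossprod(A, eps * B)
  # |eps| < delta/4 keeps every bit
  for (eps in c(0.24 * delta, -0.24 * delta)) {
    got <- wm_extract(shift_carriers(emb$watermarked, rep(eps, 40)), keys, 40)
    expect_equal(bit_error_rate(bits, got), 0)
  }
  # a systematic +delta/2 shift lands on the opposite codebook: all bits flip
  got <- wm_extract(shift_carriers(emb$watermarked, rep(delta / 2, 40)), keys, 40)
  expect_equal(bit_error_rate(bits, got), 1)
})

test_that("bit error rate counts differing positions", {
  expect_equal(bit_error_rate(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(bit_error_rate(c(1, 0, 1), c(0, 1, 0)), 1)
  expect_equal(bit_error_rate(c(1, 0, 1, 1), c(1, 1, 1, 1)), 0.25)
  expect_error(bit_error_rate(c(1, 0), c(1, 0, 1)), "length")
  expect_error(bit_error_rate(c(1, 2), c(1, 0)), "bits")
})

test_that("the watermark lands where the locality parameters point", {
  for (seed in c(2, 8)) {
    img <- phantom_image(128, 0, seed = seed)
    bits <- random_message(200, seed = seed)
    lo <- wm_embed(img, bits, wm_keys(0.1, 0.1, 300, seed = 1))
    hi <- wm_embed(img, bits, wm_keys(0.9, 0.9, 300, seed = 1))
    c_lo <- diff_centroid(lo$watermarked - img)
    c_hi <- diff_centroid(hi$watermarked - img)
    expect_true(all(c_lo < 64))  # top-left quadrant
    expect_true(all(c_hi > 64))  # bottom-right quadrant
  }
})

test_that("pixel distortion grows with the embedding strength", {
  img <- phantom_image(128, 1, seed = 17)
  bits <- random_message(200, seed = 17)
  mad <- vapply(c(50, 100, 200, 300), function(delta) {
    emb <- wm_embed(img, bits, wm_keys(0.5, 0.5, delta, seed = 4))
    mean(abs(emb$watermarked - img))
  }, numeric(1))
  expect_true(all(diff(mad) > 0))
})

test_that("embedding validates message and capacity", {
  img <- rand_image(8, seed = 2)
  keys <- wm_keys(0.5, 0.5, 50)
  expect_error(wm_embed(img, rep(2, 3), keys), "bits")
  expect_error(wm_embed(img, rep(0L, 64), keys), "capacity")
  expect_error(wm_keys(0.5, 0.5, -1), "delta")
  expect_error(wm_keys(1.1, 0.5, 10), "p1")
})
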