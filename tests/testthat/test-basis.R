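# weight, norm, and orthonormal basis construction

test_that("binomial weight function matches hand-evaluated values and sums to 1", {
  expect_equal(kraw_weight(0.5, 2), c(0.25, 0.5, 0.25))
  for (p in c(0.1, 0.37, 0.9)) for (N in c(1, 7, 63, 255)) {
    w <- kraw_weight(p, N)
    expect_length(w, N + 1)
    expect_true(all(w > 0))
    expect_equal(sum(w), 1)
  }
  # symmetry at p = 0.5
  w <- kraw_weight(0.5, 17)
  expect_equal(w, rev(w))
})

test_that("weight and norm reject invalid parameters", {
  expect_error(kraw_weight(0, 4), "p")
  expect_error(kraw_weight(1, 4), "p")
  expect_error(kraw_weight(0.5, 0), "N")
  expect_error(kraw_norm(-0.1, 4), "p")
  expect_error(kraw_norm(0.5, 0.5), "N")
})

test_that("Krawtchouk norm has rho(0) = 1, rho(1; 0.5, 4) = 0.25, all positive", {
  for (p in c(0.1, 0.5, 0.8)) for (N in c(1, 5, 50)) {
    r <- kraw_norm(p, N)
    expect_equal(r[1], 1)
    expect_true(all(r > 0))
  }
  expect_equal(kraw_norm(0.5, 4)[2], 0.25)
  # log form agrees with the direct form where both are representable
  expect_equal(kraw_norm(0.2, 30, log = TRUE), log(kraw_norm(0.2, 30)))
})

test_that("basis rows are orthonormal and row 0 is the square-root weight", {
  for (p in seq(0.1, 0.9, by = 0.2)) for (size in c(8, 32, 64)) {
    b <- kraw_basis(p, size)
    G <- tcrossprod(b$values)
    expect_lt(max(abs(G - diag(size))), 1e-8)
    expect_equal(b$values[1, ], sqrt(kraw_weight(p, size - 1)), tolerance = 1e-12)
  }
})

test_that("basis entries match arbitrary-precision direct evaluation", {
  # Reference values computed once with mpmath (60 decimal digits) from the
  # terminating hypergeometric sum 2F1(-n, -x; -N; 1/p) scaled by
  # sqrt(w(x)/rho(n)), with the standard rising-factorial Pochhammer symbol.
  v8 <- matrix(c(
    0.28697438910118791, 0.49705422239429774, 0.56360651167281593,
    0.47633444133297773, 0.31183409050326746, 0.15812874501494028,
    0.059767047777182369, 0.014788509052639485,
    0.49705422239429774, 0.45095975430186672, 0.046485481604475176,
    -0.35358662305013746, -0.48867320368524403, -0.37822493307554435,
    -0.19225061768431331, -0.059767047777182369,
    0.56360651167281593, 0.046485481604475176, -0.41582003318743555,
    -0.25243712088359747, 0.22358555409507118, 0.47487545735697902,
    0.37822493307554435, 0.15812874501494028,
    0.47633444133297773, -0.35358662305013746, -0.25243712088359747,
    0.33048071048095984, 0.29850879384031553, -0.22358555409507118,
    -0.48867320368524403, -0.31183409050326746,
    0.31183409050326746, -0.48867320368524403, 0.22358555409507118,
    0.29850879384031553, -0.33048071048095984, -0.25243712088359747,
    0.35358662305013746, 0.47633444133297773,
    0.15812874501494028, -0.37822493307554435, 0.47487545735697902,
    -0.22358555409507118, -0.25243712088359747, 0.41582003318743555,
    0.046485481604475176, -0.56360651167281593,
    0.059767047777182369, -0.19225061768431331, 0.37822493307554435,
    -0.48867320368524403, 0.35358662305013746, 0.046485481604475176,
    -0.45095975430186672, 0.49705422239429774,
    0.014788509052639485, -0.059767047777182369, 0.15812874501494028,
    -0.31183409050326746, 0.47633444133297773, -0.56360651167281593,
    0.49705422239429774, -0.28697438910118791), 8, 8, byrow = TRUE)
  expect_lt(max(abs(kraw_basis(0.3, 8)$values - v8)), 1e-10)

  sel <- rbind(c(0, 0), c(1, 5), c(5, 1), c(10, 16), c(16, 10), c(15, 15),
               c(20, 31), c(25, 7), c(31, 0), c(31, 31))
  ref32 <- list(
    "0.1" = c(0.1953254782349056, -0.37689022171775628, -0.37689022171775628,
              -0.038510910189666458, -0.038510910189666458, 0.25677814543049925,
              0.010146022271875259, -9.9277418577756168e-5,
              3.1622776601683793e-16, -0.1953254782349056),
    "0.5" = c(2.1579186437577744e-5, 0.033549361788841379, 0.033549361788841379,
              -0.16868803108365998, -0.16868803108365998, -0.13886206472581278,
              0.19856641005524172, 0.059662353045330334, 2.1579186437577744e-5,
              -2.1579186437577744e-5),
    "0.7" = c(7.8592200394437806e-9, 0.00017634296400044297,
              0.00017634296400044297, -0.16252534094958984,
              -0.16252534094958984, -0.18247040210045911,
              0.0076405123878624695, -0.24213577283828593,
              0.0039720949388810662, -7.8592200394437806e-9))
  for (p in c(0.1, 0.5, 0.7)) {
    V <- kraw_basis(p, 32)$values
    got <- V[cbind(sel[, 1] + 1, sel[, 2] + 1)]
    expect_lt(max(abs(got - ref32[[as.character(p)]])), 1e-10)
  }
})

test_that("basis is symmetric in (n, x) and finite at large sizes", {
  for (p in c(0.1, 0.9)) {
    V <- kraw_basis(p, 256)$values
    expect_true(all(is.finite(V)))
    expect_lt(max(abs(V - t(V))), 1e-10) # K_n(x) = K_x(n) duality
  }
})

test_that("low-order basis energy follows the locality parameter", {
  size <- 60
  for (n in 0:5) {
    peak_low <- which.max(abs(kraw_basis(0.1, size)$values[n + 1, ]))
    peak_high <- which.max(abs(kraw_basis(0.9, size)$values[n + 1, ]))
    expect_lte(peak_low, size / 3)       # first third when p = 0.1
    expect_gte(peak_high, 2 * size / 3)  # last third when p = 0.9
  }
})

test_that("basis construction rejects invalid and oversized inputs", {
  expect_error(kraw_basis(0, 16), "p")
  expect_error(kraw_basis(1.5, 16), "p")
  expect_error(kraw_basis(0.5, 1), "size")
  expect_error(kraw_basis(0.5, 513), "cap")
})
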