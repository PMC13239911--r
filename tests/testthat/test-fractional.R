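test_that("GL coefficients match closed-form values and handle integer orders", {
  expect_identical(glCoefficients(0.7, 1), 1)
  expect_equal(glCoefficients(1, 3), c(1, -1, 0), tolerance = 1e-15)
  expect_equal(glCoefficients(1.5, 3), c(1, -1.5, 0.375), tolerance = 1e-15)
  expect_equal(glCoefficients(2, 5), c(1, -2, 1, 0, 0), tolerance = 1e-15)
  w <- glCoefficients(1.3, 8)
  expect_identical(w[1], 1)
  expect_identical(w[2], -1.3)
  expect_true(all(is.finite(w)))
  expect_error(glCoefficients(0, 3), "beta")
  expect_error(glCoefficients(1.3, 0), "K")
})

test_that("GL partial weight sums shrink towards zero as K grows", {
  for (beta in c(0.5, 1.3, 1.7, 2)) {
    sums <- sapply(c(2, 4, 8, 16, 32), function(K) sum(glCoefficients(beta, K)))
    expect_true(all(diff(abs(sums)) <= 1e-12),
                info = paste("beta =", beta))
    expect_lt(abs(sums[length(sums)]), 0.2)
  }
})

test_that("fractional difference reduces to the backward difference at order 1", {
  op <- fracDiffOperator(1, 2, "replicate")
  v <- matrix(c(5, 7, 4), ncol = 1)
  expect_equal(fracDiff(v, op, "rows"), matrix(c(0, 2, -3), ncol = 1))
  set.seed(11)
  M <- matrix(rnorm(48), 8, 6)
  expect_equal(fracDiff(M, op, "rows"), rbind(0, diff(M)), tolerance = 1e-14)
  expect_equal(fracDiff(M, op, "cols"), t(rbind(0, diff(t(M)))),
               tolerance = 1e-14)
  # order 1 with replicate padding annihilates constants
  C <- matrix(3.7, 5, 5)
  expect_equal(fracDiff(C, op, "rows"), matrix(0, 5, 5))
})

test_that("fractional truncation does not annihilate constants", {
  op <- fracDiffOperator(1.5, 3, "replicate")
  ones <- matrix(1, 4, 4)
  expect_equal(fracDiff(ones, op, "rows"), matrix(-0.125, 4, 4),
               tolerance = 1e-14)
})

test_that("fracDiff and fracAdjoint are linear", {
  op <- fracDiffOperator(1.3, 3)
  set.seed(3)
  U <- matrix(rnorm(30), 6, 5)
  V <- matrix(rnorm(30), 6, 5)
  expect_equal(fracDiff(2 * U - 3 * V, op, "rows"),
               2 * fracDiff(U, op, "rows") - 3 * fracDiff(V, op, "rows"),
               tolerance = 1e-12)
  expect_equal(fracAdjoint(2 * U - 3 * V, op, "cols"),
               2 * fracAdjoint(U, op, "cols") - 3 * fracAdjoint(V, op, "cols"),
               tolerance = 1e-12)
})

test_that("fracAdjoint is the exact adjoint of fracDiff", {
  set.seed(42)
  for (beta in c(1, 1.3, 1.7)) {
    for (bnd in c("replicate", "zero")) {
      op <- fracDiffOperator(beta, 3, bnd)
      for (axis in c("rows", "cols")) {
        u <- matrix(rnorm(16 * 16), 16, 16)
        p <- matrix(rnorm(16 * 16), 16, 16)
        expect_equal(sum(fracDiff(u, op, axis) * p),
                     sum(u * fracAdjoint(p, op, axis)),
                     tolerance = 1e-10,
                     info = paste(beta, bnd, axis))
      }
    }
  }
  # 1x1 grid, zero boundary: only w_0 survives, adjoint(p) = p
  op1 <- fracDiffOperator(1.3, 3, "zero")
  expect_equal(fracAdjoint(matrix(2.5), op1, "rows"), matrix(2.5))
  # 1x1 grid, replicate boundary: every lag clamps to the same entry, so
  # both operator and adjoint multiply by the weight sum
  opr <- fracDiffOperator(1.3, 3, "replicate")
  w <- sum(opr@weights)
  expect_equal(fracDiff(matrix(2.5), opr, "rows"), matrix(2.5 * w))
  expect_equal(fracAdjoint(matrix(2.5), opr, "rows"), matrix(2.5 * w))
})

test_that("fracAdjoint matches the transpose of the materialised operator", {
  for (bnd in c("zero", "replicate")) {
    op <- fracDiffOperator(1, 2, bnd)
    D <- materializeOp(function(U) fracDiff(U, op, "rows"), 5, 3)
    A <- materializeOp(function(P) fracAdjoint(P, op, "rows"), 5, 3)
    expect_equal(A, t(D), tolerance = 1e-14, info = bnd)
  }
  op <- fracDiffOperator(1.7, 4, "replicate")
  D <- materializeOp(function(U) fracDiff(U, op, "cols"), 4, 6)
  A <- materializeOp(function(P) fracAdjoint(P, op, "cols"), 4, 6)
  expect_equal(A, t(D), tolerance = 1e-12)
})

test_that("anisotropic fractional TV energy matches hand-computed cases", {
  op <- fracDiffOperator(1, 2)
  expect_identical(aftvEnergy(matrix(0, 4, 4), op), 0)
  H <- matrix(c(0, 0, 1, 1), 2, 2) # columns (0,0) and (1,1)
  expect_equal(aftvEnergy(H, op), 2)
  set.seed(9)
  M <- matrix(rnorm(35), 5, 7)
  expect_equal(aftvEnergy(-3.2 * M, op), 3.2 * aftvEnergy(M, op),
               tolerance = 1e-12)
})

test_that("adaptive exponent maps gradients into (1, 2) with the right shape", {
  H <- matrix(0, 8, 8) # perfectly flat: l clamps at 2 - delta
  L <- adaptiveExponent(H, kappa = 1, sigma = 0, delta = 1e-3)
  expect_equal(L, matrix(2 - 1e-3, 8, 8))
  # g = kappa maps to exactly 1.5
  H2 <- matrix(rep(seq(0, 7), each = 8), 8, 8) # constant column gradient 1
  L2 <- adaptiveExponent(H2, kappa = 1, sigma = 0, delta = 1e-3)
  expect_equal(L2[4, 4], 1.5, tolerance = 1e-12)
  # monotone: larger gradient never raises the exponent
  set.seed(5)
  H3 <- matrix(rnorm(100), 10, 10)
  L3 <- adaptiveExponent(H3, kappa = 1, sigma = 0)
  d1 <- fracDiff(H3, fracDiffOperator(1, 2), "rows")
  d2 <- fracDiff(H3, fracDiffOperator(1, 2), "cols")
  g <- sqrt(d1^2 + d2^2)
  ord <- order(g)
  expect_true(all(diff(L3[ord]) <= 1e-12))
  expect_true(all(L3 > 1 & L3 < 2))
})

test_that("AFTV gradient matches central finite differences of the smoothed energy", {
  set.seed(21)
  H <- matrix(rnorm(16 * 16), 16, 16)
  Lfix <- adaptiveExponent(H)
  params <- aftvParams(beta = 1.3, K = 3, exponentField = Lfix)
  G <- aftvGradient(H, params)
  h <- 1e-5
  for (rep in 1:5) {
    V <- matrix(rnorm(16 * 16), 16, 16)
    V <- V / sqrt(sum(V^2))
    fd <- (aftvSmoothedEnergy(H + h * V, params) -
             aftvSmoothedEnergy(H - h * V, params)) / (2 * h)
    expect_equal(sum(G * V), fd, tolerance = 1e-4)
  }
})

test_that("a gradient-flow step decreases the smoothed energy", {
  set.seed(8)
  H <- matrix(rnorm(16 * 16), 16, 16)
  params <- aftvParams(beta = 1, K = 2,
                       exponentField = matrix(1 + 1e-3, 16, 16))
  G <- aftvGradient(H, params)
  expect_lt(aftvSmoothedEnergy(H - 0.01 * G, params),
            aftvSmoothedEnergy(H, params))
  # constant grid: both fractional differences vanish, so does the gradient
  Hc <- matrix(2, 6, 6)
  pc <- aftvParams(beta = 1, K = 2,
                   exponentField = matrix(1.5, 6, 6))
  expect_equal(aftvGradient(Hc, pc), matrix(0, 6, 6), tolerance = 1e-12)
})
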