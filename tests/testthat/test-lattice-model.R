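# Model algebra: lattice, negpotential, conditionals, enumeration oracle,
# coding conversion.

test_that("build_lattice obeys the 4-neighbour rule", {
  g1 <- build_lattice(1, 1)
  expect_equal(g1$n, 1)
  expect_equal(nrow(g1$edges), 0)
  expect_equal(g1$degree, 0)

  g2 <- build_lattice(2, 2)
  expect_equal(nrow(g2$edges), 4)
  expect_equal(g2$degree, rep(2, 4))

  g3 <- build_lattice(3, 3)
  expect_equal(nrow(g3$edges), 12)
  expect_equal(sort(g3$degree), c(2, 2, 2, 2, 3, 3, 3, 3, 4))
  expect_equal(g3$degree[5], 4)  # centre pixel (column-major index 5)

  # edge count formula on a rectangle
  g <- build_lattice(4, 7)
  expect_equal(nrow(g$edges), 4 * 6 + 7 * 3)
  expect_error(build_lattice(0, 3), "positive")
  expect_error(build_lattice(2, -1), "positive")
})

test_that("neighbor_sum matches hand counts and rejects shape mismatch", {
  g <- build_lattice(3, 3)
  z <- matrix(1, 3, 3)
  s <- neighbor_sum(z, g)
  expect_equal(s[2, 2], 4)
  expect_equal(s[1, 1], 2)
  expect_equal(s[1, 2], 3)

  # alternating rows: every pixel sees one +1 and one -1 neighbour
  z2 <- matrix(c(-1, 1, -1, 1), 2, 2)
  expect_equal(neighbor_sum(z2, build_lattice(2, 2)),
               matrix(0, 2, 2))
  expect_error(neighbor_sum(matrix(1, 2, 3), g), "shape")
})

test_that("negpotential matches hand-summed unary and edge terms", {
  # beta = 0, lambda = 0 -> 0 for any state
  g <- build_lattice(2, 2)
  X <- rand_design(4)
  m0 <- autologistic_model(c(0, 0), 0)
  z <- encode_field(matrix(c(1, 0, 0, 1), 2, 2), "pm1")
  expect_equal(negpotential(m0, X, z, g), 0)

  # single edge: 1x2 lattice, Xbeta = 0, lambda = 1, z = (1,1) -> 1
  g12 <- build_lattice(1, 2)
  m1 <- autologistic_model(0, 1)
  expect_equal(negpotential(m1, matrix(0, 2, 1),
                            matrix(1, 1, 2), g12), 1)

  # 2x2, coding (0,1), Xbeta = 0.5 each, lambda = 0.8, z = all 1:
  # 4 unary terms (2.0) + 4 edges * 0.8 (3.2) = 5.2
  m2 <- autologistic_model(0.5, 0.8, coding = "01")
  expect_equal(negpotential(m2, matrix(1, 4, 1), matrix(1, 2, 2), g), 5.2)
})

test_that("independence_expectation has its closed forms", {
  g <- build_lattice(1, 3)
  X <- matrix(c(0, 0, 1), 3, 1)
  m01 <- autologistic_model(1, 0.3, coding = "01")
  mpm <- autologistic_model(1, 0.3, coding = "pm1")
  e01 <- independence_expectation(m01, X, g)
  epm <- independence_expectation(mpm, X, g)
  expect_equal(e01[1, 1], 0.5)
  expect_equal(epm[1, 1], 0.0)
  expect_equal(epm[1, 3], tanh(1))
  expect_equal(e01[1, 3], plogis(1))
})

test_that("enumerate_pmf normalises, caps n, and shows flip-symmetric modes", {
  g1 <- build_lattice(1, 1)
  m <- autologistic_model(0, 0)
  pmf <- enumerate_pmf(m, matrix(1, 1, 1), g1)
  expect_equal(pmf$prob, c(0.5, 0.5))

  set.seed(4)
  g <- build_lattice(2, 3)
  X <- rand_design(6)
  m2 <- autologistic_model(c(0.4, -0.7), 0.6)
  pmf2 <- enumerate_pmf(m2, X, g)
  expect_equal(sum(pmf2$prob), 1, tolerance = 1e-12)

  # beta = 0, pm1: all-H and all-L tie as joint modes
  g22 <- build_lattice(2, 2)
  m3 <- autologistic_model(0, 0.5)
  pmf3 <- enumerate_pmf(m3, matrix(0, 4, 1), g22)
  top <- order(pmf3$prob, decreasing = TRUE)[1:2]
  expect_setequal(rowSums(pmf3$states[top, ]), c(-4, 4))
  expect_equal(pmf3$prob[top[1]], pmf3$prob[top[2]])

  expect_error(enumerate_pmf(m3, matrix(0, 21, 1), build_lattice(3, 7)),
               "n_pixels > 20")
})

test_that("exact_marginals: independence collapse, flip symmetry, interior pull", {
  set.seed(11)
  g <- build_lattice(2, 3)
  X <- rand_design(6)
  for (cod in c("pm1", "01")) {
    m <- autologistic_model(c(0.3, 0.8), 0, coding = cod)
    span <- coding(cod)$span
    expect_equal(exact_marginals(m, X, g),
                 matrix(antilogit(span * X %*% m$beta), 2, 3),
                 tolerance = 1e-12)
  }
  # flip symmetry: pm1, beta = 0, any lambda -> all marginals 1/2
  m0 <- autologistic_model(0, 0.9)
  expect_equal(exact_marginals(m0, matrix(0, 6, 1), g),
               matrix(0.5, 2, 3), tolerance = 1e-12)

  # positive association pulls interior pixels harder than corners
  g9 <- build_lattice(3, 3)
  m9 <- autologistic_model(0.2, 0.3)
  p9 <- exact_marginals(m9, matrix(1, 9, 1), g9)
  expect_gt(p9[2, 2], p9[1, 1])
  expect_gt(p9[2, 2], p9[3, 3])
})

test_that("conditional probabilities agree with the enumeration oracle", {
  # property: every lattice up to 3x4, both codings x both variants
  set.seed(21)
  for (dims in list(c(1, 2), c(2, 2), c(2, 3), c(3, 4))) {
    g <- build_lattice(dims[1], dims[2])
    X <- rand_design(g$n)
    for (cod in c("pm1", "01")) for (ctr in c(FALSE, TRUE)) {
      m <- autologistic_model(rnorm(2, 0, 0.8), runif(1, 0, 1),
                              coding = cod, centred = ctr)
      z <- encode_field(matrix(runif(g$n) > 0.5, dims[1], dims[2]), cod)
      cp <- conditional_probabilities(m, X, z, g)
      pmf <- enumerate_pmf(m, X, g)
      for (i in seq_len(g$n)) {
        expect_equal(as.vector(cp)[i],
                     cond_from_pmf(pmf, z, i, m$coding),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("closed-form conditionals: lambda 0 and saturated neighbourhoods", {
  g <- build_lattice(3, 3)
  m <- autologistic_model(0, 1)
  z <- matrix(1, 3, 3)
  cp <- conditional_probabilities(m, matrix(0, 9, 1), z, g)
  expect_equal(cp[2, 2], plogis(8))   # (H-L) * lambda * 4 = 8
  m0 <- autologistic_model(0, 0)
  expect_equal(conditional_probabilities(m0, matrix(0, 9, 1), z, g),
               matrix(0.5, 3, 3))
})

test_that("coding conversion preserves the joint and round-trips", {
  # independence case: lambda = 0 doubles the unary field
  g <- build_lattice(2, 2)
  u <- matrix(0.3, 2, 2)
  out <- convert_coding(u, 0, g, "pm1", "01")
  expect_equal(out$unary, 2 * u)
  expect_equal(out$lambda, 0)
  expect_equal(convert_coding(u, 0.5, g, "pm1", "01")$lambda, 2.0)

  # enumeration agreement + round-trip identity on random parameters
  set.seed(31)
  for (rep in 1:3) {
    u01 <- matrix(rnorm(4), 2, 2)
    l01 <- runif(1, 0, 2)
    cv <- convert_coding(u01, l01, g, "01", "pm1")
    back <- convert_coding(cv$unary, cv$lambda, g, "pm1", "01")
    expect_equal(back$unary, u01, tolerance = 1e-12)
    expect_equal(back$lambda, l01, tolerance = 1e-12)

    p01 <- enumerate_pmf(autologistic_model(as.vector(u01), l01,
                                            coding = "01"),
                         diag(4), g)
    ppm <- enumerate_pmf(autologistic_model(as.vector(cv$unary), cv$lambda,
                                            coding = "pm1"),
                         diag(4), g)
    expect_equal(p01$prob, ppm$prob, tolerance = 1e-10)
  }
})

test_that("regression-constrained models are not conversion-closed (1x3)", {
  # constant unary + lambda > 0 converts to a degree-dependent unary field
  g <- build_lattice(1, 3)
  cv <- convert_coding(matrix(0.4, 1, 3), 0.8, g, "pm1", "01")
  expect_equal(g$degree, c(1, 2, 1))
  expect_false(length(unique(as.vector(cv$unary))) == 1)
})

test_that("centred model is exactly coding-equivariant (beta/2, lambda/4)", {
  set.seed(41)
  g <- build_lattice(2, 3)
  X <- rand_design(6)
  b01 <- rnorm(2); l01 <- 0.8
  m01 <- autologistic_model(b01, l01, coding = "01", centred = TRUE)
  mpm <- autologistic_model(b01 / 2, l01 / 4, coding = "pm1", centred = TRUE)
  expect_equal(exact_marginals(m01, X, g), exact_marginals(mpm, X, g),
               tolerance = 1e-10)
})

test_that("model JSON round-trips at full precision", {
  m <- autologistic_model(c(pi, -exp(1), 1 / 3), 0.123456789012345,
                          coding = "pm1", centred = TRUE,
                          columns = c("(Intercept)", "1", "2"))
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_identical(m2$beta, m$beta)
  expect_identical(m2$lambda, m$lambda)
  expect_identical(m2$coding$name, "pm1")
  expect_true(m2$centred)
  expect_identical(m2$columns, m$columns)
})
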