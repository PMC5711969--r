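# Sampling, logistic stage 1, pseudolikelihood, MPL, plug-in tuning.

test_that("sample_pixels is balanced, deterministic, and fails loudly", {
  ss <- small_scene_set(size = 16, k = 2, seed = 3)
  s1 <- sample_pixels(ss, "train", 10, 0.5, seed = 5)
  expect_equal(sum(s1$high), 5)
  expect_equal(sum(!s1$high), 5)
  s2 <- sample_pixels(ss, "train", 10, 0.5, seed = 5)
  expect_identical(s1$provenance, s2$provenance)
  expect_identical(s1$bands, s2$bands)
  # no duplicate (scene, row, col)
  key <- with(s1$provenance, paste(scene, row, col))
  expect_false(anyDuplicated(key) > 0)
  # asymmetric fraction
  s3 <- sample_pixels(ss, "validation", 10, 0.3, seed = 5)
  expect_equal(sum(s3$high), 3)
  # shortage error names the class
  expect_error(sample_pixels(ss, "train", 10^6, 0.5, seed = 5),
               "high-class")
})

test_that("fit_logistic recovers a known model and respects the scale convention", {
  set.seed(7)
  n <- 2e4
  x <- matrix(runif(n * 2, -1, 1), n, 2)
  b_true <- c(0.5, -1.2, 2.0)
  p <- plogis(cbind(1, x) %*% b_true)
  y <- runif(n) < p
  design <- cbind("(Intercept)" = 1, x1 = x[, 1], x2 = x[, 2])
  fit <- fit_logistic(design, y, coding = "pm1")
  # logit-scale estimates close to truth (3 SEs ~ few % at n = 2e4)
  expect_equal(as.numeric(fit$b), b_true, tolerance = 0.1)
  expect_equal(fit$beta, fit$b / 2)

  # coding invariance of fitted probabilities at lambda = 0 (identity)
  fit01 <- fit_logistic(design, y, coding = "01")
  g <- build_lattice(n, 1)
  ppm <- antilogit(2 * design %*% fit$beta)
  p01 <- antilogit(1 * design %*% fit01$beta)
  expect_equal(ppm, p01, tolerance = 1e-10)

  # null model: slopes ~ 0 on label-shuffled data, intercept at the
  # base-rate log odds
  y0 <- sample(y)
  fit0 <- fit_logistic(design, y0)
  expect_lt(max(abs(fit0$b[2:3])), 0.1)
  expect_equal(fit0$b[["(Intercept)"]], qlogis(mean(y0)), tolerance = 0.01)
})

test_that("fit_logistic flags rank deficiency and separation", {
  set.seed(8)
  x <- runif(50)
  design <- cbind("(Intercept)" = 1, a = x, b = 2 * x)
  expect_error(fit_logistic(design, x > 0.5), "collinear")
  design2 <- cbind("(Intercept)" = 1, a = x)
  expect_warning(fit <- fit_logistic(design2, x > 0.5), "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$b)))
})

test_that("deviance_binary has its closed forms and hand value", {
  expect_equal(deviance_binary(c(TRUE, FALSE), c(1, 0)), 0)
  m <- 7
  expect_equal(deviance_binary(rep(c(TRUE, FALSE), length.out = m),
                               rep(0.5, m)), 2 * m * log(2))
  # labels (1,0,1,0), p = (.9,.1,.8,.3): -2(log.9 + log.9 + log.8 + log.7)
  hand <- -2 * (log(0.9) + log(0.9) + log(0.8) + log(0.7))
  expect_equal(deviance_binary(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.3)), hand)
  expect_equal(hand, 1.5810791, tolerance = 1e-6)
})

test_that("pseudolikelihood: independence collapse, hand sum, additivity", {
  sc <- tiny_scene(4, 4)
  xb <- design_builder()
  m0 <- autologistic_model(c(0.2, -0.4, 0.6, 0.1), 0)
  X <- xb(sc)
  p <- antilogit(2 * X %*% m0$beta)
  y <- as.numeric(sc$foreground)
  expect_equal(pseudolikelihood(m0, list(sc), xb),
               sum(y * log(p) + (1 - y) * log(1 - p)))

  # 2x2 hand-summed 4-term log product
  fg <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  sc2 <- list(image = array(0.5, c(2, 2, 3)), foreground = fg)
  m <- autologistic_model(c(0.1, 0.3, -0.2, 0.4), 0.7)
  g <- build_lattice(2, 2)
  X2 <- xb(sc2)
  z <- encode_field(fg, "pm1")
  # hand computation: 4-term log product with explicit neighbour sums
  ns <- neighbor_sum(z, g)
  t <- 2 * (matrix(X2 %*% m$beta, 2, 2) + 0.7 * ns)
  pr <- plogis(ifelse(fg, t, -t))
  expect_equal(pseudolikelihood(m, list(sc2), xb), sum(log(pr)))

  # additive across images
  expect_equal(pseudolikelihood(m, list(sc2, sc2), xb),
               2 * pseudolikelihood(m, list(sc2), xb))
})

test_that("MPL gradient matches finite differences (both variants)", {
  set.seed(77)
  scenes <- list(tiny_scene(5, 6, seed = 1), tiny_scene(5, 6, seed = 2))
  xb <- design_builder()
  pre <- lapply(scenes, function(sc) {
    g <- build_lattice(5, 6)
    z <- encode_field(sc$foreground, "pm1")
    list(X = xb(sc), y = as.numeric(sc$foreground),
         s = as.numeric(neighbor_sum(z, g)), graph = g, nr = 5, nc = 6)
  })
  for (ctr in c(FALSE, TRUE)) {
    par <- c(rnorm(4, 0, 0.5), 0.4)
    obj <- autologit:::mpl_objective(par, pre, coding("pm1"), ctr)
    eps <- 1e-6
    fd <- vapply(seq_along(par), function(k) {
      pp <- par; pp[k] <- pp[k] + eps
      pm <- par; pm[k] <- pm[k] - eps
      (autologit:::mpl_objective(pp, pre, coding("pm1"), ctr)$value -
         autologit:::mpl_objective(pm, pre, coding("pm1"), ctr)$value) /
        (2 * eps)
    }, 0)
    expect_equal(obj$gradient, fd, tolerance = 1e-5)
  }
})

test_that("MPL with lambda fixed near 0 matches the logistic MLE optimum", {
  # independence data: MPL over (beta, lambda) should put lambda ~ 0 and
  # beta at the logistic solution
  set.seed(55)
  scenes <- lapply(1:3, function(i) {
    nr <- 40
    img <- array(runif(nr * nr * 3), c(nr, nr, 3))
    eta <- 2 * (0.5 - img[, , 1] + img[, , 3])
    fg <- matrix(runif(nr * nr) < plogis(2 * eta), nr, nr)
    list(image = img, foreground = fg, split = "train", id = paste0("s", i))
  })
  xb <- design_builder()
  mpl <- fit_mpl(scenes, xb)
  expect_true(mpl$converged)
  expect_lt(mpl$model$lambda, 0.05)
  allX <- do.call(rbind, lapply(scenes, xb))
  ally <- unlist(lapply(scenes, function(s) as.vector(s$foreground)))
  ref <- fit_logistic(allX, ally)
  expect_equal(mpl$model$beta, as.numeric(ref$beta), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("tune_lambda_plugin: singleton grid, null data prefers lambda ~ 0", {
  ss <- small_scene_set(size = 20, k = 2, seed = 12)
  xb <- design_builder()
  sr <- tune_lambda_plugin(c(0, -0.5, -0.5, 0.5), 0.7,
                           scenes_split(ss, "validation"), xb,
                           cfg = gibbs_config(10, 20), seed = 2)
  expect_equal(sr$best, 0.7)

  # labels spatially independent given X: criterion minimised at/near 0
  set.seed(66)
  scenes <- lapply(1:2, function(i) {
    nr <- 30
    img <- array(runif(nr * nr * 3), c(nr, nr, 3))
    eta <- 3 * (img[, , 1] - img[, , 2])
    fg <- matrix(runif(nr * nr) < plogis(2 * eta), nr, nr)
    list(image = img, foreground = fg, split = "validation",
         id = paste0("v", i))
  })
  allX <- do.call(rbind, lapply(scenes, xb))
  ally <- unlist(lapply(scenes, function(s) as.vector(s$foreground)))
  beta <- fit_logistic(allX, ally)$beta
  sr2 <- tune_lambda_plugin(beta, seq(0, 1, by = 0.25), scenes, xb,
                            criterion = "deviance",
                            cfg = gibbs_config(30, 80), seed = 4)
  expect_lte(sr2$best, 0.25)
  # deviance at lambda = 0 strictly better than at lambda = 1
  expect_lt(sr2$criterion[1], sr2$criterion[5])
})
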