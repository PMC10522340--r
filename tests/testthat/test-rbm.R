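test_that("energy reduces to known closed forms for fields-only models", {
  card <- c(3L, 2L, 3L)
  states <- smallStates(card, n = 5)
  # empty model: zero energy everywhere
  m0 <- rbm(card, 0)
  expect_equal(energy(m0, states), rep(0, 5))
  # constant fields c at every (site, state): energy -N*c
  mc <- rbm(card, 0, fields = rep(0.7, sum(card)))
  expect_equal(energy(mc, states), rep(-3 * 0.7, 5))
})

test_that("energy with a hidden unit matches the quadrature oracle", {
  m <- smallRBM(c(2L, 2L, 2L), M = 1L, family = "drelu", seed = 7)
  U <- dreluU(m@potentials[[1]]@params[["gamma_plus"]],
              m@potentials[[1]]@params[["gamma_minus"]],
              m@potentials[[1]]@params[["theta_plus"]],
              m@potentials[[1]]@params[["theta_minus"]])
  states <- smallStates(c(2L, 2L, 2L), n = 4, seed = 3)
  for (k in seq_len(nrow(states))) {
    s <- states[k, ]
    idx <- diffrbm:::flatIndex(1:3, s, c(2L, 2L, 2L))
    gterm <- sum(m@fields[idx])
    I <- sum(m@weights[idx, 1])
    expect_equal(energy(m, states)[k], -(gterm + quadCGF(U, I)),
                 tolerance = 1e-8)
  }
})

test_that("exact partition function: uniform, factorized and normalized", {
  expect_equal(exactLogPartition(rbm(c(2L, 2L, 2L), 0)), log(8))
  # fields only factorizes: log prod_i sum_a exp(g_i(a))
  set.seed(9)
  card <- c(3L, 4L)
  g <- rnorm(7)
  m <- rbm(card, 0, fields = g)
  expect_equal(exactLogPartition(m),
               log(sum(exp(g[1:3]))) + log(sum(exp(g[4:7]))))
  # with hidden units probabilities still sum to one
  m2 <- smallRBM(c(3L, 3L, 2L, 2L), M = 2L, family = "gaussian", seed = 4)
  en <- diffrbm:::enumerateStates(m2)
  expect_equal(sum(exp(en$logp)), 1, tolerance = 1e-10)
  expect_error(exactLogPartition(rbm(rep(21L, 9), 0)), "too large")
})

test_that("gibbs sampling is seed-reproducible", {
  m <- smallRBM(c(3L, 3L), M = 1L, seed = 5)
  s1 <- gibbsSample(m, 50, steps = 10, seed = 123)
  s2 <- gibbsSample(m, 50, steps = 10, seed = 123)
  expect_identical(s1, s2)
})

test_that("fields-only gibbs marginals converge to softmax of the fields", {
  set.seed(8)
  card <- c(4L, 3L)
  g <- rnorm(7, sd = 1)
  m <- rbm(card, 0, fields = g)
  s <- gibbsSample(m, 20000, steps = 2, seed = 11)
  for (i in 1:2) {
    idx <- diffrbm:::flatIndex(i, seq_len(card[i]), card)
    p <- exp(g[idx]) / sum(exp(g[idx]))
    f <- tabulate(s[, i], card[i]) / nrow(s)
    se <- sqrt(p * (1 - p) / nrow(s))
    expect_true(all(abs(f - p) < 3.5 * se + 1e-4))
  }
})

test_that("gibbs equilibrium matches exact enumeration on a small RBM", {
  m <- smallRBM(c(2L, 2L, 2L), M = 1L, family = "gaussian", seed = 13,
                sd = 0.5)
  en <- diffrbm:::enumerateStates(m)
  s <- gibbsSample(m, 50000, steps = 25, seed = 17)
  key <- apply(s, 1, paste, collapse = "")
  ekey <- apply(en$states, 1, paste, collapse = "")
  obs <- as.numeric(table(factor(key, levels = ekey)))
  expect_gt(stats::chisq.test(obs, p = exp(en$logp))$p.value, 0.01)
})

test_that("analytic likelihood gradient matches finite differences", {
  card <- c(3L, 2L, 3L)
  m <- smallRBM(card, M = 1L, family = "drelu", seed = 21, sd = 0.3)
  states <- smallStates(card, n = 8, seed = 22)
  gr <- diffrbm:::exactLikelihoodGradient(m, states)
  eps <- 1e-6
  for (k in c(1L, 4L, 8L)) {
    mp <- m; mp@fields[k] <- mp@fields[k] + eps
    mm <- m; mm@fields[k] <- mm@fields[k] - eps
    fd <- (exactMeanLogLik(mp, states) - exactMeanLogLik(mm, states)) /
      (2 * eps)
    expect_equal(gr$G[k], fd, tolerance = 1e-4)
  }
  for (k in c(2L, 7L)) {
    mp <- m; mp@weights[k, 1] <- mp@weights[k, 1] + eps
    mm <- m; mm@weights[k, 1] <- mm@weights[k, 1] - eps
    fd <- (exactMeanLogLik(mp, states) - exactMeanLogLik(mm, states)) /
      (2 * eps)
    expect_equal(gr$W[k, 1], fd, tolerance = 1e-4)
  }
  for (pn in names(m@potentials[[1]]@params)) {
    mp <- m; mp@potentials[[1]]@params[[pn]] <-
      mp@potentials[[1]]@params[[pn]] + eps
    mm <- m; mm@potentials[[1]]@params[[pn]] <-
      mm@potentials[[1]]@params[[pn]] - eps
    fd <- (exactMeanLogLik(mp, states) - exactMeanLogLik(mm, states)) /
      (2 * eps)
    expect_equal(unname(gr$P[1, pn]), fd, tolerance = 1e-4)
  }
})

test_that("fields-only training recovers empirical log-frequencies", {
  set.seed(5)
  card <- rep(21L, 9)
  pwm <- zeroSumGauge(rbm(card, 0, fields = rnorm(sum(card), sd = 1)))
  samp <- gibbsSample(pwm, 5000, steps = 3, seed = 2)
  fit <- trainBackground(samp, config = trainingConfig(nHidden = 0,
                                                       epochs = 300,
                                                       seed = 1))
  f <- positionFrequencies(samp, pseudocount = 0.01 / 21)
  lf <- log(f); lf <- lf - rowMeans(lf)
  gm <- matrix(rbmFields(fit), 9, 21, byrow = TRUE)
  expect_lt(max(abs(gm - lf)), 0.02)
})

test_that("a huge weight penalty drives the weights to zero", {
  sc <- makeScenario(nSites = 4, cardinality = 4, Mb = 0, Md = 0,
                     strength = 0, focusPositions = 2:3, seed = 31)
  samp <- gibbsSample(sc$background, 400, steps = 20, seed = 32)
  fit <- trainBackground(samp, config = trainingConfig(
    nHidden = 2, l21 = 1e4, epochs = 60, seed = 33))
  expect_lt(max(abs(rbmWeights(fit))), 0.02)
})

test_that("training is reproducible under a fixed master seed", {
  samp <- smallStates(c(4L, 4L), n = 200, seed = 41)
  cfg <- trainingConfig(nHidden = 1, epochs = 10, seed = 99)
  f1 <- trainBackground(samp, config = cfg)
  f2 <- trainBackground(samp, config = cfg)
  expect_identical(rbmFields(f1), rbmFields(f2))
  expect_identical(rbmWeights(f1), rbmWeights(f2))
})

test_that("zero-sum gauge preserves energies up to a constant", {
  m <- smallRBM(c(3L, 3L, 2L), M = 2L, family = "drelu", seed = 51)
  states <- smallStates(c(3L, 3L, 2L), n = 10, seed = 52)
  gm <- zeroSumGauge(m)
  d <- energy(gm, states) - energy(m, states)
  expect_lt(diff(range(d)), 1e-10)
  # fields and weights now sum to zero over states at each site
  for (i in 1:3) {
    idx <- diffrbm:::flatIndex(i, seq_len(c(3, 3, 2)[i]), c(3L, 3L, 2L))
    expect_equal(sum(gm@fields[idx]), 0, tolerance = 1e-12)
    expect_equal(colSums(gm@weights[idx, , drop = FALSE]), c(0, 0),
                 tolerance = 1e-12)
  }
})

test_that("parameter recovery: retrained small RBM reproduces planted statistics", {
  m <- zeroSumGauge(smallRBM(c(3L, 3L, 3L), M = 1L, family = "gaussian",
                             seed = 61, sd = 0.6))
  samp <- gibbsSample(m, 10000, steps = 25, seed = 62)
  fit <- trainBackground(samp, config = trainingConfig(
    nHidden = 1, family = "gaussian", epochs = 120, seed = 63))
  # compare single-site marginals and pairwise correlations by enumeration
  enP <- diffrbm:::enumerateStates(m)
  enF <- diffrbm:::enumerateStates(fit)
  pP <- exp(enP$logp); pF <- exp(enF$logp)
  X <- as.matrix(diffrbm:::oneHot(enP$states))
  margP <- colSums(X * pP); margF <- colSums(X * pF)
  expect_lt(max(abs(margP - margF)), 0.03)
  pairP <- t(X) %*% (X * pP); pairF <- t(X) %*% (X * pF)
  expect_lt(max(abs(pairP - pairF)), 0.03)
})
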