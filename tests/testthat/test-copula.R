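test_that("marginal transforms reproduce the empirical CDF", {
  md <- microdata(data.frame(q = c("a", "b", "a", "b")))
  mt <- fitMarginals(md, "q")$q
  expect_equal(mt@cumProbs, c(0.5, 1.0))

  ## degenerate single-category marginal: every draw returns that category
  one <- microdata(data.frame(q = rep("only", 3)))
  m1 <- fitGaussianCopula(one, "q", seed = 1)
  syn <- sampleCopula(m1, 50, seed = 2)
  expect_true(all(microdataFrame(syn)$q == "only"))

  ## 1e5 draws from a 3-category marginal stay within 4-SE binomial bands
  md <- microdata(data.frame(q = rep(c("a", "b", "c"), times = c(50, 30, 20))))
  syn <- sampleCopula(fitGaussianCopula(md, "q", seed = 1), 1e5, seed = 3)
  props <- prop.table(table(microdataFrame(syn)$q))
  target <- c(a = 0.5, b = 0.3, c = 0.2)
  for (nm in names(target)) {
    p <- target[[nm]]
    expect_lt(abs(props[[nm]] - p), 4 * sqrt(p * (1 - p) / 1e5))
  }

  ## distributional transform round-trip: inverse(forward(v)) == v
  mt <- fitMarginals(md, "q")$q
  vals <- microdataFrame(md)$q
  u <- withr::with_seed(9, stats::runif(length(vals)))
  fwd <- reidrisk:::.marginalForward(mt, vals, u)
  expect_identical(reidrisk:::.marginalInverse(mt, fwd), vals)
})

test_that("Gaussian copula fit recovers independence and known dependence", {
  ## independent columns: |rho| < 0.1
  spec <- populationSpec(5000, list(list(name = "x", levels = 5),
                                    list(name = "y", levels = 4)),
                         seed = 21)
  pop <- generateSyntheticPopulation(spec)
  fitInd <- fitGaussianCopula(pop, c("x", "y"), seed = 5)
  expect_lt(abs(copulaCorrelation(fitInd)[1, 2]), 0.1)

  ## generating rho = 0.8 recovered within [0.7, 0.9] at n = 5000
  spec <- populationSpec(5000, list(list(name = "x", levels = 5, dist = "zipf", s = 1),
                                    list(name = "y", levels = 5)),
                         dependence = matrix(c(1, .8, .8, 1), 2), seed = 11)
  pop <- generateSyntheticPopulation(spec)
  fit <- fitGaussianCopula(pop, c("x", "y"), seed = 5)
  rhoHat <- copulaCorrelation(fit)[1, 2]
  expect_gte(rhoHat, 0.7)
  expect_lte(rhoHat, 0.9)

  ## m = 1: trivial 1x1 matrix
  expect_equal(copulaCorrelation(fitGaussianCopula(pop, "x", seed = 1)),
               matrix(1, 1, 1))

  ## fitted matrix is a valid correlation matrix
  r <- copulaCorrelation(fit)
  expect_equal(r, t(r))
  expect_equal(diag(r), rep(1, 2))
  expect_gte(min(eigen(r, symmetric = TRUE)$values), 0)
})

test_that("Gaussian copula sampling honours size, domains, seed and independence", {
  md <- microdata(randomCatFrame(200, c(3, 4), seed = 31))
  fit <- fitGaussianCopula(md, c("q1", "q2"), seed = 7)
  syn <- sampleCopula(fit, 7, seed = 9)
  expect_equal(rowCount(syn), 7L)
  expect_true(all(microdataFrame(syn)$q1 %in% categoryDomains(md)$q1))
  expect_true(all(microdataFrame(syn)$q2 %in% categoryDomains(md)$q2))

  ## same seed: bit-identical tables
  syn2 <- sampleCopula(fit, 7, seed = 9)
  expect_identical(microdataFrame(syn), microdataFrame(syn2))

  ## a zero-correlation model draws (near) independent columns
  fit0 <- fit
  fit0@rho <- diag(1, 2)
  big <- microdataFrame(sampleCopula(fit0, 1e5, seed = 13))
  expect_lt(mutualInformation(big$q1, big$q2), 5e-4)
  expect_lt(cramersV(big$q1, big$q2), 0.05)
})

test_that("a 2-variable d-vine agrees with the Gaussian copula fit", {
  spec <- populationSpec(5000, list(list(name = "x", levels = 5, dist = "zipf", s = 1),
                                    list(name = "y", levels = 5)),
                         dependence = matrix(c(1, .8, .8, 1), 2), seed = 11)
  pop <- generateSyntheticPopulation(spec)
  g <- fitGaussianCopula(pop, c("x", "y"), seed = 5)
  d <- fitDVineCopula(pop, c("x", "y"), seed = 5)
  expect_lt(abs(dvinePairParams(d)[[1]][1] - copulaCorrelation(g)[1, 2]), 0.05)
})

test_that("d-vine fit recovers independence and conditional independence", {
  spec <- populationSpec(5000, list(list(name = "a", levels = 4),
                                    list(name = "b", levels = 5),
                                    list(name = "c", levels = 3)),
                         seed = 3)
  pop <- generateSyntheticPopulation(spec)
  d <- fitDVineCopula(pop, c("a", "b", "c"), seed = 5)
  expect_true(all(abs(unlist(dvinePairParams(d))) < 0.1))

  ## latent Markov chain a -> b -> c: tree-2 parameter near 0
  R <- matrix(c(1, .7, .49, .7, 1, .7, .49, .7, 1), 3)
  spec <- populationSpec(5000, list(list(name = "a", levels = 8),
                                    list(name = "b", levels = 8),
                                    list(name = "c", levels = 8)),
                         dependence = R, seed = 12)
  pop <- generateSyntheticPopulation(spec)
  d <- fitDVineCopula(pop, c("a", "b", "c"), seed = 5)
  expect_lt(abs(dvinePairParams(d)[[2]][1]), 0.1)
  expect_true(all(abs(dvinePairParams(d)[[1]] - 0.7) < 0.1))
})

test_that("d-vine sampling matches contract, marginals and dependence fidelity", {
  md <- microdata(randomCatFrame(300, c(4, 3), seed = 41))
  d <- fitDVineCopula(md, c("q1", "q2"), seed = 7)
  syn <- sampleCopula(d, 11, seed = 9)
  expect_equal(rowCount(syn), 11L)
  expect_true(all(microdataFrame(syn)$q1 %in% categoryDomains(md)$q1))
  expect_identical(microdataFrame(sampleCopula(d, 11, seed = 9)),
                   microdataFrame(syn))

  ## all pair parameters zero: marginal frequencies follow the ECDF
  d0 <- d
  d0@pairParams <- list(0)
  big <- microdataFrame(sampleCopula(d0, 1e5, seed = 13))
  mt <- fitMarginals(md, c("q1", "q2"))
  for (j in c("q1", "q2")) {
    props <- prop.table(table(factor(big[[j]], levels = mt[[j]]@categories)))
    for (i in seq_along(mt[[j]]@probs)) {
      p <- mt[[j]]@probs[i]
      expect_lt(abs(props[[i]] - p), 4 * sqrt(p * (1 - p) / 1e5))
    }
  }

  ## strong dependence is reproduced: synthetic Cramer's V close to sample's
  spec <- populationSpec(5000, list(list(name = "x", levels = 5, dist = "zipf", s = 1),
                                    list(name = "y", levels = 5)),
                         dependence = matrix(c(1, .8, .8, 1), 2), seed = 11)
  pop <- generateSyntheticPopulation(spec)
  d <- fitDVineCopula(pop, c("x", "y"), seed = 5)
  syn <- microdataFrame(sampleCopula(d, 5e4, seed = 17))
  vSample <- cramersV(microdataFrame(pop)$x, microdataFrame(pop)$y)
  expect_lt(abs(cramersV(syn$x, syn$y) - vSample), 0.1)
})

test_that("d-vine inverse-Rosenblatt sampler matches the partial-correlation oracle", {
  ## a hand-built 4-variable model with fine marginals (so discretization
  ## attenuation is negligible) must induce the joint correlation matrix
  ## implied by its partial-correlation parameters
  k <- 50
  marg <- lapply(1:4, function(j)
    new("MarginalTransform", column = paste0("q", j),
        categories = sprintf("q%d_%02d", j, 1:k),
        probs = rep(1 / k, k), cumProbs = cumsum(rep(1 / k, k))))
  names(marg) <- paste0("q", 1:4)
  pp <- list(c(0.6, -0.4, 0.7), c(0.3, 0.2), c(-0.25))
  mod <- new("DVineCopulaModel", marginals = marg, order = 1:4,
             pairParams = pp, seed = 1L)
  syn <- microdataFrame(sampleCopula(mod, 1e5, seed = 3))
  z <- vapply(1:4, function(j) {
    idx <- match(syn[[j]], marg[[j]]@categories)
    u <- (idx - withr::with_seed(60 + j, stats::runif(1e5))) / k
    stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  }, numeric(1e5))
  expect_equal(cor(z), dvineParamsToCorrelation(pp, 4), tolerance = 0.05)
})

test_that("copula fitting is fully deterministic given the seed", {
  md <- microdata(randomCatFrame(400, c(4, 3, 3), seed = 51))
  qi <- c("q1", "q2", "q3")
  g1 <- fitGaussianCopula(md, qi, seed = 5)
  g2 <- fitGaussianCopula(md, qi, seed = 5)
  expect_identical(copulaCorrelation(g1), copulaCorrelation(g2))
  d1 <- fitDVineCopula(md, qi, seed = 5)
  d2 <- fitDVineCopula(md, qi, seed = 5)
  expect_identical(dvinePairParams(d1), dvinePairParams(d2))
  expect_identical(dvineOrder(d1), dvineOrder(d2))
})
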