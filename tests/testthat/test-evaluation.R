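test_that("the population generator honours marginals, seed and independence", {
  ## uniform 4-category variable at N = 1000: counts within 4-SE bands
  spec <- populationSpec(1000, list(list(name = "q", levels = 4)), seed = 5)
  pop <- generateSyntheticPopulation(spec)
  counts <- table(microdataFrame(pop)$q)
  se <- sqrt(1000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 250) < 4 * se))

  ## same spec (same seed): identical tables
  pop2 <- generateSyntheticPopulation(spec)
  expect_identical(microdataFrame(pop), microdataFrame(pop2))

  ## independent spec: pairwise Cramer's V < 0.05 at N = 50,000
  spec <- populationSpec(50000, list(list(name = "a", levels = 4),
                                     list(name = "b", levels = 5),
                                     list(name = "c", levels = 3)),
                         seed = 6)
  df <- microdataFrame(generateSyntheticPopulation(spec))
  expect_lt(cramersV(df$a, df$b), 0.05)
  expect_lt(cramersV(df$a, df$c), 0.05)
  expect_lt(cramersV(df$b, df$c), 0.05)

  ## invalid specs are rejected
  expect_error(populationSpec(100, list(list(name = "q", levels = 3,
                                             dist = "explicit",
                                             probs = c(0.5, 0.6))), seed = 1),
               class = "reidrisk_validation_error")
  expect_error(populationSpec(100, list(list(name = "a", levels = 2),
                                        list(name = "b", levels = 2)),
                              dependence = matrix(c(1, 2, 2, 1), 2), seed = 1),
               class = "reidrisk_validation_error")
})

test_that("zipf and explicit marginals have the stated probabilities", {
  spec <- populationSpec(20000, list(list(name = "q", levels = 3,
                                          dist = "zipf", s = 1)), seed = 9)
  props <- prop.table(table(microdataFrame(generateSyntheticPopulation(spec))$q))
  target <- (1 / 1:3) / sum(1 / 1:3)
  expect_true(all(abs(as.numeric(props) - target) < 0.02))
})

test_that("the simulation harness books runs correctly and isolates estimators", {
  ## population-unique everywhere: true B = 1 in every run; an estimator
  ## that always answers 1 has error 0 everywhere
  pop <- microdata(data.frame(id = sprintf("u%03d", 1:200)))
  seenArgs <- NULL
  oracle <- function(sample, qi, N, seed) {
    seenArgs <<- list(sample = sample, qi = qi, N = N, seed = seed)
    1
  }
  res <- runSimulation(pop, "id", nRuns = 8, methods = list(one = oracle),
                       seed = 17)
  expect_s3_class(res, "SimulationResult")
  expect_equal(nrow(res), 8L)
  expect_true(all(res$true_B == 1))
  expect_true(all(res$error == 0))
  expect_true(all(res$n == round(res$sampling_fraction * 200)))
  expect_true(all(res$sampling_fraction >= 0.01 & res$sampling_fraction <= 0.99))

  ## the estimator interface carries no population information
  expect_named(seenArgs, c("sample", "qi", "N", "seed"))
  expect_s4_class(seenArgs$sample, "MicrodataTable")
  expect_lte(rowCount(seenArgs$sample), 200L)
  expect_equal(seenArgs$N, 200L)

  ## determinism of the whole harness
  res2 <- runSimulation(pop, "id", nRuns = 8, methods = list(one = oracle),
                        seed = 17)
  expect_identical(res$sampling_fraction, res2$sampling_fraction)
  expect_identical(res$qi_subset, res2$qi_subset)
})

test_that("baseline estimators run inside the harness", {
  spec <- populationSpec(2000, list(list(name = "a", levels = 6,
                                         dist = "zipf", s = 1),
                                    list(name = "b", levels = 4)),
                         dependence = matrix(c(1, .4, .4, 1), 2), seed = 23)
  pop <- generateSyntheticPopulation(spec)
  res <- runSimulation(pop, c("a", "b"), nRuns = 6,
                       methods = c("entropy", "hypothesis_test",
                                   "benedetti_franconi"), seed = 31)
  expect_equal(nrow(res), 18L)
  expect_true(all(res$estimate > 0 & res$estimate <= 1))
  expect_equal(res$error, res$estimate - res$true_B)
})

test_that("signed error follows the estimate-minus-truth convention", {
  expect_equal(computeError(0.30, 0.25), 0.05)
  expect_equal(computeError(0.25, 0.25), 0)
  expect_equal(computeError(0.10, 0.40), -0.30)
  est <- reidrisk:::.riskEstimate(0.3, "B_hat", "entropy", 10L, 100L)
  expect_equal(computeError(est, 0.25), 0.05)
  expect_error(computeError(1.2, 0.5), class = "reidrisk_validation_error")
})

test_that("error summaries bin, aggregate and handle empty bins correctly", {
  mk <- function(trueB, err, method = "m") {
    structure(data.frame(method = method, true_B = trueB, error = err,
                         stringsAsFactors = FALSE),
              class = c("SimulationResult", "data.frame"))
  }
  ## binning rule: 0.27 falls in [0.2, 0.3)
  s <- summarizeErrors(mk(0.27, 0.05))
  row <- s[s$count > 0, ]
  expect_equal(c(row$bin_lo, row$bin_hi), c(0.2, 0.3))
  ## singleton: median = q1 = q3
  expect_equal(c(row$median_error, row$q1, row$q3), rep(0.05, 3))
  ## boundary: true risk 1.0 falls in the closed top bin
  sTop <- summarizeErrors(mk(1.0, 0))
  expect_equal(sTop[sTop$count > 0, ]$bin_lo, 0.9)
  ## empty bins are present with count 0 and no statistics
  expect_equal(sum(s$count == 0), 9L)
  expect_true(all(is.na(s$median_error[s$count == 0])))

  ## known errors in one bin: median 0, IQR 0.1
  s3 <- summarizeErrors(mk(rep(0.25, 3), c(-0.1, 0, 0.1)))
  row <- s3[s3$count > 0, ]
  expect_equal(row$median_error, 0)
  expect_equal(row$q3 - row$q1, 0.1)

  ## median/quartiles agree with a sort-based oracle on random bins
  for (s4 in 1:3) {
    errs <- withr::with_seed(700 + s4, stats::rnorm(25, 0, 0.1))
    trueB <- withr::with_seed(800 + s4, stats::runif(25))
    summ <- summarizeErrors(mk(trueB, errs))
    bins <- pmin(findInterval(trueB, seq(0, 0.9, 0.1)), 10)
    for (b in unique(bins)) {
      e <- sort(errs[bins == b])
      got <- summ[round(summ$bin_lo * 10) == b - 1, ]
      expect_equal(got$count, length(e))
      med <- if (length(e) %% 2 == 1) e[(length(e) + 1) / 2] else
        (e[length(e) / 2] + e[length(e) / 2 + 1]) / 2
      expect_equal(got$median_error, med)
    }
  }
})
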