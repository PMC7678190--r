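test_that("percentile interval follows the inclusive type-7 definition", {
  # {1..100}: quantile positions 1 + 0.025*99 and 1 + 0.975*99
  expect_equal(percentileInterval(1:100, 0.95), c(3.475, 97.525),
               tolerance = 1e-12)
  expect_equal(percentileInterval(rep(4.2, 10)), c(4.2, 4.2))
  expect_error(percentileInterval(c(1, NA, 3)), "non-finite")
  expect_error(percentileInterval(5), "at least 2")
})

test_that("percentile interval is equivariant under exp", {
  # at n = 41 and level 0.9 the type-7 quantile positions are integers,
  # so order preservation makes the equivariance exact; between order
  # statistics the linear interpolation makes it approximate
  set.seed(61)
  s <- rnorm(41)
  expect_equal(exp(percentileInterval(s, 0.9)),
               percentileInterval(exp(s), 0.9), tolerance = 1e-12)
  s2 <- rnorm(250)
  expect_equal(exp(percentileInterval(s2, 0.9)),
               percentileInterval(exp(s2), 0.9), tolerance = 1e-3)
})

test_that("wider level gives a containing interval", {
  set.seed(62)
  s <- rt(400, df = 3)
  i95 <- percentileInterval(s, 0.95)
  i99 <- percentileInterval(s, 0.99)
  expect_lte(i99[1], i95[1])
  expect_gte(i99[2], i95[2])
})

test_that("stratified resampling preserves the case/control margin", {
  idx <- mqtlmed:::.bootstrapIndices(caseIdx = 1:40, ctlIdx = 41:100,
                                     n = 100, B = 25, stratified = TRUE,
                                     seed = 5)
  for (b in seq_along(idx)) {
    expect_equal(sum(idx[[b]] <= 40), 40)
    expect_equal(sum(idx[[b]] > 40), 60)
  }
  # unstratified resamples vary the margin but keep the size
  idxU <- mqtlmed:::.bootstrapIndices(1:40, 41:100, n = 100, B = 25,
                                      stratified = FALSE, seed = 5)
  expect_true(all(lengths(idxU) == 100))
  expect_gt(stats::sd(vapply(idxU, function(i) sum(i <= 40),
                             numeric(1))), 0)
})

test_that("identical seeds give bit-identical intervals", {
  co <- makeSimpleCohort(n = 250, seed = 63)
  spec <- simpleSpec()
  cfg <- bootstrapConfig(B = 40, seed = 9L)
  r1 <- bootstrapMediation(co, spec, cfg)
  r2 <- bootstrapMediation(co, spec, cfg)
  expect_identical(r1@ci, r2@ci)
  expect_identical(r1@boot$logSamples, r2@boot$logSamples)
  r3 <- bootstrapMediation(co, spec, bootstrapConfig(B = 40, seed = 10L))
  expect_false(identical(r1@ci, r3@ci))
})

test_that("bootstrapMediation leaves the caller's RNG stream untouched", {
  co <- makeSimpleCohort(n = 200, seed = 64)
  set.seed(123)
  before <- .Random.seed
  invisible(bootstrapMediation(co, simpleSpec(),
                               bootstrapConfig(B = 10, seed = 2L)))
  expect_identical(.Random.seed, before)
})

test_that("point estimates are plug-in fits, intervals exponentiated", {
  co <- makeSimpleCohort(n = 300, seed = 65)
  spec <- simpleSpec()
  r <- bootstrapMediation(co, spec, bootstrapConfig(B = 60, seed = 3L))
  p <- runMediation(co, spec)
  expect_equal(r@estimates, p@estimates, tolerance = 1e-12)
  ok <- stats::complete.cases(r@boot$logSamples)
  expect_equal(unname(r@ci["nie", ]),
               exp(percentileInterval(r@boot$logSamples[ok, "nie"],
                                      0.95)),
               tolerance = 1e-12)
  expect_true(all(r@ci[, "lower"] <= r@ci[, "upper"]))
})
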