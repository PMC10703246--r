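test_that("Mann-Whitney U handles exact, tied and degenerate cases", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)              # 2 / choose(6, 3)
  expect_identical(r$method, "exact")

  same <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 9 / 2)          # n^2 / 2
  expect_equal(same$p, 1)

  expect_equal(mannWhitneyU(rep(2, 4), rep(2, 5))$p, 1)  # all identical
  expect_error(mannWhitneyU(numeric(0), 1:3), "empty")

  # large samples take the tie-corrected normal branch
  big <- mannWhitneyU(1:30, 5:40)
  expect_identical(big$method, "normal")
  ref <- stats::wilcox.test(1:30, 5:40, exact = FALSE, correct = FALSE)
  expect_equal(big$p, ref$p.value, tolerance = 1e-12)
})

test_that("exact p equals full permutation enumeration for small samples", {
  set.seed(77)
  for (na in 2:4) for (nb in 2:4) {
    pool <- sample(1:100, na + nb)        # tie-free: exact branch applies
    a <- pool[seq_len(na)]; b <- pool[na + seq_len(nb)]
    got <- mannWhitneyU(a, b)
    orc <- oracleMannWhitney(a, b)
    expect_equal(got$U, orc$U)
    expect_equal(got$p, orc$p, tolerance = 1e-12)
  }
})

test_that("standard error follows its formula", {
  expect_equal(standardError(rep(7, 5)), 0)
  expect_equal(standardError(c(0, 2)), 1)
  set.seed(3)
  x <- rnorm(17)
  expect_equal(standardError(x),
               sqrt(sum((x - mean(x))^2) / 16) / sqrt(17))
  expect_error(standardError(5), "at least 2")
})

test_that("linear regression reproduces closed forms and invariances", {
  x <- c(1, 2, 3, 4, 5)
  exact <- linearRegressionR2(x, 2 * x + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)

  flat <- linearRegressionR2(x, rep(4, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  set.seed(21)
  xr <- rnorm(40); yr <- 1.4 * xr + rnorm(40, sd = 0.6)
  got <- linearRegressionR2(xr, yr)
  orc <- oracleOls(xr, yr)
  expect_equal(got$slope, orc$slope)
  expect_equal(got$intercept, orc$intercept)
  expect_equal(got$r_squared, orc$r_squared)

  # R^2 is invariant under affine rescaling of either variable
  expect_equal(linearRegressionR2(3 * xr - 7, yr)$r_squared,
               got$r_squared)
  expect_equal(linearRegressionR2(xr, -2 * yr + 11)$r_squared,
               got$r_squared)

  expect_error(linearRegressionR2(rep(1, 5), x), "constant")
  expect_error(linearRegressionR2(1:2, 1:2), "n >= 3")
})

test_that("group comparison flags untested groups and stars significance", {
  set.seed(10)
  ctrl <- rpois(30, 20)
  groups <- list(ctrl = ctrl, wt = rep(0L, 30))
  same <- compareGroups(groups, groups)
  expect_true(all(same$groups$p[!same$groups$untested] == 1))
  expect_true(all(same$groups$significance[!same$groups$untested] == "ns"))
  expect_true(same$groups$untested[same$groups$group == "wt"])
  expect_true(is.na(same$groups$p[same$groups$group == "wt"]))
  expect_equal(same$regression$r_squared, 1)

  expect_error(compareGroups(list(a = 1:3), list(b = 1:3)), "differ")

  # a clearly shifted pair earns a significance star
  shifted <- compareGroups(list(g = rpois(40, 25)),
                           list(g = rpois(40, 5)))
  expect_lte(shifted$groups$p, 0.05)
  expect_true(shifted$groups$significance %in% c("*", "**", "***", "****"))
})

test_that("simulated group shift is detected at study sample sizes", {
  # two arms of simulator truth counts: untreated-like vs knocked-down
  ctrl <- generatePlate(simConfig(frameSize = 256L, nSlices = 1L,
                                  fishProb = 1, spotsPerFish = c(5L, 60L),
                                  seed = 101L))
  mo <- generatePlate(simConfig(frameSize = 256L, nSlices = 1L,
                                fishProb = 1, spotsPerFish = c(1L, 4L),
                                seed = 102L))
  a <- truthCounts(ctrl$truth)[1:90]
  b <- truthCounts(mo$truth)[1:90]
  r <- mannWhitneyU(a, b)
  expect_lte(r$p, 0.05)
  expect_gt(mean(a), mean(b))
})
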