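stillTrack <- function(id, n = 320) {
  data.frame(track_id = id, frame = 0:n, cx = 10, cy = 10)
}
moveTrack <- function(id, n = 320) {
  data.frame(track_id = id, frame = 0:n, cx = (0:n) * 2, cy = 10)
}

test_that("immobility tables count stationary animals per chamber", {
  trajsA <- rbind(moveTrack(1), moveTrack(2), moveTrack(3))
  trajsB <- rbind(stillTrack(1), stillTrack(2), stillTrack(3))
  trajsC <- rbind(moveTrack(1), stillTrack(2), moveTrack(3))
  tab <- immobilityTable(list(`0` = trajsA, `1` = trajsC, `2` = trajsB),
                         nTotal = 3)
  expect_equal(tab$concentration, c(0, 1, 2))
  expect_equal(tab$n_immobile, c(0, 1, 3))
  # totals are conserved
  mobile <- vapply(list(trajsA, trajsC, trajsB), mobileCount, integer(1))
  expect_equal(sum(tab$n_immobile + mobile), sum(tab$n_total))
  # an over-full chamber flags a tracking problem
  expect_error(immobilityTable(list(`1` = trajsA), nTotal = 2),
               "exceeds")
})

test_that("the EC50 of a symmetric midpoint design is the midpoint", {
  rec <- data.frame(concentration = c(1, 2, 4), n_total = 10,
                    n_immobile = c(0, 5, 10))
  fit <- fitEC50(rec)
  expect_equal(fit@ec50, 2, tolerance = 1e-2)
})

test_that("noiseless log-logistic data are recovered to 4 significant figures", {
  conc <- c(0.3, 0.6, 1.2, 2.4, 4.8, 9.6)
  p <- 1 / (1 + (1.5 / conc)^3)
  n <- 1e6
  rec <- data.frame(concentration = conc, n_total = n,
                    n_immobile = round(n * p))
  fit <- fitEC50(rec)
  expect_equal(fit@ec50, 1.5, tolerance = 5e-5)
  expect_equal(fit@slope, 3, tolerance = 5e-5)
  expect_true(fit@converged)
  # fitted response is monotone in concentration
  grid <- predictImmobility(fit, seq(0.1, 20, length.out = 50))
  expect_true(all(diff(grid) >= 0))
  expect_equal(predictImmobility(fit, fit@ec50), 0.5)
})

test_that("the fit agrees with binomial GLM on log-concentration", {
  set.seed(22)
  conc <- c(0.25, 0.5, 1, 2, 4, 8)
  k <- rbinom(6, 40, 1 / (1 + (1.8 / conc)^2.2))
  rec <- data.frame(concentration = conc, n_total = 40, n_immobile = k)
  fit <- fitEC50(rec)
  glmFit <- glm(cbind(k, 40 - k) ~ log(conc), family = binomial)
  b <- coef(glmFit)
  expect_equal(fit@slope, unname(b[2]), tolerance = 1e-4)
  expect_equal(fit@ec50, exp(-unname(b[1]) / unname(b[2])),
               tolerance = 1e-4)
})

test_that("concentration rescaling rescales the EC50, not the slope", {
  rec <- data.frame(concentration = c(0.5, 1, 2, 4, 8), n_total = 20,
                    n_immobile = c(1, 4, 10, 16, 19))
  f1 <- fitEC50(rec)
  rec2 <- rec; rec2$concentration <- rec$concentration * 7
  f2 <- fitEC50(rec2)
  expect_equal(f2@ec50, 7 * f1@ec50, tolerance = 1e-5)
  expect_equal(f2@slope, f1@slope, tolerance = 1e-5)
})

test_that("degenerate dose-response tables are rejected", {
  expect_error(fitEC50(data.frame(concentration = c(1, 2),
                                  n_total = 10, n_immobile = c(0, 10))),
               "3 distinct")
  allLow <- data.frame(concentration = c(1, 2, 4, 8), n_total = 10,
                       n_immobile = c(0, 0, 1, 2))
  expect_error(fitEC50(allLow), "never cross")
  fit <- fitEC50(allLow, extrapolate = TRUE)
  expect_gt(fit@ec50, 8)                  # flagged extrapolation mode
  expect_error(fitEC50(data.frame(concentration = c(1, 2, 4),
                                  n_total = 10, n_immobile = 0)),
               "all 0 or all 1")
})

test_that("bootstrap intervals bracket the estimate deterministically", {
  rec <- data.frame(concentration = c(0.5, 1, 2, 4, 8), n_total = 20,
                    n_immobile = c(1, 4, 10, 16, 19))
  f1 <- fitEC50(rec, ci = "bootstrap", nboot = 60, seed = 5)
  f2 <- fitEC50(rec, ci = "bootstrap", nboot = 60, seed = 5)
  expect_equal(f1@ci, f2@ci)
  expect_true(f1@ci[1] < f1@ec50 && f1@ec50 < f1@ci[2])
})

test_that("concordance matches the textbook covariance formulas", {
  expect_equal(concordance(c(1, 2, 3), c(1, 2, 3))$r_squared, 1)
  fit <- concordance(c(1, 2, 3, 4), c(3, 5, 7, 9))   # y = 2x + 1
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)

  set.seed(23)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20, 0, 0.4)
  cc <- concordance(x, y)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  expect_equal(cc$r_squared,
               sxy^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-12)
  expect_equal(cc$slope, sxy / sum((x - mean(x))^2), tolerance = 1e-12)

  expect_warning(z <- concordance(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(z$r_squared))
})
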