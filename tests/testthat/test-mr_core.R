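test_that("Wald ratio divides effects and is orientation-invariant", {
  w <- wald_ratio(0.020, -0.0181639706277, 0.00649823031615)
  expect_equal(w$theta, -0.908198531384, tolerance = 1e-9)
  expect_equal(w$se, 0.324911515808, tolerance = 1e-9)
  expect_equal(wald_ratio(0.1, 0, 0.05)$theta, 0)
  expect_equal(wald_ratio(-0.02, 0.01, 0.005), wald_ratio(0.02, -0.01, 0.005))
  expect_error(wald_ratio(0, 0.1, 0.1), "undefined ratio")
})

test_that("IVW matches the forced symmetric case and single-variant reduction", {
  two <- data.frame(X = c(1, 1), Y = c(0.5, 1.5), se_Y = c(1, 1))
  fit <- mr_ivw(two)
  expect_equal(fit$beta, 1)
  expect_equal(fit$se, 1 / sqrt(2))

  one <- data.frame(X = 0.020, Y = -0.018164, se_Y = 0.006498)
  w <- wald_ratio(one$X, one$Y, one$se_Y)
  f1 <- mr_ivw(one)
  expect_equal(f1$beta, w$theta)
  expect_equal(f1$se, w$se)

  expect_error(mr_ivw(two[0, ]), "empty")
  expect_error(mr_ivw(data.frame(X = 1, Y = 1, se_Y = 0)), "se_Y")
})

test_that("IVW equals the weighted mean of Wald ratios and is invariant to order and joint sign flips", {
  for (seed in 1:25) {
    s <- rand_instruments(sample(2:8, 1), seed)
    fit <- mr_ivw(s)
    th <- s$Y / s$X
    w <- s$X^2 / s$se_Y^2
    expect_equal(fit$beta, sum(w * th) / sum(w), tolerance = 1e-13)
    expect_equal(fit$se, 1 / sqrt(sum(w)), tolerance = 1e-13)

    perm <- s[sample(nrow(s)), ]
    expect_equal(mr_ivw(perm)$beta, fit$beta, tolerance = 1e-12)

    flip <- s
    k <- sample(nrow(s), 1)
    flip$X[k] <- -flip$X[k]
    flip$Y[k] <- -flip$Y[k]
    expect_equal(mr_ivw(flip)$beta, fit$beta, tolerance = 1e-12)
  }
})

test_that("IVW standard error shrinks monotonically as instruments accrue", {
  s <- rand_instruments(12, 99)
  ses <- vapply(2:12, function(k) mr_ivw(s[1:k, ])$se, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("Cochran's Q matches its closed forms", {
  # homogeneity: identical ratios give Q = 0, p = 1
  hom <- data.frame(X = c(0.5, 1, 2), Y = c(0.25, 0.5, 1), se_Y = c(0.1, 0.2, 0.1))
  q0 <- cochran_q(hom)
  expect_equal(q0$Q, 0)
  expect_equal(q0$pvalue, 1)

  # the symmetric two-instrument case, hand computation
  two <- data.frame(X = c(1, 1), Y = c(0.5, 1.5), se_Y = c(1, 1))
  q2 <- cochran_q(two, beta = 1)
  expect_equal(q2$Q, 0.5)
  expect_equal(q2$df, 1L)
  expect_equal(q2$pvalue, 0.479500122187, tolerance = 1e-9)

  # K = 2 closed form: squared standardized difference under the weights
  for (seed in 1:20) {
    s <- rand_instruments(2, seed + 400)
    th <- s$Y / s$X
    w <- s$X^2 / s$se_Y^2
    expect_equal(cochran_q(s)$Q,
                 (th[1] - th[2])^2 * w[1] * w[2] / (w[1] + w[2]),
                 tolerance = 1e-12)
  }

  # scaling all se_Y by c rescales Q by 1/c^2 with the pooled beta recomputed
  s <- rand_instruments(6, 77)
  sc <- s
  sc$se_Y <- 3 * s$se_Y
  expect_equal(cochran_q(sc)$Q, cochran_q(s)$Q / 9, tolerance = 1e-12)

  expect_error(cochran_q(s[1, , drop = FALSE]), "K >= 2")
})

test_that("Egger regression recovers exact linear structure", {
  X <- c(0.1, 0.2, 0.3, 0.4)
  exact <- data.frame(X = X, Y = 0.1 + 0.3 * X, se_Y = 0.01)
  fit <- suppressWarnings(mr_egger(exact, orient = FALSE))  # zero residual: lm warns
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$slope, 0.3, tolerance = 1e-10)

  through <- data.frame(X = X, Y = 0.3 * X, se_Y = 0.01)
  f0 <- suppressWarnings(mr_egger(through, orient = FALSE))
  expect_equal(f0$intercept, 0, tolerance = 1e-12)
  expect_equal(f0$intercept_or_scale$or_value, 1, tolerance = 1e-12)

  expect_error(mr_egger(exact[1:2, ]), "K >= 3")
  expect_error(mr_egger(data.frame(X = c(1, 1, 1), Y = 1:3, se_Y = 1)),
               "singular design")
})

test_that("zero-intercept weighted regression reduces Egger's slope to IVW", {
  for (seed in 1:10) {
    s <- rand_instruments(sample(4:10, 1), seed + 200)
    w <- 1 / s$se_Y^2
    slope0 <- sum(w * s$X * s$Y) / sum(w * s$X^2)
    expect_equal(slope0, mr_ivw(s)$beta, tolerance = 1e-13)
  }
})

test_that("Egger orientation changes the intercept but not the IVW analogue", {
  s <- rand_instruments(8, 314)
  a <- mr_egger(s, orient = TRUE)
  b <- mr_egger(s, orient = FALSE)
  expect_equal(a$n_snps, b$n_snps)
  # with mixed-sign X the two fits genuinely differ
  expect_false(isTRUE(all.equal(a$intercept, b$intercept)))
  # t vs normal intervals: t is wider at small K
  tn <- mr_egger(s, intercept_dist = "normal")
  expect_lt(tn$intercept_ci_high - tn$intercept_ci_low,
            a$intercept_ci_high - a$intercept_ci_low)
})

test_that("pooling concatenates per policy and counts unique rsids", {
  s1 <- rand_instruments(4, 1)
  s2 <- rand_instruments(3, 2)
  s2$rsid <- sprintf("rs9%02d", 1:3)
  s2$dataset <- "sim2"

  expect_equal(mr_pool(list(s1))$beta, mr_ivw(s1)$beta)
  un <- mr_pool(list(s1, s2))
  expect_equal(un$beta, mr_ivw(rbind(s1, s2))$beta)
  expect_equal(un$n_snps, 7L)
  expect_equal(un$n_rows, 7L)

  # duplicated rsid in a second dataset: contributes a row per dataset,
  # but the SNP count stays unique
  s3 <- s1
  s3$dataset <- "sim3"
  both <- mr_pool(list(s1, s3), dedup_policy = "per_dataset_rows")
  expect_equal(both$n_rows, 8L)
  expect_equal(both$n_snps, 4L)
  first <- mr_pool(list(s1, s3), dedup_policy = "first_dataset")
  expect_equal(first$n_rows, 4L)
  expect_equal(first$beta, mr_ivw(s1)$beta)

  expect_error(mr_pool(list()), "non-empty")
})
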