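test_that("intercept-only fit reproduces the closed-form log-odds", {
  d <- data.frame(y = rep(c(1L, 0L), c(7, 41)), one = 0)
  # single constant term: glm drops nothing, intercept = log(k/(n-k))
  f <- glm(y ~ 1, family = binomial(), data = d)
  expect_equal(unname(coef(f)[1]), log(7 / 41), tolerance = 1e-8)
  # and through the package surface with a null predictor
  d$x <- withr::with_seed(1, rnorm(48))
  m <- fit_logistic(d, "y", "x")
  expect_equal(unname(m$coefficients["(Intercept)"]), log(7 / 41), tolerance = 0.5)
  expect_equal(m$table$or, exp(m$table$estimate), tolerance = 1e-12)
})

test_that("a perfectly separating predictor is flagged and carries no OR", {
  d <- data.frame(y = rep(0:1, each = 10), x = rep(0:1, each = 10))
  m <- fit_logistic(d, "y", "x")
  expect_true(m$separation[["x"]])
  expect_equal(m$separation_kind[["x"]], "complete")
  expect_true(m$model_separated)
  row <- m$table[m$table$term == "x", ]
  expect_true(is.na(row$or) && is.na(row$or_low) && is.na(row$or_high))

  # quasi-separation: boundary overlap only
  dq <- data.frame(y = rep(0:1, each = 10), x = c(1:10, 10:19))
  mq <- fit_logistic(dq, "y", "x")
  expect_equal(mq$separation_kind[["x"]], "quasi")

  # well-mixed predictor is not flagged
  dn <- data.frame(y = rep(0:1, each = 50),
                   x = withr::with_seed(2, rnorm(100)))
  expect_false(fit_logistic(dn, "y", "x")$separation[["x"]])
})

test_that("null predictors recover OR near 1 at large n", {
  d <- withr::with_seed(3, data.frame(y = rbinom(10000, 1, 0.3),
                                      x = rnorm(10000)))
  m <- fit_logistic(d, "y", "x")
  or <- m$table$or[m$table$term == "x"]
  expect_true(or > 0.95 && or < 1.05)
})

test_that("coefficients of the generating model are recovered with low bias", {
  # bias (mean estimate over replicates) below 5% per coefficient at n = 20,000
  truth <- c(-1.768, 3.482, 3.022)
  ests <- vapply(1:5, function(s) {
    d <- withr::with_seed(s, {
      fd <- rnorm(20000, 0.5, 0.35)
      lac <- rnorm(20000, 0, 0.35)
      data.frame(fd = fd, lac = lac,
                 y = rbinom(20000, 1, plogis(truth[1] + truth[2] * fd + truth[3] * lac)))
    })
    unname(fit_logistic(d, "y", c("fd", "lac"))$coefficients[
      c("(Intercept)", "fd", "lac")])
  }, numeric(3))
  bias <- rowMeans(ests) - truth
  expect_true(all(abs(bias) / abs(truth) < 0.05))
})

test_that("VIF flags exact collinearity and matches the car oracle", {
  d <- withr::with_seed(4, data.frame(a = rnorm(100), b = rnorm(100)))
  d$c <- d$a                        # duplicated predictor
  v <- vif(d, c("a", "b", "c"))
  expect_true(all(v[c("a", "c")] >= 10))
  expect_gte(min(v), 1)

  d2 <- withr::with_seed(5, data.frame(x1 = rnorm(200), x2 = rnorm(200)))
  d2$x3 <- 0.7 * d2$x1 + rnorm(200, sd = 0.5)
  d2$resp <- rnorm(200)
  ours <- vif(d2, c("x1", "x2", "x3"))
  oracle <- car::vif(lm(resp ~ x1 + x2 + x3, data = d2))
  expect_equal(unname(ours), unname(oracle[c("x1", "x2", "x3")]),
               tolerance = 1e-8)
})

test_that("univariable screen reports separated terms as unestimable", {
  d <- data.frame(y = rep(0:1, c(41, 7)))
  withr::with_seed(6, {
    d$age <- rnorm(48, 55, 10) + 10 * d$y
    d$capsular <- 0L
    d$capsular[d$y == 0][1:5] <- 1L   # present only in controls: separation-free
    d$perfect <- d$y                  # complete separation
  })
  scr <- univariable_screen(d, "y", c("age", "perfect"))
  expect_true(scr$separated[scr$term == "perfect"])
  expect_true(is.na(scr$or[scr$term == "perfect"]))
  expect_false(scr$separated[scr$term == "age"])
})

test_that("backward elimination drops noise terms and honours the LR threshold", {
  gen <- function(seed, n = 2000) {
    withr::with_seed(seed, {
      x1 <- rnorm(n); x2 <- rnorm(n); noise <- rnorm(n)
      y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 + 0.6 * x2))
      data.frame(y, x1, x2, noise)
    })
  }
  # p_enter = 1 forces all three terms into the multivariable model so the
  # likelihood-ratio elimination itself is exercised
  first_out <- vapply(1:30, function(s) {
    sel <- backward_eliminate(gen(s), "y", c("x1", "x2", "noise"), p_enter = 1)
    if (nrow(sel$elimination_trace)) sel$elimination_trace$term[1] else "none"
  }, character(1))
  # an informative term is never the first casualty; the pure-noise term is
  # eliminated first except when it happens to reach significance itself
  expect_true(all(first_out %in% c("noise", "none")))
  expect_gte(sum(first_out == "noise"), 26)

  sel <- backward_eliminate(gen(99), "y", c("x1", "x2", "noise"), p_enter = 1)
  expect_setequal(sel$final_terms, c("x1", "x2"))
  # every removed term had LR p >= p_stay at its removal step
  expect_true(all(sel$elimination_trace$lr_p >= sel$p_stay))
  # retained terms all significant by LR in the final model
  lrt <- drop1(sel$final$fit, test = "LRT")
  expect_true(all(lrt[["Pr(>Chi)"]][-1] < 0.05))
})

test_that("an empty candidate set yields an empty model, not an error", {
  d <- withr::with_seed(8, data.frame(y = rbinom(200, 1, 0.2),
                                      a = rnorm(200), b = rnorm(200)))
  sel <- backward_eliminate(d, "y", c("a", "b"))
  expect_length(sel$candidates, 0)
  expect_null(sel$final)
  expect_length(sel$final_terms, 0)
})

test_that("duplicated candidates are both reported at VIF >= 10", {
  d <- withr::with_seed(9, {
    x <- rnorm(400)
    data.frame(y = rbinom(400, 1, plogis(x)), x1 = x, x2 = x)
  })
  sel <- backward_eliminate(d, "y", c("x1", "x2"))
  expect_setequal(sel$high_vif_terms, c("x1", "x2"))
})

test_that("fit_logistic validates its inputs", {
  d <- data.frame(y = c(0, 1, 1), x = 1:3)
  expect_error(fit_logistic(d, "y", c("x", "zz")), "not in data")
  expect_error(fit_logistic(data.frame(y = rep(1, 10), x = rnorm(10)), "y", "x"),
               "single class")
  tiny <- data.frame(y = c(0, 1), x = c(2, 5))
  expect_error(fit_logistic(tiny, "y", "x"), "n > number of terms")
})
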