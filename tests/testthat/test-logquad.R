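test_that("k = 0 reduces to the two-parameter model and identities hold", {
  cf <- fx_coefs()
  s0 <- loglq_schedule(cf, 0.02, k = 0, sex = "male")
  cfm <- cf[cf$sex == "male", ]
  lq <- log(0.02)
  expect_equal(s0$mx, exp(cfm$a + cfm$b * lq + cfm$c * lq^2),
               tolerance = 1e-12)
  # degenerate coefficients b=1, c=0, v=0, a=0 give mx = 5q0 at all ages
  toy <- structure(data.frame(sex = "male",
                              age_group_start = age_grid_abridged(100),
                              a = 0, b = 1, c = 0, v = 0),
                   class = c("logquad_coefs", "data.frame"))
  expect_equal(loglq_schedule(toy, 0.07, 5, sex = "male")$mx,
               rep(0.07, 22), tolerance = 1e-12)
  expect_error(loglq_schedule(cf, 1.2, 0, sex = "male"), "0,1")
})

test_that("implied child mortality closes to within 1% relative", {
  cf <- fx_coefs()
  for (s in c("male", "female"))
    for (q5 in c(0.004, 0.01, 0.03, 0.08, 0.15)) {
      lt <- loglq_lifetable(cf, q5, 0, sex = s)
      expect_lt(abs(interval_prob(lt, 0, 5) - q5) / q5, 0.01)
    }
})

test_that("adult mortality is strictly increasing in k", {
  cf <- fx_coefs()
  ks <- seq(-2, 2, length.out = 9)
  a45 <- vapply(ks, function(k)
    interval_prob(loglq_lifetable(cf, 0.015, k, sex = "female"), 15, 45),
    numeric(1))
  expect_true(all(diff(a45) > 0))
})

test_that("solve_k round-trips its target and is monotone", {
  cf <- fx_coefs()
  # root at origin when target equals the k=0 implied value
  t0 <- interval_prob(loglq_lifetable(cf, 0.02, 0, sex = "male"), 15, 45)
  expect_lt(abs(solve_k(cf, 0.02, t0, sex = "male")), 1e-6)
  # round trip to 1e-8 on assorted targets
  ks <- c()
  for (tgt in c(0.05, 0.10, 0.18, 0.30)) {
    k <- solve_k(cf, 0.02, tgt, sex = "male")
    got <- interval_prob(loglq_lifetable(cf, 0.02, k, sex = "male"),
                         15, 45)
    expect_lt(abs(got - tgt), 1e-8)
    ks <- c(ks, k)
  }
  expect_true(all(diff(ks) > 0))  # larger targets need larger k
  expect_error(solve_k(cf, 0.02, 1e-9, sex = "male"), "attainable")
})

test_that("old-age adjustment matches its closed form and its target", {
  cf <- fx_coefs()
  implied <- interval_prob(loglq_lifetable(cf, 0.02, 0.5, sex = "male"),
                           60, 15)
  # target = implied -> zero shift
  f0 <- adjust_old_age(cf, 0.02, 0.5, implied, sex = "male")
  expect_lt(abs(f0$old_age_shift), 1e-9)
  # doubling the cumulative hazard -> one-step shift exactly log 2
  t2 <- 1 - (1 - implied)^2
  f2 <- adjust_old_age(cf, 0.02, 0.5, t2, sex = "male", refine = FALSE)
  expect_equal(f2$old_age_shift, log(2), tolerance = 1e-12)
  # refined shift reproduces arbitrary targets to 1e-6
  set.seed(11)
  for (tgt in stats::runif(5, 0.15, 0.6)) {
    f <- adjust_old_age(cf, 0.02, 0.5, tgt, sex = "male")
    lt <- loglq_lifetable(cf, 0.02, 0.5, sex = "male",
                          old_age_shift = f$old_age_shift)
    expect_lt(abs(interval_prob(lt, 60, 15) - tgt), 1e-6)
    # the shift only acts at ages 60+
    base <- loglq_schedule(cf, 0.02, 0.5, sex = "male")
    shifted <- loglq_schedule(cf, 0.02, 0.5, sex = "male",
                              old_age_shift = f$old_age_shift)
    young <- base$age < 60
    expect_identical(shifted$mx[young], base$mx[young])
    expect_false(any(shifted$mx[!young] == base$mx[!young]))
  }
})

test_that("old-age blending is the bounded arithmetic mean", {
  expect_identical(blend_old_age(0.3, 0.3), 0.3)
  expect_equal(blend_old_age(0.2, 0.4), 0.3)
  set.seed(3)
  a <- stats::runif(50, 0.05, 0.9); b <- stats::runif(50, 0.05, 0.9)
  bl <- mapply(blend_old_age, a, b)
  expect_true(all(bl >= pmin(a, b) & bl <= pmax(a, b)))
})

test_that("intercensal cohort survival converts to old-age mortality", {
  c1 <- data.frame(age_group_start = seq(0, 100, 5),
                   population = rep(1000, 21))
  c2 <- c1
  c2$population <- 1000  # no attrition
  expect_equal(intercensal_old_age_q(c1, c2), 0)
  # cohorts exactly halved: age-flat survival of 0.5; the fitted
  # survival model collapses to its constant-hazard limit, for which
  # the hand-computed conversion is 1 - 0.5^(15/10)
  c3 <- c1
  c3$population[c3$age_group_start %in% c(70, 75, 80)] <- 500
  expect_equal(intercensal_old_age_q(c1, c3), 1 - 0.5^1.5,
               tolerance = 1e-6)
  expect_error(intercensal_old_age_q(c1[c1$age_group_start < 60, ], c2),
               "missing")
})

test_that("generated zero-migration censuses recover old-age mortality", {
  # stationary population under a known table: the second census equals
  # the first and cohort ratios are exact survival; recovery within 5%
  for (s in c("male", "female")) {
    for (tg in list(c(0.015, 76), c(0.005, 84))) {
      mx <- synth_mx_schedule(tg[1], tg[2], s)
      lt <- lifetable(mx, sex = s)
      cen <- data.frame(sex = s, age_group_start = lt$age,
                        population = round(lt$Lx))
      got <- intercensal_old_age_q(cen, cen)
      want <- interval_prob(lt, 60, 15)
      expect_lt(abs(got - want) / want, 0.05)
    }
  }
})
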