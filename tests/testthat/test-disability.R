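test_that("severity classification counts difficulty items", {
  expect_identical(as.character(classify_adl(rep(0, 6))), "none")
  expect_identical(as.character(classify_adl(c(1, 1, 0, 0, 0, 0))),
                   "mild")
  expect_identical(as.character(classify_adl(c(1, 1, 1, 1, 1, 0))),
                   "severe")
  # exhaustive brute force over all 64 flag combinations
  combos <- as.matrix(expand.grid(rep(list(0:1), 6)))
  got <- as.character(classify_adl(combos))
  want <- vapply(rowSums(combos), function(d) {
    if (d == 0) "none" else if (d <= 2) "mild"
    else if (d <= 4) "moderate" else "severe"
  }, character(1))
  expect_identical(got, want)
})

test_that("prevalence tabulates exact cell fractions", {
  toy <- data.frame(
    id = 1:10,
    age = c(62, 63, 64, 67, 68, 69, 62, 63, 67, 68),
    sex = c(rep("male", 6), rep("female", 4)),
    bathing = c(1, 1, 0, 1, 0, 0, 1, 1, 1, 0),
    dressing = c(1, 1, 0, 1, 0, 0, 1, 1, 0, 0),
    eating = c(1, 0, 0, 1, 0, 0, 1, 0, 0, 0),
    transferring = c(1, 0, 0, 1, 0, 0, 1, 0, 0, 0),
    toileting = c(1, 0, 0, 1, 0, 0, 1, 0, 0, 0),
    continence = c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0))
  # cells: male 60-64 (severe, mild, none), male 65-69 (severe, none x2)
  #        female 60-64 (severe, mild), female 65-69 (mild, none)
  p <- adl_prevalence(toy, require_complete = FALSE)
  g <- function(s, ag, sv)
    p$rate[p$sex == s & p$age_group == ag & p$severity == sv]
  expect_equal(g("male", "60-64", "severe"), 1 / 3)
  expect_equal(g("male", "60-64", "mild"), 1 / 3)
  expect_equal(g("male", "65-69", "severe"), 1 / 3)
  expect_equal(g("female", "60-64", "mild"), 1 / 2)
  expect_equal(g("female", "65-69", "mild"), 1 / 2)
  # partition: severities sum to the overall disabled fraction
  agg <- stats::aggregate(rate ~ sex + age_group, p, sum)
  m6064 <- agg$rate[agg$sex == "male" & agg$age_group == "60-64"]
  expect_equal(m6064, 2 / 3)
  # all-severe corner
  toy2 <- toy
  toy2[, ltcisim:::adl_items] <- 1
  p2 <- adl_prevalence(toy2, require_complete = FALSE)
  expect_true(all(p2$rate[p2$severity == "severe"] == 1))
  expect_true(all(p2$rate[p2$severity != "severe"] == 0))
})

test_that("empty cells are reported as errors", {
  toy <- data.frame(id = 1, age = 62, sex = "male", bathing = 1,
                    dressing = 0, eating = 0, transferring = 0,
                    toileting = 0, continence = 0)
  expect_error(adl_prevalence(toy), "empty prevalence cells")
})

test_that("scenario factors scale prevalence multiplicatively", {
  prev <- fx_pipeline()$prevalence
  med <- disability_scenario("medium")
  expect_identical(scale_prevalence(prev, med, 2067)$rate, prev$rate)
  hi <- disability_scenario("high")
  lo <- disability_scenario("low")
  s80 <- scale_prevalence(prev, hi, 2080)
  expect_equal(s80$rate, pmin(prev$rate * 1.008^60, 1),
               tolerance = 1e-12)
  # closed-form worked example: factor 1.6130, 0.10 -> 0.16130
  expect_equal(1.008^60, 1.6130, tolerance = 2e-4)
  tab <- prev
  tab$rate <- 0.10
  expect_equal(scale_prevalence(tab, hi, 2080)$rate[1], 0.16130,
               tolerance = 1e-4)
  # high x low factor product collapses to (1 - r^2)^h
  h <- 37
  expect_equal(1.008^h * 0.992^h, (1 - 0.008^2)^h, tolerance = 1e-12)
  expect_error(scale_prevalence(prev, hi, 2010), "base year")
})

test_that("demand multiplies population by prevalence", {
  res <- fx_pipeline()
  pop <- res$populations$mean
  prev <- res$prevalence
  med <- disability_scenario("medium")
  # zero prevalence -> zero counts
  z <- prev; z$rate <- 0
  d0 <- ltc_demand(pop, z, med, years = 2023:2025)
  expect_true(all(d0$persons == 0))
  # uniform 10% severe prevalence -> a tenth of the 60+ population
  u <- prev
  u$rate <- ifelse(u$severity == "severe", 0.10, 0)
  d1 <- ltc_demand(pop, u, med, years = 2030)
  sev <- d1[d1$severity == "severe", ]
  expect_equal(sev$persons, 0.10 * sev$older_population,
               tolerance = 1e-9)
})

test_that("scenario ratios factor out of the demand exactly", {
  res <- fx_pipeline()
  pop <- res$populations$mean
  prev <- res$prevalence
  dm <- ltc_demand(pop, prev, disability_scenario("medium"),
                   years = c(2030, 2050, 2080))
  dh <- ltc_demand(pop, prev, disability_scenario("high"),
                   years = c(2030, 2050, 2080))
  dl <- ltc_demand(pop, prev, disability_scenario("low"),
                   years = c(2030, 2050, 2080))
  for (y in c(2030, 2050, 2080)) {
    for (sv in c("mild", "moderate", "severe")) {
      m <- dm$persons[dm$year == y & dm$severity == sv]
      h <- dh$persons[dh$year == y & dh$severity == sv]
      l <- dl$persons[dl$year == y & dl$severity == sv]
      if (y < 2080) {
        # exact factorisation while no cell hits the probability cap
        expect_equal(h / m, 1.008^(y - 2020), tolerance = 1e-12)
      } else {
        # far out, the highest cells cap at 1, so the ratio only bounds
        expect_lte(h / m, 1.008^(y - 2020) + 1e-12)
        expect_gte(h / m, 0.95 * 1.008^(y - 2020))
      }
      expect_equal(l / m, 0.992^(y - 2020), tolerance = 1e-12)
      expect_true(l <= m && m <= h)
    }
  }
  # counts never exceed the older population
  expect_true(all(dh$persons <= dh$older_population))
})
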