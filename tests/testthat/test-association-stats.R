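test_that("balanced outcomes give a null coefficient", {
  d <- tibble::tibble(outcome = c(0L, 1L, 0L, 1L),
                      covariate = c(0, 0, 1, 1), age = 5)
  r <- fit_logistic(d)
  expect_equal(r$beta, 0, tolerance = 1e-8)
  expect_equal(r$odds_ratio, 1, tolerance = 1e-8)
  expect_true(r$converged)
})

test_that("MLE matches the grid-search likelihood oracle on small fixtures", {
  fixtures <- list(
    list(y = c(1L, 0L, 1L, 0L, 0L, 1L, 1L, 0L),
         x = c(1, 1, 2, 2, 4, 4, 1, 2)),
    list(y = c(1L, 1L, 0L, 0L, 1L, 0L),
         x = c(0, 1, 0, 1, 1, 0)),
    list(y = c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L, 0L),
         x = c(1, 3, 5, 2, 8, 1, 4, 9, 10, 2))
  )
  for (f in fixtures) {
    d <- tibble::tibble(outcome = f$y, covariate = f$x, age = 1)
    fit <- fit_logistic(d)
    oracle <- grid_logit_oracle(f$y, f$x)
    expect_lt(abs(fit$beta - oracle[["beta"]]), 1e-3)
  }
})

test_that("degenerate model tables are refused, separation is flagged", {
  d <- tibble::tibble(outcome = rep(1L, 5), covariate = 1:5, age = 1:5)
  expect_error(fit_logistic(d), "constant")
  d2 <- tibble::tibble(outcome = c(0L, 1L), covariate = c(2, 2), age = 1:2)
  expect_error(fit_logistic(d2), "covariate is constant")
  # perfectly separated data: reported, never silent
  d3 <- tibble::tibble(outcome = rep(c(0L, 1L), each = 10),
                       covariate = rep(c(0, 1), each = 10), age = 1)
  r <- fit_logistic(d3)
  expect_false(r$converged)
})

test_that("odds ratio and Wald interval follow the closed form", {
  r <- odds_ratio_ci(0, 0.5)
  expect_equal(r$or, 1)
  expect_equal(r$low * r$high, 1, tolerance = 1e-12)  # symmetric on log scale
  r2 <- odds_ratio_ci(2, 0)
  expect_equal(r2$low, exp(2)); expect_equal(r2$high, exp(2))
  r3 <- odds_ratio_ci(log(2), 0.1)
  expect_equal(r3$or, 2)
  expect_equal(r3$low, exp(log(2) - 0.196))
  expect_equal(r3$high, exp(log(2) + 0.196))
  expect_error(odds_ratio_ci(0, -1))
})

test_that("recoding a binary covariate inverts the odds ratio", {
  set.seed(9)
  d <- tibble::tibble(covariate = rep(c(0, 1), each = 25),
                      age = runif(50, 0, 10))
  d$outcome <- rbinom(50, 1, plogis(-0.5 + 0.9 * d$covariate))
  f1 <- fit_logistic(d)
  d2 <- d; d2$covariate <- 1 - d2$covariate
  f2 <- fit_logistic(d2)
  expect_equal(f1$odds_ratio, 1 / f2$odds_ratio, tolerance = 1e-6)
})

test_that("chi-square on 2x2 tables matches hand computation", {
  ct <- chi_square_2x2(matrix(c(14, 0, 4, 12), 2))
  # E = (8.4, 9.6, 5.6, 6.4); sum (O-E)^2/E = 17.5
  expect_equal(ct$chi2, 17.5, tolerance = 1e-12)
  expect_equal(ct$df, 1)
  expect_lt(ct$p_value, 0.001)
  expect_false(ct$yates)

  null <- chi_square_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(null$chi2, 0)
  expect_equal(null$p_value, 1)

  expect_error(chi_square_2x2(matrix(c(0, 0, 4, 12), 2)), "zero margin")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integers")
  expect_error(chi_square_2x2(matrix(1:6, 2)), "2x2")
})

test_that("chi-square is invariant under simultaneous row and column swap", {
  tab <- matrix(c(14, 0, 4, 12), 2)
  swapped <- tab[2:1, 2:1]
  for (y in c(FALSE, TRUE)) {
    expect_equal(chi_square_2x2(tab, yates = y)$chi2,
                 chi_square_2x2(swapped, yates = y)$chi2)
  }
})

test_that("fatal variants require a homozygous infant death", {
  fc <- fatal_example_cohort()
  fv <- identify_fatal_variants(fc)
  expect_setequal(fv$variant,
                  c("c.153delT", "c.1431-12G>A", "c.1111C>T",
                    "c.1887+1G>A", "c.995delT"))

  alive <- fc
  alive$died_in_infancy <- "absent"
  expect_equal(nrow(identify_fatal_variants(alive)), 0L)

  # a death in a compound-heterozygous carrier never flags the variant
  het_death <- fc
  het_death$died_in_infancy <- ifelse(
    het_death$zygosity == "compound-heterozygous", "present", "absent")
  expect_equal(nrow(identify_fatal_variants(het_death)), 0L)
})

test_that("fatal contingency builds the zygosity x mortality table", {
  fc <- fatal_example_cohort()
  ct <- fatal_contingency(fc)
  expect_equal(unname(ct$table),
               matrix(c(14, 0, 4, 12), 2))
  expect_equal(rowSums(ct$table), c(homozygous = 18, heterozygous = 12))
  # no heterozygous carriers -> zero margin
  hom_only <- fc[fc$zygosity == "homozygous", ]
  expect_error(fatal_contingency(hom_only), "zero margin")
})

test_that("the association grid reports degenerate cells without aborting", {
  co <- code_cohort(fatal_example_cohort())
  grid <- associate_all(co, variables = c("halfx", "d5x"),
                        phenotypes = c("erythroderma", "asthma"))
  expect_equal(nrow(grid), 4L)
  # erythroderma is uniformly present here -> constant outcome notes
  ery <- grid[grid$phenotype == "erythroderma", ]
  expect_true(all(!is.na(ery$note)))
  expect_true(all(is.na(ery$odds_ratio)))
})
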