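ann1 <- function(s, prot = NULL) annotate_variant(s, protein_consequence = prot)

test_that("allele coding reproduces the worked product examples", {
  a153 <- ann1("c.153delT")
  g <- code_alleles(a153, a153)
  expect_equal(g$half1, 1L); expect_equal(g$halfx, 1L)
  expect_equal(g$dom1, 1L); expect_equal(g$domnum_x, 1L)
  expect_equal(g$d5x, 0L); expect_equal(g$indom_x, 1L)

  a1887 <- ann1("c.1887+1G>A")
  g2 <- code_alleles(a153, a1887)
  expect_equal(g2$halfx, 2L)          # 1 x 2
  expect_equal(g2$domnum_x, 10L)      # 1 x 10
  expect_equal(g2$d5x, 0L)            # 0 x 1
  expect_equal(g2$indom_x, 1L)

  a81 <- ann1("c.81+2T>A")            # non-domain allele
  g3 <- code_alleles(a153, a81)
  expect_equal(g3$in_dom2, 0L)
  expect_equal(g3$indom_x, 0L)
  expect_true(is.na(g3$domnum_x))
})

test_that("coding is symmetric in allele order", {
  sim <- simulate_cohort(simulation_config(n_patients = 150, seed = 21))
  for (i in c(1L, 40L, 99L)) {
    a <- tibble::tibble(half = sim$a1_half[i], domain = sim$a1_domain[i],
                        region = sim$a1_region[i],
                        in_domain = sim$a1_in_domain[i])
    b <- tibble::tibble(half = sim$a2_half[i], domain = sim$a2_domain[i],
                        region = sim$a2_region[i],
                        in_domain = sim$a2_in_domain[i])
    ab <- code_alleles(a, b)
    ba <- code_alleles(b, a)
    for (v in c("halfx", "domnum_x", "d5x", "indom_x")) {
      expect_equal(ab[[v]], ba[[v]])
    }
  }
})

test_that("coded covariates stay inside their defined ranges", {
  sim <- code_cohort(simulate_cohort(simulation_config(n_patients = 400,
                                                       seed = 22)))
  expect_true(all(sim$halfx %in% c(1L, 2L, 4L)))
  expect_true(all(sim$d5x %in% 0:1))
  expect_true(all(sim$indom_x %in% 0:1))
  dn <- sim$domnum_x[!is.na(sim$domnum_x)]
  expect_true(all(dn >= 1L & dn <= 225L))
  expect_equal(is.na(sim$domnum_x), is.na(sim$dom1) | is.na(sim$dom2))
})

test_that("homozygous products equal squared single-allele values", {
  sim <- code_cohort(simulate_cohort(simulation_config(n_patients = 400,
                                                       seed = 23)))
  hom <- sim[sim$zygosity == "homozygous", ]
  expect_gt(nrow(hom), 0)
  expect_equal(as.numeric(hom$halfx), as.numeric(hom$half1)^2)
  expect_equal(as.numeric(hom$domnum_x), as.numeric(hom$dom1)^2)
  expect_equal(as.numeric(hom$d5x), as.numeric(hom$in_d5_1)^2)
  expect_equal(as.numeric(hom$indom_x), as.numeric(hom$in_dom1)^2)
})

test_that("model tables are complete-case with counted drops", {
  df <- make_cohort_df(5)
  df$failure_to_thrive <- c("+", "-", "NA", "NA", "+")
  co <- code_cohort(as_cohort(df))
  d <- build_dataset(co, "halfx", "failure_to_thrive")
  expect_equal(nrow(d), 3L)
  expect_equal(attr(d, "dropped")[["phenotype_unknown"]], 2L)
  expect_equal(d$outcome, c(1L, 0L, 1L))

  # non-domain allele drops the row for the domain-number product
  df2 <- make_cohort_df(3)
  df2$allele2_cdna[1] <- "c.81+2T>A"
  co2 <- code_cohort(as_cohort(df2))
  d2 <- build_dataset(co2, "domnum_x", "ilc")
  expect_equal(nrow(d2), 2L)
  expect_equal(attr(d2, "dropped")[["covariate_missing"]], 1L)

  # missing age drops the row
  df3 <- make_cohort_df(3)
  df3$age_years[2] <- NA
  co3 <- code_cohort(as_cohort(df3))
  d3 <- build_dataset(co3, "halfx", "ilc")
  expect_equal(attr(d3, "dropped")[["age_missing"]], 1L)
  expect_equal(nrow(d3), 2L)
})

test_that("homozygous-only mode uses single-allele values", {
  co <- code_cohort(fatal_example_cohort())
  d <- build_dataset(co, "half", "died_in_infancy", homozygous_only = TRUE)
  expect_equal(nrow(d), sum(co$zygosity == "homozygous"))
  hom <- co[co$zygosity == "homozygous", ]
  expect_equal(d$covariate, as.numeric(hom$half1))
  expect_error(build_dataset(co, "half", "ilc"), "homozygous_only")
  expect_error(build_dataset(co, "bogus", "ilc"), "unknown covariate")
})

test_that("an empty model table names the responsible filters", {
  df <- make_cohort_df(2)
  df$ilc <- "NA"
  co <- code_cohort(as_cohort(df))
  expect_error(build_dataset(co, "halfx", "ilc"),
               "phenotype_unknown=2")
})
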