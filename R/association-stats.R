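#' Fit a binary logistic regression for one genotype covariate
#'
#' Maximum-likelihood logit fit of `outcome ~ covariate + age` (all
#' covariates entered simultaneously, no selection), reporting the
#' genotype covariate's coefficient with a Wald z-test and the odds ratio
#' with a 95% Wald confidence interval (`exp(beta +/- 1.96 se)`). If age
#' is constant in the model table it carries no information and is
#' dropped from the fit. Non-convergence and (quasi-)separation — detected
#' as a fitted |beta| above `separation_limit` — are reported through
#' `converged = FALSE`, never silently.
#'
#' @param data Model table from [build_dataset()] (columns `outcome`,
#'   `covariate`, `age`).
#' @param phenotype,variable Optional labels copied into the result.
#' @param include_age Include age as a covariate (default `TRUE`).
#' @param separation_limit |beta| beyond which the fit is flagged as
#'   separated.
#' @return A one-row tibble: `phenotype`, `variable`, `n_used`, `beta`,
#'   `se`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `converged`.
#' @export
fit_logistic <- function(data, phenotype = NA_character_,
                         variable = NA_character_, include_age = TRUE,
                         separation_limit = 15) {
  stopifnot(all(c("outcome", "covariate", "age") %in% names(data)))
  y <- data$outcome
  if (length(unique(y)) < 2L) {
    stop("outcome is constant (", sum(y), "/", length(y),
         " cases); at least one case and one control are required",
         call. = FALSE)
  }
  if (length(unique(data$covariate)) < 2L) {
    stop("covariate is constant; no association is estimable",
         call. = FALSE)
  }
  use_age <- include_age && length(unique(data$age)) > 1L
  form <- if (use_age) outcome ~ covariate + age else outcome ~ covariate
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  co <- summary(fit)$coefficients
  beta <- co["covariate", "Estimate"]
  se <- co["covariate", "Std. Error"]
  p <- co["covariate", "Pr(>|z|)"]
  orci <- odds_ratio_ci(beta, se)
  tibble::tibble(
    phenotype = phenotype, variable = variable, n_used = nrow(data),
    beta = beta, se = se, odds_ratio = orci$or, ci_low = orci$low,
    ci_high = orci$high, p_value = p,
    converged = fit$converged && abs(beta) <= separation_limit
  )
}

#' Odds ratio with 95% Wald confidence interval
#'
#' @param beta Log-odds coefficient.
#' @param se Standard error (`>= 0`).
#' @param z Critical value; 1.96 for a 95% interval.
#' @return A list with `or`, `low`, `high`.
#' @export
odds_ratio_ci <- function(beta, se, z = 1.96) {
  stopifnot(all(se >= 0))
  list(or = exp(beta), low = exp(beta - z * se), high = exp(beta + z * se))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param yates Apply the Yates continuity correction.
#' @return A `contingency_result` list: `table`, `chi2`, `df`, `p_value`,
#'   `yates`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(14, 0, 4, 12), 2))
chi_square_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in contingency table; the chi-square test is ",
         "undefined — consider an exact test", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  structure(
    list(table = table, chi2 = unname(ct$statistic),
         df = unname(ct$parameter), p_value = unname(ct$p.value),
         yates = yates),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square = %.4g, df = %d, p = %.3g%s\n", x$chi2, x$df,
              x$p_value,
              if (x$yates) " (Yates-corrected)" else " (uncorrected)"))
  invisible(x)
}

#' Identify fatal variants in a cohort
#'
#' A fatal variant is defined operationally as a variant with at least one
#' homozygous carrier who died during infancy. Deaths in compound
#' heterozygous carriers never flag a variant. Carrier and death tallies
#' are reported per variant for both zygosity classes.
#'
#' @param cohort An annotated `ns_cohort` tibble with `died_in_infancy`
#'   statuses.
#' @return A tibble (possibly empty) with columns `variant`,
#'   `hom_carriers`, `hom_deaths`, `het_carriers`, `het_deaths`.
#' @export
identify_fatal_variants <- function(cohort) {
  variants <- sort(unique(c(cohort$allele1_cdna, cohort$allele2_cdna)))
  died <- cohort$died_in_infancy == "present"
  tally <- purrr::map_dfr(variants, function(v) {
    hom <- cohort$zygosity == "homozygous" & cohort$allele1_cdna == v
    het <- cohort$zygosity != "homozygous" &
      (cohort$allele1_cdna == v | cohort$allele2_cdna == v)
    tibble::tibble(
      variant = v,
      hom_carriers = sum(hom), hom_deaths = sum(hom & died),
      het_carriers = sum(het), het_deaths = sum(het & died)
    )
  })
  tally[tally$hom_deaths >= 1L, ]
}

#' Contingency analysis of fatal-variant zygosity vs infant death
#'
#' Builds the 2x2 table of fatal-variant carriers (rows: homozygous,
#' heterozygous; columns: died in infancy, survived) and runs
#' [chi_square_2x2()]. A heterozygous carrier is any non-homozygous
#' patient with a fatal variant on at least one allele. Patients whose
#' infant-death status is unknown are dropped.
#'
#' @param cohort An annotated `ns_cohort` tibble.
#' @param fatal Fatal-variant table from [identify_fatal_variants()], or a
#'   character vector of variant strings.
#' @param yates Continuity correction flag.
#' @return A `contingency_result` with the labelled 2x2 table.
#' @export
fatal_contingency <- function(cohort, fatal = identify_fatal_variants(cohort),
                              yates = FALSE) {
  fatal_set <- if (is.character(fatal)) fatal else fatal$variant
  if (length(fatal_set) == 0L) stop("empty fatal-variant set", call. = FALSE)
  carrier <- cohort$allele1_cdna %in% fatal_set |
    cohort$allele2_cdna %in% fatal_set
  hom <- carrier & cohort$zygosity == "homozygous" &
    cohort$allele1_cdna %in% fatal_set
  known <- cohort$died_in_infancy != "unknown"
  died <- cohort$died_in_infancy == "present"
  tab <- matrix(
    c(sum(carrier & hom & known & died),
      sum(carrier & !hom & known & died),
      sum(carrier & hom & known & !died),
      sum(carrier & !hom & known & !died)),
    nrow = 2,
    dimnames = list(zygosity = c("homozygous", "heterozygous"),
                    infancy = c("died", "survived"))
  )
  chi_square_2x2(tab, yates = yates)
}

#' Fit the full grid of phenotype x covariate associations
#'
#' Runs [build_dataset()] and [fit_logistic()] for every combination of
#' the requested phenotypes and covariates. Cells whose model table is
#' empty or degenerate (constant outcome or covariate) are reported with
#' `NA` estimates and the failure message rather than aborting the grid.
#'
#' @param cohort A coded cohort ([code_cohort()]).
#' @param variables Covariate names (see [build_dataset()]).
#' @param phenotypes Phenotype names; defaults to all nine.
#' @param homozygous_only Restrict to homozygous genotypes.
#' @param include_age Pass-through to [fit_logistic()].
#' @return A tibble with one row per phenotype x variable, the
#'   [fit_logistic()] columns, and a `note` column for degenerate cells.
#' @export
associate_all <- function(cohort,
                          variables = c("halfx", "domnum_x", "d5x", "indom_x"),
                          phenotypes = phenotype_names(),
                          homozygous_only = FALSE, include_age = TRUE) {
  grid <- tidyr::expand_grid(phenotype = phenotypes, variable = variables)
  purrr::pmap_dfr(grid, function(phenotype, variable) {
    res <- tryCatch({
      d <- build_dataset(cohort, variable, phenotype,
                         homozygous_only = homozygous_only)
      r <- fit_logistic(d, phenotype, variable, include_age = include_age)
      r$note <- NA_character_
      r
    }, error = function(e) {
      tibble::tibble(
        phenotype = phenotype, variable = variable, n_used = NA_integer_,
        beta = NA_real_, se = NA_real_, odds_ratio = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
        converged = NA, note = conditionMessage(e)
      )
    })
    res
  })
}
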