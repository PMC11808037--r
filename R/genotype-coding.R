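#' Numeric genotype codes for a pair of annotated alleles
#'
#' Implements the allele-value coding used as regression covariates:
#' \describe{
#'   \item{half}{5' half = 1, 3' half = 2; `halfx` is the product of the
#'     two allele values (1, 2 or 4).}
#'   \item{domnum}{the domain number (1..15) of an in-domain allele;
#'     `domnum_x` is the product of the two domain numbers and is missing
#'     whenever either allele lies outside every domain (no domain number
#'     is defined for non-domain variants, so their product is
#'     undefined).}
#'   \item{in_d5}{indicator for domain region 5 (domains 10-15) = 1,
#'     anything else = 0; `d5x` is the product.}
#'   \item{in_dom}{indicator for lying inside any domain region = 1,
#'     non-domain = 0; `indom_x` is the product.}
#' }
#' Products are commutative, so the coding is symmetric in allele order;
#' for homozygous genotypes each product equals the square of the
#' single-allele value.
#'
#' @param a1,a2 One-row annotation data (each with `half`, `domain`,
#'   `region`, `in_domain`), e.g. rows of [annotate_variant()] output.
#' @return A one-row tibble of class fields `half1`, `half2`, `halfx`,
#'   `dom1`, `dom2`, `domnum_x`, `in_d5_1`, `in_d5_2`, `d5x`, `in_dom1`,
#'   `in_dom2`, `indom_x`.
#' @export
#' @examples
#' a <- annotate_variant(c("c.153delT", "c.1887+1G>A"))
#' code_alleles(a[1, ], a[2, ])
code_alleles <- function(a1, a2) {
  .code_vec(a1$half, a1$domain, a1$region, a1$in_domain,
            a2$half, a2$domain, a2$region, a2$in_domain)
}

.code_vec <- function(h1, d1, r1, in1, h2, d2, r2, in2) {
  in_d5_1 <- as.integer(!is.na(r1) & r1 == 5L)
  in_d5_2 <- as.integer(!is.na(r2) & r2 == 5L)
  in_dom1 <- as.integer(in1)
  in_dom2 <- as.integer(in2)
  tibble::tibble(
    half1 = h1, half2 = h2, halfx = h1 * h2,
    dom1 = d1, dom2 = d2, domnum_x = d1 * d2,
    in_d5_1 = in_d5_1, in_d5_2 = in_d5_2, d5x = in_d5_1 * in_d5_2,
    in_dom1 = in_dom1, in_dom2 = in_dom2, indom_x = in_dom1 * in_dom2
  )
}

#' Add coded genotype covariates to a cohort
#'
#' @param cohort An annotated `ns_cohort` tibble ([as_cohort()]).
#' @return The cohort with the [code_alleles()] columns appended.
#' @export
code_cohort <- function(cohort) {
  # idempotent: recode from the annotation columns, replacing stale codes
  cohort <- cohort[, setdiff(names(cohort), .coded_cols)]
  codes <- .code_vec(cohort$a1_half, cohort$a1_domain, cohort$a1_region,
                     cohort$a1_in_domain,
                     cohort$a2_half, cohort$a2_domain, cohort$a2_region,
                     cohort$a2_in_domain)
  out <- dplyr::bind_cols(cohort, codes)
  class(out) <- class(cohort)
  out
}

.coded_cols <- c("half1", "half2", "halfx", "dom1", "dom2", "domnum_x",
                 "in_d5_1", "in_d5_2", "d5x", "in_dom1", "in_dom2",
                 "indom_x")

.product_vars <- c("halfx", "domnum_x", "d5x", "indom_x")
.single_vars <- c(half = "half1", domnum = "dom1", in_d5 = "in_d5_1",
                  in_dom = "in_dom1")

#' Build a complete-case model table for one phenotype and covariate
#'
#' Selects outcome (phenotype present = 1 / absent = 0), genotype
#' covariate and age, dropping and counting rows with unknown phenotype,
#' missing covariate or missing age (complete-case analysis). In
#' homozygous-only mode the cohort is restricted to homozygous genotypes
#' and the single-allele covariates (`half`, `domnum`, `in_d5`, `in_dom`)
#' are available, since both alleles are identical.
#'
#' @param cohort A coded cohort ([code_cohort()]).
#' @param variable Covariate name: one of `halfx`, `domnum_x`, `d5x`,
#'   `indom_x`, or (homozygous-only) `half`, `domnum`, `in_d5`, `in_dom`.
#' @param phenotype One of [phenotype_names()] or `"died_in_infancy"`.
#' @param homozygous_only Restrict to homozygous patients and use
#'   single-allele values.
#' @return A tibble with columns `patient_id`, `outcome` (0/1),
#'   `covariate`, `age`; attribute `dropped` holds a named count of rows
#'   removed per reason.
#' @export
build_dataset <- function(cohort, variable, phenotype,
                          homozygous_only = FALSE) {
  stopifnot(phenotype %in% c(phenotype_names(), "died_in_infancy"))
  if (!all(.product_vars %in% names(cohort))) {
    cohort <- code_cohort(cohort)
  }

  if (variable %in% names(.single_vars)) {
    if (!homozygous_only) {
      stop("single-allele variable '", variable,
           "' requires homozygous_only = TRUE", call. = FALSE)
    }
    covariate <- cohort[[.single_vars[[variable]]]]
  } else if (variable %in% .product_vars) {
    covariate <- cohort[[variable]]
  } else {
    stop("unknown covariate '", variable, "'", call. = FALSE)
  }

  keep_zyg <- if (homozygous_only) cohort$zygosity == "homozygous" else
    rep(TRUE, nrow(cohort))
  phen <- cohort[[phenotype]]
  dropped <- c(
    not_homozygous = sum(!keep_zyg),
    phenotype_unknown = sum(keep_zyg & phen == "unknown"),
    covariate_missing = sum(keep_zyg & phen != "unknown" & is.na(covariate)),
    age_missing = sum(keep_zyg & phen != "unknown" & !is.na(covariate) &
                        is.na(cohort$age_years))
  )
  keep <- keep_zyg & phen != "unknown" & !is.na(covariate) &
    !is.na(cohort$age_years)

  if (!any(keep)) {
    stop("no complete cases left for phenotype '", phenotype,
         "' and covariate '", variable, "' (dropped: ",
         paste(names(dropped), dropped, sep = "=", collapse = ", "), ")",
         call. = FALSE)
  }
  out <- tibble::tibble(
    patient_id = cohort$patient_id[keep],
    outcome = as.integer(phen[keep] == "present"),
    covariate = as.numeric(covariate[keep]),
    age = cohort$age_years[keep]
  )
  attr(out, "dropped") <- dropped
  out
}
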