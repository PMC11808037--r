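#' Names of the nine recorded clinical phenotypes
#'
#' The phenotypes commonly recorded in Netherton syndrome case reports and
#' analysed by this package, in canonical column order.
#'
#' @return Character vector of nine snake_case phenotype column names.
#' @export
phenotype_names <- function() {
  c("ilc", "erythroderma", "hair_shaft_anomalies", "failure_to_thrive",
    "recurrent_systemic_infection", "hypernatremia", "angioedema",
    "urticaria", "asthma")
}

.tristate_levels <- c("present", "absent", "unknown")
.tristate_tokens <- c("+" = "present", "-" = "absent", "NA" = "unknown")

.required_cols <- function() {
  c("patient_id", "source", "age_years", "allele1_cdna", "allele2_cdna",
    "died_in_infancy", phenotype_names())
}

.optional_cols <- c("allele1_protein", "allele2_protein",
                    "large_event_flag", "exclude_reason")

.decode_tristate <- function(x, col, ids) {
  x <- trimws(as.character(x))
  decoded <- x %in% .tristate_levels
  bad <- !decoded & !(x %in% names(.tristate_tokens))
  if (any(bad)) {
    stop("invalid phenotype token '", x[bad][1L], "' for patient '",
         ids[bad][1L], "' in column '", col,
         "'; allowed tokens are {+, -, NA}", call. = FALSE)
  }
  ifelse(decoded, x, unname(.tristate_tokens[x]))
}

.encode_tristate <- function(x) {
  names(.tristate_tokens)[match(x, .tristate_tokens)]
}

#' Validate and annotate a cohort data frame
#'
#' Checks a raw cohort table against the schema (see [read_cohort()] for
#' the column dialect), decodes tri-state phenotype tokens, derives
#' zygosity from allele equality, and annotates both alleles with half,
#' codon, domain, region and mutation type. Every patient must carry two
#' alleles: single-variant records are rejected, matching the inclusion
#' rule that only confirmed biallelic (homozygous or compound
#' heterozygous) genotypes enter the analysis.
#'
#' @param df A data frame in the cohort dialect.
#' @param transcript A [transcript_model()].
#' @param domains,regions Domain tables (see [lekti_domains()]).
#' @return A `ns_cohort` tibble: the input columns plus `zygosity` and
#'   per-allele annotation columns `a1_half`, `a1_codon`, `a1_domain`,
#'   `a1_region`, `a1_in_domain`, `a1_type` (and `a2_*`).
#' @export
as_cohort <- function(df, transcript = spink5_transcript(),
                      domains = lekti_domains(), regions = lekti_regions()) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(.required_cols(), names(df))
  if (length(missing_cols)) {
    stop("cohort table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in .optional_cols) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col == "large_event_flag") FALSE else NA_character_
    }
  }

  df$patient_id <- as.character(df$patient_id)
  if (any(is.na(df$patient_id) | df$patient_id == "")) {
    stop("empty patient_id", call. = FALSE)
  }
  df$age_years <- suppressWarnings(as.numeric(df$age_years))
  if (any(!is.na(df$age_years) & df$age_years < 0)) {
    stop("negative age_years for patient '",
         df$patient_id[which(!is.na(df$age_years) & df$age_years < 0)[1L]],
         "'", call. = FALSE)
  }
  df$large_event_flag <- .as_flag(df$large_event_flag)
  df$exclude_reason <- dplyr::na_if(
    trimws(as.character(df$exclude_reason)), "")

  for (a in c("allele1_cdna", "allele2_cdna")) {
    v <- trimws(as.character(df[[a]]))
    empty <- is.na(v) | v == "" | v == "NA"
    if (any(empty)) {
      stop("patient '", df$patient_id[empty][1L], "' has no ", a,
           "; biallelic genotypes are required", call. = FALSE)
    }
    df[[a]] <- v
  }

  for (col in c("died_in_infancy", phenotype_names())) {
    df[[col]] <- .decode_tristate(df[[col]], col, df$patient_id)
  }

  prot <- function(x) {
    x <- trimws(as.character(x))
    x[is.na(x) | x == "" | x == "NA"] <- NA_character_
    x
  }
  df$allele1_protein <- prot(df$allele1_protein)
  df$allele2_protein <- prot(df$allele2_protein)

  ann <- function(cdna, protein) {
    a <- annotate_variant(cdna, transcript, domains, regions,
                          protein_consequence = protein)
    tibble::tibble(cdna = a$hgvs, half = a$half, codon = a$codon,
                   domain = a$domain, region = a$region,
                   in_domain = a$in_domain, type = a$mutation_type)
  }
  a1 <- ann(df$allele1_cdna, df$allele1_protein)
  a2 <- ann(df$allele2_cdna, df$allele2_protein)
  df$allele1_cdna <- a1$cdna
  df$allele2_cdna <- a2$cdna
  names(a1) <- paste0("a1_", names(a1))
  names(a2) <- paste0("a2_", names(a2))

  out <- dplyr::bind_cols(
    df,
    a1[setdiff(names(a1), "a1_cdna")],
    a2[setdiff(names(a2), "a2_cdna")]
  )
  out$zygosity <- ifelse(out$allele1_cdna == out$allele2_cdna,
                         "homozygous", "compound-heterozygous")
  class(out) <- c("ns_cohort", class(out))
  out
}

.as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "1", "yes", "y", "+")
}

#' Read a cohort table from delimited text
#'
#' The cohort dialect is UTF-8 TSV (or CSV) with header columns
#' `patient_id`, `source`, `age_years`, `allele1_cdna`, `allele2_cdna`,
#' optional `allele1_protein`/`allele2_protein`, optional
#' `large_event_flag` and `exclude_reason`, `died_in_infancy`, and one
#' column per phenotype in [phenotype_names()]. Phenotype and
#' `died_in_infancy` cells use the tokens `+` (present), `-` (absent) and
#' `NA` (no clear clinical record) — `NA` is a token, not a missing cell,
#' so absence of a record is distinct from absence of the phenotype.
#'
#' @param path Path to the delimited file.
#' @param transcript,domains,regions See [as_cohort()].
#' @param delim Field delimiter; `"\t"` by default.
#' @return An annotated `ns_cohort` tibble (see [as_cohort()]).
#' @export
read_cohort <- function(path, transcript = spink5_transcript(),
                        domains = lekti_domains(),
                        regions = lekti_regions(), delim = "\t") {
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
  as_cohort(raw, transcript, domains, regions)
}

#' Write a cohort table in the dialect [read_cohort()] accepts
#'
#' Annotation columns are dropped; tri-state fields are re-encoded to the
#' `+`/`-`/`NA` tokens. Reading the written file back reproduces the
#' cohort.
#'
#' @param cohort An `ns_cohort` tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = "\t") {
  keep <- c("patient_id", "source", "age_years", "allele1_cdna",
            "allele2_cdna", "allele1_protein", "allele2_protein",
            "large_event_flag", "exclude_reason", "died_in_infancy",
            phenotype_names())
  out <- tibble::as_tibble(cohort)[, keep]
  for (col in c("died_in_infancy", phenotype_names())) {
    out[[col]] <- .encode_tristate(out[[col]])
  }
  out$large_event_flag <- ifelse(out$large_event_flag, "TRUE", "FALSE")
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Apply cohort exclusion filters
#'
#' Executable curation filters: duplicate records of the same patient
#' (same `patient_id`; the first occurrence is kept), records flagged as
#' large deletions/duplications (`large_event_flag`, which cannot be
#' assigned to a single domain), and records carrying a curator-supplied
#' `exclude_reason` (covering judgment-based criteria such as inconsistent
#' mutation assessment, which the package does not recompute). The filter
#' is idempotent.
#'
#' @param cohort An `ns_cohort` tibble.
#' @return A list with elements `kept` (the filtered cohort) and `report`
#'   (a tibble of per-criterion removal counts and patient ids).
#' @export
apply_exclusions <- function(cohort) {
  crit <- list(
    curator_excluded = !is.na(cohort$exclude_reason),
    duplicate_patient = duplicated(cohort$patient_id),
    large_event = cohort$large_event_flag
  )
  drop <- rep(FALSE, nrow(cohort))
  rows <- list()
  for (name in names(crit)) {
    hit <- crit[[name]] & !drop
    rows[[name]] <- tibble::tibble(
      criterion = name, n_removed = sum(hit),
      patient_ids = paste(cohort$patient_id[hit], collapse = ",")
    )
    drop <- drop | hit
  }
  list(kept = cohort[!drop, ], report = dplyr::bind_rows(rows))
}

#' Summarize a cohort: phenotype counts and allele distribution
#'
#' Tri-state counts and percentages per phenotype (percent of cohort size,
#' two decimals), plus allele tallies by mutation type, by domain region
#' and by positional bin ([domain_bin()]). Each patient contributes
#' exactly two alleles to the allele tallies.
#'
#' @param cohort A non-empty `ns_cohort` tibble.
#' @return A list of class `cohort_summary` with elements `n_patients`,
#'   `n_alleles`, `n_distinct_variants`, `phenotypes`, `allele_types`,
#'   `allele_regions`, `allele_bins`.
#' @export
phenotype_summary <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  n <- nrow(cohort)
  pct <- function(k) round(100 * k / n, 2)

  phen <- purrr::map_dfr(c(phenotype_names(), "died_in_infancy"), function(p) {
    x <- cohort[[p]]
    tibble::tibble(
      phenotype = p,
      n_present = sum(x == "present"), n_absent = sum(x == "absent"),
      n_unknown = sum(x == "unknown"),
      pct_present = pct(sum(x == "present")),
      pct_absent = pct(sum(x == "absent")),
      pct_unknown = pct(sum(x == "unknown")),
      n_recorded = sum(x != "unknown")
    )
  })

  alleles <- tibble::tibble(
    cdna = c(cohort$allele1_cdna, cohort$allele2_cdna),
    type = c(cohort$a1_type, cohort$a2_type),
    region = c(cohort$a1_region, cohort$a2_region),
    codon = c(cohort$a1_codon, cohort$a2_codon)
  )
  apct <- function(k) round(100 * k / nrow(alleles), 2)

  types <- alleles |>
    dplyr::count(.data$type, name = "n_alleles") |>
    dplyr::arrange(dplyr::desc(.data$n_alleles)) |>
    dplyr::mutate(pct = apct(.data$n_alleles))
  regions <- alleles |>
    dplyr::mutate(region = ifelse(is.na(.data$region), "non-domain",
                                  paste0("DomainR-", .data$region))) |>
    dplyr::count(.data$region, name = "n_alleles") |>
    dplyr::mutate(pct = apct(.data$n_alleles))
  bins <- alleles |>
    dplyr::mutate(bin = domain_bin(.data$codon)) |>
    dplyr::count(.data$bin, name = "n_alleles") |>
    dplyr::mutate(pct = apct(.data$n_alleles))

  structure(
    list(n_patients = n, n_alleles = nrow(alleles),
         n_distinct_variants = dplyr::n_distinct(alleles$cdna),
         phenotypes = phen, allele_types = types, allele_regions = regions,
         allele_bins = bins),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$n_patients, " patients, ", x$n_alleles,
      " alleles (", x$n_distinct_variants, " distinct variants)\n\n",
      sep = "")
  cat("Phenotypes (n present/absent/unknown):\n")
  print(x$phenotypes, n = Inf)
  cat("\nAlleles by mutation type:\n")
  print(x$allele_types, n = Inf)
  cat("\nAlleles by domain region:\n")
  print(x$allele_regions, n = Inf)
  invisible(x)
}
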