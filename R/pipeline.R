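#' Run the full genotype-phenotype analysis pipeline
#'
#' Executes the whole analysis on a cohort file or table: read and
#' validate -> apply exclusion filters -> annotate alleles -> code
#' genotypes -> fit the phenotype x covariate association grid (biallelic
#' product covariates, and single-allele covariates on the homozygous
#' subset) -> fatal-variant identification and the zygosity x infant-death
#' contingency analysis. Every reported number is computed by the
#' corresponding exported function, and rerunning on the same input
#' reproduces the report exactly.
#'
#' @param x Path to a cohort file ([read_cohort()]) or a cohort data
#'   frame.
#' @param variables Biallelic product covariates for the association
#'   grid.
#' @param homozygous_variables Single-allele covariates for the
#'   homozygous-only grid.
#' @param phenotypes Phenotypes to analyse.
#' @param yates Continuity-correction flag for the fatal-variant
#'   chi-square.
#' @param transcript,domains,regions Reference tables (see
#'   [as_cohort()]).
#' @return A list of class `pipeline_report`: `cohort_summary`,
#'   `exclusions`, `associations`, `associations_homozygous`,
#'   `fatal_variants`, `fatal_contingency` (or `NULL` when no fatal
#'   variant exists or a margin is empty, with the reason in
#'   `fatal_note`), and `provenance`.
#' @export
run_pipeline <- function(x,
                         variables = c("halfx", "domnum_x", "d5x", "indom_x"),
                         homozygous_variables = c("half", "domnum",
                                                  "in_d5", "in_dom"),
                         phenotypes = phenotype_names(),
                         yates = FALSE,
                         transcript = spink5_transcript(),
                         domains = lekti_domains(),
                         regions = lekti_regions()) {
  cohort <- if (is.character(x)) {
    read_cohort(x, transcript, domains, regions)
  } else if (inherits(x, "ns_cohort")) {
    x
  } else {
    as_cohort(x, transcript, domains, regions)
  }
  if (nrow(cohort) == 0L) stop("stage read_cohort: empty cohort",
                               call. = FALSE)

  filtered <- apply_exclusions(cohort)
  kept <- code_cohort(filtered$kept)
  if (nrow(kept) == 0L) {
    stop("stage apply_exclusions: no records left after exclusions",
         call. = FALSE)
  }

  summary <- phenotype_summary(kept)
  assoc <- associate_all(kept, variables, phenotypes,
                         homozygous_only = FALSE)
  assoc_hom <- associate_all(kept, homozygous_variables, phenotypes,
                             homozygous_only = TRUE)

  fatal <- identify_fatal_variants(kept)
  fatal_note <- NA_character_
  fatal_ct <- NULL
  if (nrow(fatal) == 0L) {
    fatal_note <- "no fatal variants (no homozygous infant death)"
  } else {
    fatal_ct <- tryCatch(fatal_contingency(kept, fatal, yates = yates),
                         error = function(e) {
                           fatal_note <<- conditionMessage(e)
                           NULL
                         })
  }

  structure(
    list(
      cohort_summary = summary,
      exclusions = filtered$report,
      associations = assoc,
      associations_homozygous = assoc_hom,
      fatal_variants = fatal,
      fatal_contingency = fatal_ct,
      fatal_note = fatal_note,
      cohort = kept,
      provenance = list(
        package_version = as.character(utils::packageVersion("lektimap")),
        transcript = transcript$accession,
        half_boundary = transcript$half_boundary,
        n_input = nrow(cohort), n_analysed = nrow(kept),
        variables = variables,
        homozygous_variables = homozygous_variables,
        yates = yates,
        anchoring = "5'-most coding base; intronic offsets ignored",
        input = if (is.character(x)) unname(tools::md5sum(x)) else
          "in-memory table"
      )
    ),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", x$provenance$n_analysed, " patients analysed (",
      x$provenance$n_input - x$provenance$n_analysed, " excluded)\n\n",
      sep = "")
  sig <- dplyr::filter(x$associations, !is.na(.data$p_value),
                       .data$p_value < 0.05)
  cat("Associations with p < 0.05 (biallelic covariates):\n")
  print(sig, n = Inf)
  cat("\nFatal variants:\n")
  print(x$fatal_variants, n = Inf)
  if (!is.null(x$fatal_contingency)) {
    cat("\nFatal-variant zygosity vs infant death:\n")
    print(x$fatal_contingency)
  } else if (!is.na(x$fatal_note)) {
    cat("\nFatal-variant analysis: ", x$fatal_note, "\n", sep = "")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits TSV tables (`phenotype_summary.tsv`, `allele_types.tsv`,
#' `allele_regions.tsv`, `allele_bins.tsv`, `exclusions.tsv`,
#' `associations.tsv`, `associations_homozygous.tsv`,
#' `fatal_variants.tsv`, `fatal_contingency.tsv`) and/or a single
#' `report.json`. Outputs contain no timestamps, so rerunning on the same
#' input produces byte-identical files.
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if absent).
#' @param formats Subset of `c("tsv", "json")`.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir, formats = c("tsv", "json")) {
  stopifnot(inherits(report, "pipeline_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  if ("tsv" %in% formats) {
    tsv <- function(df, name) {
      path <- file.path(out_dir, name)
      readr::write_tsv(df, path, na = "NA")
      written <<- c(written, path)
    }
    tsv(report$cohort_summary$phenotypes, "phenotype_summary.tsv")
    tsv(report$cohort_summary$allele_types, "allele_types.tsv")
    tsv(report$cohort_summary$allele_regions, "allele_regions.tsv")
    tsv(report$cohort_summary$allele_bins, "allele_bins.tsv")
    tsv(report$exclusions, "exclusions.tsv")
    tsv(report$associations, "associations.tsv")
    tsv(report$associations_homozygous, "associations_homozygous.tsv")
    tsv(report$fatal_variants, "fatal_variants.tsv")
    if (!is.null(report$fatal_contingency)) {
      ct <- report$fatal_contingency
      tsv(tibble::tibble(
        zygosity = rownames(ct$table),
        died = ct$table[, "died"], survived = ct$table[, "survived"],
        chi2 = ct$chi2, df = ct$df, p_value = ct$p_value, yates = ct$yates
      ), "fatal_contingency.tsv")
    }
  }

  if ("json" %in% formats) {
    path <- file.path(out_dir, "report.json")
    payload <- list(
      provenance = report$provenance,
      n_patients = report$cohort_summary$n_patients,
      n_alleles = report$cohort_summary$n_alleles,
      phenotypes = report$cohort_summary$phenotypes,
      allele_types = report$cohort_summary$allele_types,
      allele_regions = report$cohort_summary$allele_regions,
      exclusions = report$exclusions,
      associations = report$associations,
      associations_homozygous = report$associations_homozygous,
      fatal_variants = report$fatal_variants,
      fatal_contingency = if (!is.null(report$fatal_contingency)) {
        ct <- report$fatal_contingency
        list(table = ct$table, chi2 = ct$chi2, df = ct$df,
             p_value = ct$p_value, yates = ct$yates)
      }
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, path)
  }
  invisible(written)
}

#' Bar chart of the allele distribution over domain bins
#'
#' A Figure-style bar chart of allele counts per positional bin (domains
#' and inter-domain intervals, in transcript order). Requires ggplot2.
#'
#' @param cohort An annotated `ns_cohort` tibble.
#' @return A ggplot object.
#' @export
plot_allele_distribution <- function(cohort) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  bins <- phenotype_summary(cohort)$allele_bins
  order <- c("pre-D1", unlist(lapply(1:15, function(d) {
    c(paste0("D", d), if (d < 15) paste0("D", d, "-", d + 1))
  })), "post-D15")
  bins$bin <- factor(bins$bin, levels = order)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$n_alleles)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "LEKTI domain bin", y = "alleles") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
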