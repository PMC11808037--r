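#' Worked-example cohort of fatal-variant carriers
#'
#' A compact synthetic 30-patient cohort built in code around the five
#' recurrent fatal SPINK5 variants (c.153delT, c.1431-12G>A, c.1111C>T,
#' c.1887+1G>A, c.995delT): 18 homozygous carriers of whom 14 died during
#' infancy, and 12 compound-heterozygous carriers (a fatal variant paired
#' with a non-fatal second allele), none of whom died. One surviving
#' homozygous carrier is still under one year of age. Ages and phenotype
#' entries other than infant death are illustrative; the genotype,
#' zygosity and mortality structure is the object of interest, giving the
#' 2x2 mortality table `[[14, 4], [0, 12]]`.
#'
#' @param transcript,domains,regions See [as_cohort()].
#' @return An annotated `ns_cohort` tibble of 30 patients.
#' @export
#' @examples
#' fc <- fatal_example_cohort()
#' identify_fatal_variants(fc)
fatal_example_cohort <- function(transcript = spink5_transcript(),
                                 domains = lekti_domains(),
                                 regions = lekti_regions()) {
  hom <- function(v, n_died, n_alive, prot = NA_character_) {
    tibble::tibble(allele1_cdna = v, allele2_cdna = v,
                   allele1_protein = prot, allele2_protein = prot,
                   died = rep(c(TRUE, FALSE), c(n_died, n_alive)))
  }
  het <- function(v, others, prot = NA_character_) {
    tibble::tibble(allele1_cdna = v, allele2_cdna = others,
                   allele1_protein = prot, allele2_protein = NA_character_,
                   died = FALSE)
  }
  g <- dplyr::bind_rows(
    hom("c.153delT", 8, 3),
    het("c.153delT", c("c.81+2T>A", "c.81+2T>A",
                       "c.891C>T", "c.891C>T", "c.891C>T")),
    hom("c.1431-12G>A", 3, 0),
    het("c.1431-12G>A", c("c.1816_1820+21delinsCT", "c.891C>T",
                          "c.2472_2473delAG")),
    hom("c.1111C>T", 1, 0, prot = "p.(Arg371*)"),
    het("c.1111C>T", c("c.2468delA", "c.1032_1036dupGAAAA",
                       "c.81+2T>A", "c.2041_2042delAG"),
        prot = "p.(Arg371*)"),
    hom("c.1887+1G>A", 1, 1),
    hom("c.995delT", 1, 0)
  )
  n <- nrow(g)
  # deaths occurred in infancy; one live homozygote is an infant (0.6 y)
  age <- ifelse(g$died, 0.5, 4 + (seq_len(n) %% 9))
  age[which(!g$died & g$allele1_cdna == g$allele2_cdna)[1L]] <- 0.6

  df <- tibble::tibble(
    patient_id = sprintf("FV%02d", seq_len(n)),
    source = "worked-example",
    age_years = age,
    allele1_cdna = g$allele1_cdna, allele2_cdna = g$allele2_cdna,
    allele1_protein = g$allele1_protein, allele2_protein = g$allele2_protein,
    large_event_flag = FALSE, exclude_reason = NA_character_,
    died_in_infancy = ifelse(g$died, "present", "absent")
  )
  for (p in phenotype_names()) df[[p]] <- "unknown"
  df$erythroderma <- "present"
  df$ilc <- ifelse(seq_len(n) %% 3 == 0, "present", "unknown")
  as_cohort(df, transcript, domains, regions)
}
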