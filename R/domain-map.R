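#' LEKTI domain table
#'
#' The 15 Kazal-type domains of the LEKTI precursor, as inclusive
#' amino-acid ranges on the 1064-residue protein. Positions outside every
#' range (the signal peptide 1-27, inter-domain linkers, and the C-terminal
#' tail beyond residue 1048) are non-domain.
#'
#' @return A tibble with columns `domain` (1..15), `aa_start`, `aa_end`.
#' @export
#' @examples
#' lekti_domains()
lekti_domains <- function() {
  tibble::tibble(
    domain = 1:15,
    aa_start = c(28L, 91L, 155L, 219L, 291L, 361L, 431L, 490L, 561L,
                 626L, 701L, 768L, 843L, 910L, 987L),
    aa_end   = c(66L, 153L, 216L, 285L, 352L, 423L, 489L, 551L, 622L,
                 688L, 757L, 830L, 905L, 971L, 1048L)
  )
}

#' LEKTI domain regions
#'
#' Grouping of the 15 domains into 5 domain regions corresponding to
#' bio-reactive proteolytic fragments of LEKTI: region 1 = domains 1-5,
#' region 2 = domain 6, region 3 = domain 7, region 4 = domains 8-9,
#' region 5 = domains 10-15.
#'
#' @return A tibble with columns `domain` (1..15) and `region` (1..5).
#' @export
lekti_regions <- function() {
  tibble::tibble(
    domain = 1:15,
    region = c(1L, 1L, 1L, 1L, 1L, 2L, 3L, 4L, 4L, 5L, 5L, 5L, 5L, 5L, 5L)
  )
}

#' Validate a user-supplied domain table
#'
#' Domain tables must have integer `domain`, `aa_start`, `aa_end` columns,
#' with `aa_start <= aa_end` and strictly increasing, non-overlapping
#' ranges when sorted by domain index.
#'
#' @param domains A domain table shaped like [lekti_domains()].
#' @param protein_length Protein length the ranges must fit within.
#' @return The validated table, invisibly coerced to a tibble.
#' @export
validate_domain_table <- function(domains, protein_length = 1064L) {
  domains <- tibble::as_tibble(domains)
  stopifnot(all(c("domain", "aa_start", "aa_end") %in% names(domains)))
  domains <- domains[order(domains$domain), ]
  if (any(domains$aa_start > domains$aa_end)) {
    stop("domain with aa_start > aa_end", call. = FALSE)
  }
  if (any(domains$aa_start < 1L) || any(domains$aa_end > protein_length)) {
    stop("domain range outside 1..", protein_length, call. = FALSE)
  }
  n <- nrow(domains)
  if (n > 1L && any(domains$aa_start[-1L] <= domains$aa_end[-n])) {
    stop("domain ranges overlap or are out of order", call. = FALSE)
  }
  domains
}

#' Domain containing an amino-acid position
#'
#' @param aa Integer vector of amino-acid positions in
#'   `1..protein_length + 1` (the stop codon maps to no domain).
#' @param domains Domain table ([lekti_domains()]).
#' @param protein_length Protein length (stop codon index is
#'   `protein_length + 1`).
#' @return Integer vector of domain indices, `NA` for non-domain positions.
#' @export
#' @examples
#' domain_of_aa(c(51, 67, 629))
domain_of_aa <- function(aa, domains = lekti_domains(),
                         protein_length = 1064L) {
  aa <- as.integer(aa)
  if (any(is.na(aa)) || any(aa < 1L | aa > protein_length + 1L)) {
    stop("amino-acid position outside 1..", protein_length + 1L,
         call. = FALSE)
  }
  domains <- validate_domain_table(domains, protein_length)
  # interval lookup: for each aa, the last start <= aa; in-domain iff also
  # <= that domain's end
  idx <- findInterval(aa, domains$aa_start)
  out <- rep(NA_integer_, length(aa))
  hit <- idx >= 1L
  hit[hit] <- aa[hit] <= domains$aa_end[idx[hit]]
  out[hit] <- domains$domain[idx[hit]]
  out
}

#' Domain region owning a domain
#'
#' @param d Integer vector of domain indices; `NA` passes through (a
#'   non-domain variant has no region).
#' @param regions Domain-to-region table ([lekti_regions()]).
#' @return Integer vector of region indices (1..5), `NA` where `d` is `NA`.
#' @export
region_of_domain <- function(d, regions = lekti_regions()) {
  d <- as.integer(d)
  ok <- is.na(d) | d %in% regions$domain
  if (!all(ok)) {
    stop("domain index outside 1..", max(regions$domain), call. = FALSE)
  }
  regions$region[match(d, regions$domain)]
}

#' Inter-domain bin label for a codon
#'
#' Assigns every codon a positional bin: `"D<k>"` inside domain k,
#' `"D<k>-<k+1>"` between consecutive domains, `"pre-D1"` before the first
#' domain (signal peptide) and `"post-D15"` after the last. Used for
#' allele-distribution bar charts; non-domain bins never carry a domain
#' code for covariate purposes.
#'
#' @param codon Integer vector of codon indices.
#' @param domains Domain table.
#' @return Character vector of bin labels.
#' @export
domain_bin <- function(codon, domains = lekti_domains()) {
  domains <- validate_domain_table(domains)
  d <- domain_of_aa(codon, domains)
  out <- ifelse(is.na(d), NA_character_, paste0("D", d))
  gap <- is.na(d)
  if (any(gap)) {
    prev <- findInterval(codon[gap], domains$aa_start)
    out[gap] <- ifelse(
      prev == 0L, "pre-D1",
      ifelse(prev >= nrow(domains), paste0("post-D", nrow(domains)),
             paste0("D", prev, "-", prev + 1L))
    )
  }
  out
}

#' Annotate parsed variants with half, codon, domain and region
#'
#' Composes [assign_half()], [anchor_codon()], [domain_of_aa()],
#' [region_of_domain()] and [classify_type()] into one annotation table.
#'
#' @param v Parsed variant tibble ([parse_hgvs()]) or character vector of
#'   HGVS strings.
#' @param transcript A [transcript_model()].
#' @param domains Domain table ([lekti_domains()]).
#' @param regions Domain-to-region table ([lekti_regions()]).
#' @param protein_consequence Optional HGVS p. strings for substitution
#'   classification (see [classify_type()]).
#' @return The variant tibble with columns `half`, `codon`, `domain`,
#'   `region`, `in_domain`, `mutation_type` appended.
#' @export
#' @examples
#' annotate_variant(c("c.153delT", "c.1431-12G>A", "c.1887+1G>A"))
annotate_variant <- function(v, transcript = spink5_transcript(),
                             domains = lekti_domains(),
                             regions = lekti_regions(),
                             protein_consequence = NULL) {
  if (is.character(v)) v <- parse_hgvs(v, transcript)
  codon <- anchor_codon(v, transcript)
  dom <- domain_of_aa(codon, domains, transcript$protein_length)
  tibble::as_tibble(v) |>
    dplyr::mutate(
      half = assign_half(v, transcript),
      codon = codon,
      domain = dom,
      region = region_of_domain(dom, regions),
      in_domain = !is.na(dom),
      mutation_type = classify_type(v, protein_consequence)
    )
}
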