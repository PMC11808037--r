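#' Reference transcript model
#'
#' A transcript model fixes the coordinate system in which cDNA (c.) variant
#' positions are interpreted: the coding-sequence (CDS) length, the encoded
#' protein length, and the boundary splitting the CDS into a 5' and a 3'
#' half. The CDS length must equal `3 * (protein_length + 1)`, i.e. it
#' includes the stop codon.
#'
#' @param accession Transcript accession string.
#' @param cds_length CDS length in base pairs (including the stop codon).
#' @param protein_length Protein length in amino acids (excluding the stop).
#' @param half_boundary Last CDS base counted in the 5' half (inclusive).
#'
#' @return An object of class `transcript_model`.
#' @seealso [spink5_transcript()] for the shipped SPINK5 default.
#' @export
#' @examples
#' transcript_model("NM_006846.4", 3195L, 1064L, 1598L)
transcript_model <- function(accession, cds_length, protein_length,
                             half_boundary) {
  cds_length <- as.integer(cds_length)
  protein_length <- as.integer(protein_length)
  half_boundary <- as.integer(half_boundary)
  stopifnot(is.character(accession), length(accession) == 1L)
  if (cds_length != 3L * (protein_length + 1L)) {
    stop("cds_length must equal 3 * (protein_length + 1); got ",
         cds_length, " vs 3 * (", protein_length, " + 1)", call. = FALSE)
  }
  if (half_boundary < 1L || half_boundary >= cds_length) {
    stop("half_boundary must lie in [1, cds_length)", call. = FALSE)
  }
  structure(
    list(accession = accession, cds_length = cds_length,
         protein_length = protein_length, half_boundary = half_boundary),
    class = "transcript_model"
  )
}

#' SPINK5 reference transcript NM_006846.4
#'
#' The default transcript model used throughout the package: the SPINK5
#' coding sequence of 3195 bp encoding the 1064-residue LEKTI precursor
#' (plus stop codon), with the 5' half defined as CDS positions 1-1598 and
#' the 3' half as 1599-3195.
#'
#' @return A `transcript_model` for SPINK5.
#' @export
spink5_transcript <- function() {
  transcript_model("NM_006846.4", cds_length = 3195L,
                   protein_length = 1064L, half_boundary = 1598L)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$accession, "\n",
      "  CDS: ", x$cds_length, " bp; protein: ", x$protein_length,
      " aa; 5' half: 1-", x$half_boundary, "\n", sep = "")
  invisible(x)
}

# Recognised edit kinds, in match order (delins before del).
.edit_kinds <- c("deletion/insertion" = "delins", "deletion" = "del",
                 "duplication" = "dup", "insertion" = "ins")

.pos_re <- "^c\\.(\\d+)([+-]\\d+)?(?:_(\\d+)([+-]\\d+)?)?"

#' Parse HGVS cDNA variant strings
#'
#' Decomposes HGVS c.-notation variant descriptions into coding anchor
#' position, intronic offset, optional range end, edit kind and bases.
#' Internal whitespace is stripped before parsing, so strings as printed in
#' the literature (`"c. 995delT"`, `"c. 1887 + 1G>A"`) parse identically to
#' their canonical forms. The supported grammar is the subset used for
#' small SPINK5 variants: `NNN`, `NNN+off`/`NNN-off`, `NNN_MMM` ranges, and
#' substitution (`A>G`), `del`, `dup`, `ins` and `delins` edits.
#'
#' @param s Character vector of HGVS cDNA strings (each starting `c.`).
#' @param transcript A [transcript_model()]; anchors outside `1..cds_length`
#'   are rejected.
#'
#' @return A tibble with one row per input string and columns `raw`,
#'   `hgvs` (normalized form), `anchor`, `intron_offset`, `end_anchor`,
#'   `end_intron_offset`, `edit_kind`, `ref_bases`, `alt_bases`.
#' @export
#' @examples
#' parse_hgvs(c("c.153delT", "c.1431-12G>A", "c. 1887 + 1G>A"))
parse_hgvs <- function(s, transcript = spink5_transcript()) {
  stopifnot(is.character(s))
  raw <- s
  x <- gsub("[[:space:]]+", "", s)
  if (any(!startsWith(x, "c."))) {
    bad <- raw[!startsWith(x, "c.")][1L]
    stop("not an HGVS cDNA (c.) description: '", bad, "'", call. = FALSE)
  }

  m <- regmatches(x, regexec(.pos_re, x))
  take <- function(i) vapply(m, function(g) {
    if (length(g) < i || g[i] == "") NA_character_ else g[i]
  }, character(1))
  matched_len <- vapply(m, function(g) nchar(g[1]), integer(1))
  if (any(lengths(m) == 0L)) {
    stop("cannot parse position in '", raw[lengths(m) == 0L][1L], "'",
         call. = FALSE)
  }

  anchor <- as.integer(take(2))
  intron_offset <- suppressWarnings(as.integer(take(3)))
  end_anchor <- suppressWarnings(as.integer(take(4)))
  end_intron_offset <- suppressWarnings(as.integer(take(5)))
  edit <- substring(x, matched_len + 1L)

  kind <- rep(NA_character_, length(x))
  ref <- alt <- rep(NA_character_, length(x))

  sub_m <- regmatches(edit, regexec("^([ACGTacgt]+)>([ACGTacgt]+)$", edit))
  is_sub <- lengths(sub_m) == 3L
  kind[is_sub] <- "substitution"
  ref[is_sub] <- toupper(vapply(sub_m[is_sub], `[`, character(1), 2L))
  alt[is_sub] <- toupper(vapply(sub_m[is_sub], `[`, character(1), 3L))

  for (k in names(.edit_kinds)) {
    tok <- .edit_kinds[[k]]
    pat <- paste0("^", tok, "([ACGTacgt]*)$")
    km <- regmatches(edit, regexec(pat, edit))
    hit <- lengths(km) == 2L & is.na(kind)
    kind[hit] <- k
    bases <- toupper(vapply(km[hit], `[`, character(1), 2L))
    bases[bases == ""] <- NA_character_
    if (tok %in% c("ins", "delins")) alt[hit] <- bases else ref[hit] <- bases
  }
  if (any(kind[!is.na(kind)] == "insertion" & is.na(alt[!is.na(kind)]))) {
    # bare "ins" with no bases is not a complete description
    bad <- raw[kind == "insertion" & is.na(alt)][1L]
    stop("insertion without inserted bases: '", bad, "'", call. = FALSE)
  }

  if (anyNA(kind)) {
    stop("cannot parse edit '", edit[is.na(kind)][1L], "' in '",
         raw[is.na(kind)][1L], "'", call. = FALSE)
  }

  bad_anchor <- anchor < 1L | anchor > transcript$cds_length |
    (!is.na(end_anchor) &
       (end_anchor > transcript$cds_length | end_anchor < anchor))
  if (any(bad_anchor)) {
    stop("cDNA position outside CDS 1..", transcript$cds_length,
         " (or inverted range) in '", raw[bad_anchor][1L], "'",
         call. = FALSE)
  }

  tibble::tibble(
    raw = raw, hgvs = x, anchor = anchor, intron_offset = intron_offset,
    end_anchor = end_anchor, end_intron_offset = end_intron_offset,
    edit_kind = kind, ref_bases = ref, alt_bases = alt
  )
}

#' Format parsed variants back to normalized HGVS strings
#'
#' Inverse of [parse_hgvs()] up to whitespace: formatting a parsed variant
#' reproduces the whitespace-normalized input.
#'
#' @param v A tibble as returned by [parse_hgvs()].
#' @return Character vector of normalized HGVS c. strings.
#' @export
format_hgvs <- function(v) {
  off <- function(o) ifelse(is.na(o), "",
                            ifelse(o > 0, paste0("+", o), as.character(o)))
  pos <- paste0(v$anchor, off(v$intron_offset),
                ifelse(is.na(v$end_anchor), "",
                       paste0("_", v$end_anchor, off(v$end_intron_offset))))
  edit <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    edit[i] <- switch(
      v$edit_kind[i],
      substitution = paste0(v$ref_bases[i], ">", v$alt_bases[i]),
      deletion = paste0("del", if (!is.na(v$ref_bases[i])) v$ref_bases[i]),
      duplication = paste0("dup", if (!is.na(v$ref_bases[i])) v$ref_bases[i]),
      insertion = paste0("ins", v$alt_bases[i]),
      `deletion/insertion` = paste0("delins", v$alt_bases[i])
    )
  }
  paste0("c.", pos, edit)
}

#' Codon index of the 5'-most affected coding base
#'
#' Multi-base edits are anchored at their 5'-most coding base; intronic
#' offsets are ignored (the variant is attributed to the exonic base named
#' in the HGVS string).
#'
#' @param v Parsed variant tibble ([parse_hgvs()]).
#' @param transcript A [transcript_model()].
#' @return Integer vector of codon indices in `1..protein_length + 1` (the
#'   last value being the stop codon).
#' @export
anchor_codon <- function(v, transcript = spink5_transcript()) {
  as.integer(ceiling(v$anchor / 3))
}

#' Transcript half of a variant
#'
#' Codes each variant 1 if its coding anchor lies in the 5' half of the CDS
#' (positions `1..half_boundary`, inclusive) and 2 otherwise.
#'
#' @inheritParams anchor_codon
#' @return Integer vector of 1s and 2s.
#' @export
assign_half <- function(v, transcript = spink5_transcript()) {
  ifelse(v$anchor <= transcript$half_boundary, 1L, 2L)
}

#' Mutation-type classes
#' @return Character vector of the seven recognised mutation types.
#' @export
mutation_types <- function() {
  c("nonsense", "missense", "splicing", "deletion", "duplication",
    "insertion", "deletion/insertion")
}

.stop_gain_re <- "(\\*|Ter|X)\\)?$"
.missense_re <- "^p\\.\\(?[A-Z][a-z]{2}\\d+[A-Z][a-z]{2}\\)?$"

#' Classify variants by mutation type
#'
#' Any variant with a nonzero intronic offset (on either end of a range) is
#' a splicing variant. Coding deletions, duplications, insertions and
#' deletion/insertions map to their own classes. Coding substitutions are
#' classified from the supplied predicted protein consequence: a stop gain
#' is nonsense, a single-residue substitution is missense. A substitution
#' without a protein consequence is returned as `"unclassified"` rather
#' than guessed; the package never translates the CDS itself.
#'
#' @param v Parsed variant tibble ([parse_hgvs()]).
#' @param protein_consequence Optional character vector of HGVS p. strings
#'   (e.g. `"p.(Arg371*)"`), recycled `NA`s allowed. Supplying a protein
#'   consequence for an intronic variant is an error.
#' @return Character vector over [mutation_types()] plus `"unclassified"`.
#' @export
classify_type <- function(v, protein_consequence = NULL) {
  n <- nrow(v)
  p <- protein_consequence %||% rep(NA_character_, n)
  if (length(p) == 1L) p <- rep(p, n)
  stopifnot(length(p) == n)
  p[!is.na(p) & p == ""] <- NA_character_

  intronic <- (!is.na(v$intron_offset) & v$intron_offset != 0L) |
    (!is.na(v$end_intron_offset) & v$end_intron_offset != 0L)
  if (any(intronic & !is.na(p))) {
    stop("protein consequence supplied for intronic variant '",
         v$raw[intronic & !is.na(p)][1L], "'", call. = FALSE)
  }

  out <- rep(NA_character_, n)
  out[intronic] <- "splicing"
  plain <- !intronic & v$edit_kind != "substitution"
  out[plain] <- v$edit_kind[plain]

  subst <- !intronic & v$edit_kind == "substitution"
  stopgain <- subst & !is.na(p) & grepl(.stop_gain_re, p)
  missense <- subst & !is.na(p) & !stopgain & grepl(.missense_re, p)
  out[stopgain] <- "nonsense"
  out[missense] <- "missense"
  out[subst & is.na(out)] <- "unclassified"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
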