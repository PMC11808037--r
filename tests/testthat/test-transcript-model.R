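test_that("transcript model enforces CDS/protein consistency", {
  t <- spink5_transcript()
  expect_equal(t$cds_length, 3195L)
  expect_equal(t$cds_length, 3L * (t$protein_length + 1L))
  expect_equal(t$half_boundary, 1598L)
  expect_error(transcript_model("X", 3000, 1064, 1598), "cds_length")
  expect_error(transcript_model("X", 3195, 1064, 3195), "half_boundary")
})

test_that("HGVS strings parse into anchors, offsets and edit kinds", {
  v <- parse_hgvs("c.1431-12G>A")
  expect_equal(v$anchor, 1431L)
  expect_equal(v$intron_offset, -12L)
  expect_equal(v$edit_kind, "substitution")
  expect_equal(v$ref_bases, "G")
  expect_equal(v$alt_bases, "A")

  dup <- parse_hgvs("c.1032_1036dupGAAAA")
  expect_equal(dup$anchor, 1032L)
  expect_equal(dup$end_anchor, 1036L)
  expect_equal(dup$edit_kind, "duplication")
  expect_equal(dup$ref_bases, "GAAAA")

  di <- parse_hgvs("c.1816_1820+21delinsCT")
  expect_equal(di$edit_kind, "deletion/insertion")
  expect_equal(di$end_intron_offset, 21L)
})

test_that("whitespace inside printed variant strings is tolerated", {
  expect_equal(parse_hgvs("c. 995delT")[-1], parse_hgvs("c.995delT")[-1])
  expect_equal(parse_hgvs("c. 1887 + 1G>A")$hgvs, "c.1887+1G>A")
})

test_that("malformed or out-of-range strings raise named parse errors", {
  expect_error(parse_hgvs("c.abc>T"), "c\\.abc>T")
  expect_error(parse_hgvs("p.Arg371Ter"), "c\\.")
  expect_error(parse_hgvs("c.3196A>G"), "outside CDS")
  expect_error(parse_hgvs("c.0A>G"), "outside CDS")
  expect_error(parse_hgvs("c.10_5del"), "outside CDS|inverted")
  expect_error(parse_hgvs("c.995frobnicate"), "cannot parse edit")
})

test_that("parse/format round-trips every fixture variant string", {
  strings <- c("c.153delT", "c.1431-12G>A", "c.1111C>T", "c.1887+1G>A",
               "c.995delT", "c.81+2T>A", "c.891C>T",
               "c.1816_1820+21delinsCT", "c.2472_2473delAG", "c.2468delA",
               "c.1032_1036dupGAAAA", "c.2041_2042delAG")
  expect_equal(format_hgvs(parse_hgvs(strings)), strings)
})

test_that("codon anchoring uses the 5'-most coding base", {
  v <- parse_hgvs(c("c.153delT", "c.1887+1G>A", "c.1A>G",
                    "c.1032_1036dupGAAAA"))
  expect_equal(anchor_codon(v), c(51L, 629L, 1L, 344L))
  # anchor_codon(3k) = k for every codon
  k <- 1:1065
  expect_equal(as.integer(ceiling((3L * k) / 3)), k)
  v3 <- parse_hgvs(sprintf("c.%ddelA", 3L * c(1L, 533L, 1065L)))
  expect_equal(anchor_codon(v3), c(1L, 533L, 1065L))
})

test_that("half assignment is a monotone partition with boundary at 1598", {
  pos <- c(1L, 1598L, 1599L, 3195L)
  v <- parse_hgvs(sprintf("c.%dA>G", pos))
  expect_equal(assign_half(v), c(1L, 1L, 2L, 2L))
  # intronic offsets are ignored: the coding anchor decides
  expect_equal(assign_half(parse_hgvs("c.1431-12G>A")), 1L)
  expect_equal(assign_half(parse_hgvs("c.1887+1G>A")), 2L)

  all_pos <- parse_hgvs(sprintf("c.%dA>G", 1:3195))
  halves <- assign_half(all_pos)
  expect_setequal(unique(halves), c(1L, 2L))
  expect_true(all(diff(halves) >= 0))
  expect_equal(sum(halves == 1L), 1598L)
})

test_that("mutation-type classification covers all classes and never guesses", {
  v <- parse_hgvs(c("c.1431-12G>A", "c.2472_2473delAG", "c.1111C>T",
                    "c.1032_1036dupGAAAA", "c.100_101insA",
                    "c.200_201delinsGG", "c.891C>T"))
  prot <- c(NA, NA, "p.(Arg371*)", NA, NA, NA, NA)
  expect_equal(
    classify_type(v, prot),
    c("splicing", "deletion", "nonsense", "duplication", "insertion",
      "deletion/insertion", "unclassified")
  )
  expect_equal(classify_type(parse_hgvs("c.100G>A"), "p.(Gly34Ser)"),
               "missense")
  expect_equal(classify_type(parse_hgvs("c.100G>A"), "p.(Trp34Ter)"),
               "nonsense")
  expect_error(classify_type(parse_hgvs("c.81+2T>A"), "p.(Gly28Ser)"),
               "intronic")
})

test_that("classification is total over simulated variants", {
  sim <- simulate_cohort(simulation_config(n_patients = 1500, seed = 11))
  types <- c(sim$a1_type, sim$a2_type)
  expect_false(anyNA(types))
  expect_true(all(types %in% c(mutation_types(), "unclassified")))
  expect_setequal(setdiff(unique(types), "unclassified"),
                  mutation_types())
})
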