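test_that("profile library is seed-deterministic with separable RH/ARH", {
  a <- make_profile_library(1)
  b <- make_profile_library(1)
  expect_identical(a, b)
  expect_equal(a$ARH$length, 130)  # the aRH domain is ~130 aa
  expect_equal(a$RH$length, 130)
  for (spec in a[c("RH", "ARH")])
    expect_identical(spec$catalytic_positions$res, c("D", "E", "D", "D"))
  for (seed in 1:20) {
    lib <- make_profile_library(seed)
    ident <- mean(strsplit(lib$RH$consensus, "")[[1]] ==
                    strsplit(lib$ARH$consensus, "")[[1]])
    expect_lt(ident, 0.6)
  }
})

test_that("mutate_protein respects rate, frozen positions and bounds", {
  s <- paste(rep("A", 50), collapse = "")
  expect_identical(mutate_protein(s, 0, seed = 1), s)
  expect_identical(mutate_protein(s, 1, seed = 1, frozen = 1:50), s)
  expect_error(mutate_protein(s, 1.2, seed = 1), class = "rtt_parameter_error")
  expect_error(mutate_protein(s, 0.5, seed = 1, frozen = 99),
               class = "rtt_parameter_error")
  long <- withr::with_seed(9, paste(sample(c("A", "L", "K"), 1000, TRUE),
                                    collapse = ""))
  nsub <- vapply(1:50, function(i) {
    m <- mutate_protein(long, 0.1, seed = i)
    sum(strsplit(m, "")[[1]] != strsplit(long, "")[[1]])
  }, numeric(1))
  expect_gt(mean(nsub), 80)  # binomial mean 100, 3-sigma band
  expect_lt(mean(nsub), 120)
})

test_that("back_translate round-trips under the standard code", {
  expect_identical(back_translate("M", 1), "ATG")
  expect_identical(back_translate("W", 5), "TGG")
  expect_error(back_translate("MX", 1), class = "rtt_parameter_error")
  withr::with_seed(3, {
    for (i in 1:100) {
      s <- paste(sample(retrotether:::AA20, 25, TRUE), collapse = "")
      expect_identical(retrotether:::translate_dna(back_translate(s, i)), s)
    }
  })
})

test_that("build_element emits the declared architecture", {
  lib <- fixture_library()
  el <- build_element(element_blueprint("S1", seed = 3), lib)
  expect_identical(el$truth$domain_spans$domain,
                   c("GAG", "PR", "RT", "RH", "ARH", "INT"))
  l5 <- substr(el$dna, 1, 300)
  l3 <- substr(el$dna, el$truth$ltr_spans$three[1] + 1,
               el$truth$ltr_spans$three[2])
  expect_identical(l5, l3)  # zero LTR divergence -> identical copies
  # every planted ORF is ATG..stop with no internal in-frame stops
  for (r in seq_len(nrow(el$truth$orf_spans))) {
    orf <- substr(el$dna, el$truth$orf_spans$start[r] + 1,
                  el$truth$orf_spans$end[r])
    expect_identical(substr(orf, 1, 3), "ATG")
    aa <- retrotether:::translate_dna(orf)
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
  # zero divergence: translated domain spans equal the consensus
  for (r in seq_len(nrow(el$truth$domain_spans))) {
    ds <- el$truth$domain_spans[r, ]
    aa <- retrotether:::translate_dna(substr(el$dna, ds$start + 1, ds$end))
    expect_identical(aa, lib[[ds$domain]]$consensus)
  }
})

test_that("S5 distal degradation and NO_ARH truth are as declared", {
  lib <- fixture_library()
  s5 <- build_element(element_blueprint("S5", degrade_distal_arh = TRUE,
                                        seed = 4), lib)
  expect_identical(unname(s5$truth$arh_core_states["proximal"]), "DEDD")
  distal <- s5$truth$arh_core_states["distal"]
  expect_equal(sum(strsplit(unname(distal), "")[[1]] ==
                     c("D", "E", "D", "D")), 0)
  no <- build_element(element_blueprint("NO_ARH", seed = 5), lib)
  expect_false("ARH" %in% no$truth$domain_spans$domain)
  expect_length(no$truth$arh_core_states, 0)
})

test_that("degraded native RH loses all four carboxylates", {
  lib <- fixture_library()
  el <- build_element(element_blueprint("S1", degrade_native_rh = TRUE,
                                        seed = 6), lib)
  expect_equal(sum(strsplit(el$truth$rh_core_state, "")[[1]] ==
                     c("D", "E", "D", "D")), 0)
})

test_that("plant_elements places disjoint elements deterministically", {
  lib <- fixture_library()
  empty <- plant_elements(5000, list(), lib, seed = 1)
  expect_length(empty$truth, 0)
  expect_equal(nchar(empty$genome$seq), 5000)

  bps <- make_blueprints(rep(six_labels, length.out = 10), seed0 = 300)
  a <- plant_elements(400000, bps, lib, seed = 2)
  b <- plant_elements(400000, bps, lib, seed = 2)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(truth_table(a$truth), truth_table(b$truth))
  tt <- truth_table(a$truth)
  expect_equal(nrow(tt), 10)
  ord <- order(tt$start)
  expect_true(all(tt$start[ord][-1] >= tt$end[ord][-10]))  # disjoint
  expect_error(plant_elements(30000, bps, lib, seed = 2),
               class = "rtt_capacity_error")
})

test_that("minus-strand placement reflects coordinates faithfully", {
  lib <- fixture_library()
  bps <- make_blueprints(rep("S1", 6), seed0 = 500)
  sim <- plant_elements(250000, bps, lib, seed = 13)
  strands <- vapply(sim$truth, `[[`, character(1), "strand")
  expect_true(all(c("+", "-") %in% strands))  # both orientations exercised
  t <- sim$truth[[which(strands == "-")[1]]]
  el <- build_element(bps[[which(strands == "-")[1]]], lib)
  span_seq <- substr(sim$genome$seq, t$span[1] + 1, t$span[2])
  expect_identical(retrotether:::revcomp(span_seq), el$dna)
  # translated domain spans (element orientation) still match consensus
  ds <- t$domain_spans[1, ]
  sub <- substr(sim$genome$seq, ds$start + 1, ds$end)
  aa <- retrotether:::translate_dna(retrotether:::revcomp(sub))
  expect_identical(aa, lib[[ds$domain]]$consensus)
})

test_that("translated ORF domains stay near consensus at 5% divergence", {
  lib <- fixture_library()
  el <- build_element(element_blueprint("S2", domain_divergence = 0.05,
                                        seed = 21), lib)
  for (r in seq_len(nrow(el$truth$domain_spans))) {
    ds <- el$truth$domain_spans[r, ]
    aa <- retrotether:::translate_dna(substr(el$dna, ds$start + 1, ds$end))
    ident <- mean(strsplit(aa, "")[[1]] ==
                    strsplit(lib[[ds$domain]]$consensus, "")[[1]])
    expect_gte(ident, 1 - 0.05 - 0.05)
  }
})

test_that("truth exports to GFF3 and TSV and reimports", {
  lib <- fixture_library()
  sim <- plant_elements(120000, make_blueprints(c("S1", "S3"), seed0 = 40),
                        lib, seed = 3)
  gff <- tempfile(fileext = ".gff3")
  write_truth_gff3(sim$truth, gff)
  gr <- rtracklayer::import(gff)
  expect_equal(sum(gr$type == "mobile_genetic_element"), 2)
  expect_setequal(gr$structure[gr$type == "mobile_genetic_element"],
                  c("S1", "S3"))
  expect_equal(sum(gr$type == "long_terminal_repeat"), 4)
  # GFF3 is 1-based inclusive; truth spans are 0-based half-open
  mge <- gr[gr$type == "mobile_genetic_element"]
  expect_equal(min(GenomicRanges::start(mge)), sim$truth[[1]]$span[1] + 1)
})
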