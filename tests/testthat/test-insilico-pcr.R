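test_that("find_binding_sites locates exact prefix matches and applies thresholds", {
  tpl <- paste0("ACGTACGTAACC", random_dna(50, seed = 1))
  hits <- find_binding_sites("ACGTACGTAACC", tpl, strand = "+")
  expect_equal(hits$start[1], 1L)
  expect_equal(hits$mismatches[1], 0L)
  # one internal mismatch: invisible at max_mismatch 0, found at 1
  primer <- "ACGTACGAAACC"
  expect_equal(nrow(find_binding_sites(primer, tpl, 0L, strand = "+")), 0L)
  h1 <- find_binding_sites(primer, tpl, 1L, strand = "+")
  expect_equal(h1$start[1], 1L)
  expect_equal(h1$mismatches[1], 1L)
})

test_that("3'-window rule excludes terminally mismatched sites", {
  tpl <- paste0("GGTTGGTTGG", "CAAAAAAAAAACC", "GGTTGGTTGG")
  primer <- "CAAAAAAAAAACG"  # mismatch at the 3' terminal base
  expect_equal(nrow(find_binding_sites(primer, tpl, 1L, TRUE, strand = "+")), 0L)
  relaxed <- find_binding_sites(primer, tpl, 1L, FALSE, strand = "+")
  expect_equal(nrow(relaxed), 1L)
  expect_true(relaxed$three_prime_mismatch)
  # a reverse-orientation site: the primer's 3' end faces the footprint start
  primer_r <- revcomp("CAAAAAAAAAACC")
  hit <- find_binding_sites(primer_r, tpl, 0L, TRUE, strand = "-")
  expect_equal(hit$start, 11L)
  expect_equal(hit$mismatches, 0L)
})

test_that("binding-site scan agrees with the naive all-positions oracle", {
  set.seed(33)
  for (i in 1:40) {
    tpl <- random_dna(120)
    primer <- if (i %% 2 == 0) {
      substring(tpl, 40, 40 + sample(17:22, 1))  # planted site
    } else {
      random_dna(sample(18:22, 1))
    }
    # sprinkle IUPAC codes into the primer occasionally
    if (i %% 5 == 0) {
      pc <- strsplit(primer, "")[[1]]
      pc[sample(length(pc) - 4, 1)] <- sample(c("R", "Y", "N", "S"), 1)
      primer <- paste(pc, collapse = "")
    }
    mm <- sample(0:2, 1)
    for (str in c("+", "-")) {
      got <- find_binding_sites(primer, tpl, mm, TRUE, 3L, strand = str)
      want <- oracle_binding_sites(primer, tpl, mm, TRUE, 3L, strand = str)
      expect_equal(got$start, want$start, info = paste(i, str, mm))
      expect_equal(got$mismatches, want$mismatches)
    }
  }
})

test_that("raising max_mismatch never removes predicted products", {
  set.seed(44)
  for (i in 1:10) {
    tpl <- random_dna(400)
    f <- substring(tpl, 20, 39)
    r <- revcomp(substring(tpl, 220, 239))
    lens0 <- predict_amplicons(f, r, tpl, max_mismatch = 0L)$length
    lens1 <- predict_amplicons(f, r, tpl, max_mismatch = 1L)$length
    lens2 <- predict_amplicons(f, r, tpl, max_mismatch = 2L)$length
    expect_true(all(lens0 %in% lens1))
    expect_true(all(lens1 %in% lens2))
  }
})

test_that("amplicon geometry: constructed 117-bp product and ordering rules", {
  tpl <- random_dna(200, seed = 9)
  f <- substring(tpl, 31, 50)           # forward footprint 31..50
  r <- revcomp(substring(tpl, 128, 147))  # reverse footprint 128..147
  a <- predict_amplicons(f, r, tpl)
  expect_equal(nrow(a), 1L)
  expect_equal(a$length, 117L)
  expect_equal(a$length, a$end - a$start + 1L)
  # reversed geometry (plus-strand site downstream of the minus-strand
  # site) yields nothing
  f_down <- substring(tpl, 128, 147)
  r_up <- revcomp(substring(tpl, 31, 50))
  expect_equal(nrow(predict_amplicons(f_down, r_up, tpl)), 0L)
  # the pair is unordered on a double-stranded template
  expect_equal(predict_amplicons(r, f, tpl)$length, a$length)
  # strand symmetry: the reverse-complemented template gives the same length
  b <- predict_amplicons(f, r, revcomp(tpl))
  expect_equal(b$length, a$length)
})

test_that("specificity_matrix verdicts cover specific, off-target and untested cases", {
  gen <- generate_panel(panel_spec(seed = 20, n_species = 3, n_per_species = 2,
                                   length = 400, conserved_flank = 20))
  ms <- design_marker_set(gen$panel, "Species_A")
  sm <- specificity_matrix(ms$markers, gen$panel)
  expect_true(all(sm$verdicts == "species_specific"))
  tgt <- sm$templates$species == "Species_A"
  expect_true(all(sm$n_products[, tgt] > 0))
  expect_true(all(sm$n_products[, !tgt] == 0))

  # a universal primer pair amplifies everything -> off_target
  uni <- data.frame(marker_id = "UNI", species = "Species_A",
                    forward_seq = gen$truth$universal_primers$forward,
                    reverse_seq = gen$truth$universal_primers$reverse,
                    expected_size = 400L, stringsAsFactors = FALSE)
  sm2 <- specificity_matrix(uni, gen$panel)
  expect_equal(unname(sm2$verdicts), "off_target")

  # no templates of the marker's species -> untested
  other <- panel_templates(gen$panel)
  other <- other[other$species != "Species_A", ]
  sm3 <- specificity_matrix(ms$markers[1, ], other)
  expect_equal(unname(sm3$verdicts), "untested")

  gel <- virtual_gel(sm)
  expect_true(any(grepl("lane", gel)))
  expect_true(any(grepl("species_specific", gel)))
})

test_that("cross-species audit reports minimum mismatches and risk flags", {
  tpl <- random_dna(300, seed = 55)
  f <- substring(tpl, 50, 69)
  r <- revcomp(substring(tpl, 180, 199))
  mk <- data.frame(marker_id = "M1", species = "SpT",
                   forward_seq = f, reverse_seq = r, expected_size = 150L,
                   stringsAsFactors = FALSE)
  exact <- seq_records("near", tpl, species = "SpNear")
  audit <- audit_cross_species(mk, exact)
  expect_equal(audit$f_min_mismatch, 0L)
  expect_equal(audit$r_min_mismatch, 0L)
  expect_true(audit$risky)
  # a template with 2+ mismatches against each primer is not flagged
  ch <- strsplit(tpl, "")[[1]]
  flip <- function(x) c(A = "C", C = "A", G = "T", T = "G")[[x]]
  for (p in c(55, 60, 185, 190)) ch[p] <- flip(ch[p])
  far <- seq_records("far", paste(ch, collapse = ""), species = "SpFar")
  audit2 <- audit_cross_species(mk, far)
  expect_gte(audit2$f_min_mismatch, 2L)
  expect_false(audit2$risky)
})
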