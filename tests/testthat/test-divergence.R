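test_that("pairwise_distance matches closed-form K2P on single-change pairs", {
  a <- "AAAAAAAAAA"
  expect_equal(pairwise_distance(a, a)$d, 0)
  expect_equal(pairwise_distance(a, a)$P, 0)

  ts <- "GAAAAAAAAA"  # one A->G transition in 10 sites
  r <- pairwise_distance(a, ts, model = "K2P")
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0)
  expect_equal(r$d, -0.5 * log(0.8), tolerance = 1e-12)

  tv <- "CAAAAAAAAA"  # one A->C transversion
  r <- pairwise_distance(a, tv, model = "K2P")
  expect_equal(r$Q, 0.1)
  expect_equal(r$d, -0.5 * log(0.9 * sqrt(0.8)), tolerance = 1e-12)
  expect_equal(r$d, 0.10847, tolerance = 1e-4)

  expect_equal(pairwise_distance(a, ts, model = "p")$d, 0.1)
})

test_that("pairwise deletion excludes gaps and ambiguity codes from L", {
  r <- pairwise_distance("ACGT-ACGTN", "ACGTAAC-TR")
  expect_equal(r$L, 7L)  # columns 5, 8, 10 dropped
  # inserting a shared all-gap column never changes the distance
  a <- "ACGTACGTAA"; b <- "ACGTACGAAA"
  d0 <- pairwise_distance(a, b)$d
  d1 <- pairwise_distance(paste0("ACGT-", substring(a, 5)),
                          paste0("ACGT-", substring(b, 5)))$d
  expect_equal(d1, d0)
  expect_error(pairwise_distance("----", "AAAA"), "no comparable sites")
  expect_error(pairwise_distance("ACGTACGTAC", "CATGCATGCA"), "saturation")
})

test_that("K2P dominates the p distance and agrees with ape's K80", {
  set.seed(21)
  for (i in 1:15) {
    a <- random_dna(200)
    ch <- strsplit(a, "")[[1]]
    nm <- sample(200, sample(5:40, 1))
    for (p in nm) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    b <- paste(ch, collapse = "")
    k2p <- pairwise_distance(a, b, "K2P")$d
    pd <- pairwise_distance(a, b, "p")$d
    expect_gte(k2p, pd)
    bin <- ape::as.DNAbin(list(a = strsplit(tolower(a), "")[[1]],
                               b = strsplit(tolower(b), "")[[1]]))
    expect_equal(k2p, as.numeric(ape::dist.dna(bin, model = "K80",
                                               pairwise.deletion = TRUE)),
                 tolerance = 1e-10)
  }
})

test_that("distance_matrix equals a naive double loop and is symmetric", {
  gen <- generate_panel(panel_spec(seed = 5, n_species = 3, n_per_species = 2,
                                   length = 120, conserved_flank = 10))
  dm <- distance_matrix(gen$panel)
  expect_true(isSymmetric(dm$d))
  expect_true(all(diag(dm$d) == 0))
  r <- gen$panel$records
  for (i in 1:(nrow(r) - 1)) {
    for (j in (i + 1):nrow(r)) {
      expect_equal(dm$d[i, j], pairwise_distance(r$bases[i], r$bases[j])$d)
    }
  }
  expect_true(all(dm$L <= gen$panel$aligned_length))
})

test_that("variability_summary handles degenerate and polymorphic panels", {
  # two species, two identical records each, all heterospecific p-distances 0.1
  a <- paste(rep("A", 30), collapse = "")
  b <- paste(c(rep("C", 3), rep("A", 27)), collapse = "")  # 3/30 transversions
  pan <- species_panel(seq_records(c("a1", "a2", "b1", "b2"), c(a, a, b, b),
                                   species = c("SpA", "SpA", "SpB", "SpB")))
  vs <- variability_summary(pan, model = "p")
  expect_equal(vs$intra_mean, c(0, 0))
  expect_equal(vs$intra_sd, c(0, 0))
  expect_equal(vs$inter_mean, c(0.1, 0.1))
  expect_equal(vs$inter_sd, c(0, 0))

  # single-member species: intra undefined, not zero
  pan2 <- species_panel(seq_records(c("a1", "a2", "c1"), c(a, a, b),
                                    species = c("SpA", "SpA", "SpC")))
  vs2 <- variability_summary(pan2, model = "p")
  expect_true(is.na(vs2$intra_mean[vs2$species == "SpC"]))
  expect_equal(vs2$intra_mean[vs2$species == "SpA"], 0)

  # species_means inter mode averages per-pair means
  vs3 <- variability_summary(pan, model = "p", inter_mode = "species_means")
  expect_equal(vs3$inter_mean, c(0.1, 0.1))
})

test_that("summary recovers the generator's programmed divergence structure", {
  spec <- panel_spec(seed = 31, intra_divergence = c(0, 0))
  gen <- generate_panel(spec)
  vs <- variability_summary(gen$panel)
  expect_true(all(vs$intra_mean == 0))
  # every inter mean inside (or near) the programmed 9-21% band
  expect_true(all(vs$inter_mean > 0.07 & vs$inter_mean < 0.25))
  # per-species-pair distance tracks the sum of the two branch divergences
  bd <- gen$truth$species_branch_divergence
  dm <- distance_matrix(gen$panel)
  sp <- gen$panel$records$species
  for (s1 in names(bd)[1:3]) {
    for (s2 in names(bd)[4:6]) {
      got <- mean(dm$d[sp == s1, sp == s2])
      expect_lt(abs(got - (bd[[s1]] + bd[[s2]])) / (bd[[s1]] + bd[[s2]]), 0.2)
    }
  }
})

test_that("distance matrices export to PHYLIP and TSV", {
  dm <- distance_matrix(toy_panel())
  f1 <- withr::local_tempfile(fileext = ".phy")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_phylip(dm, f1)
  write_distance_tsv(dm, f2)
  expect_equal(as.integer(trimws(readLines(f1)[1])), 5L)
  back <- utils::read.delim(f2)
  expect_equal(back$id, dm$labels)
})
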