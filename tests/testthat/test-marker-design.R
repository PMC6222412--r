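test_that("find_diagnostic_sites flags substitutions and indels in the toy panel", {
  p <- toy_panel()
  sa <- find_diagnostic_sites(p, "SpA")
  expect_equal(sa$column, 5L)
  expect_equal(sa$target_state, "T")
  expect_equal(sa$kind, "substitution")
  sb <- find_diagnostic_sites(p, "SpB")
  expect_equal(sb$column, c(11L, 12L))
  expect_true(all(sb$kind == "indel"))
  expect_true(all(sb$target_state == "-"))
  expect_equal(nrow(find_diagnostic_sites(p, "SpC")), 0L)
  expect_error(find_diagnostic_sites(p, "SpX"), "not in panel")
})

test_that("diagnostic scan agrees with the definition-based oracle on synthetic panels", {
  for (seed in c(3, 9)) {
    gen <- generate_panel(panel_spec(seed = seed, n_species = 4,
                                     n_per_species = 2, length = 200,
                                     conserved_flank = 15))
    for (s in panel_species(gen$panel)) {
      got <- find_diagnostic_sites(gen$panel, s)
      want <- oracle_diag_sites(gen$panel, s)
      expect_equal(got$column, want$column, info = paste(seed, s))
      expect_equal(got$target_state, want$target_state)
      expect_equal(got$kind, want$kind)
    }
  }
})

test_that("partial fixation threshold admits polymorphic targets", {
  seqs <- c(a1 = "AAGGCCAATT", a2 = "AAGGCCAATT", a3 = "ATGGCCAATT",
            b1 = "AAGGCCGATT")
  p <- species_panel(seq_records(names(seqs), unname(seqs),
                                 species = c("SpA", "SpA", "SpA", "SpB")))
  # column 2 is 2/3 A within SpA: rejected at full fixation, nothing to find
  expect_false(2L %in% find_diagnostic_sites(p, "SpA")$column)
  # column 7 is fixed A in SpA vs G in SpB
  expect_true(7L %in% find_diagnostic_sites(p, "SpA")$column)
})

test_that("enumerate_primers equals a sliding-window brute force", {
  gen <- generate_panel(panel_spec(seed = 12, n_species = 3, n_per_species = 2,
                                   length = 150, conserved_flank = 10))
  pan <- gen$panel
  target <- "Species_A"
  cons <- design_constraints(primer_length = c(18L, 20L))
  cand <- enumerate_primers(pan, target, cons)
  sites <- find_diagnostic_sites(pan, target)
  # brute force over every window of the ungapped reference, both strands
  ridx <- which(pan$records$species == target)[1]
  refch <- pan$mat[ridx, ]
  keepc <- which(refch != "-")
  refseq <- paste(refch[keepc], collapse = "")
  tmat <- pan$mat[pan$records$species == target, , drop = FALSE]
  brute <- list()
  for (m in 18:20) {
    for (a in seq_len(nchar(refseq) - m + 1)) {
      b <- a + m - 1
      w <- substring(refseq, a, b)
      cols <- keepc[a]:keepc[b]
      ndiag <- sum(sites$column %in% cols)
      fixed <- all(apply(tmat[, cols, drop = FALSE], 2,
                         function(x) length(unique(x)) == 1))
      gcf <- gc_content(w)
      okhp <- max(rle(strsplit(w, "")[[1]])$lengths) <= cons$max_homopolymer
      tmw <- tm_wallace(w)
      if (ndiag >= 1 && fixed && gcf >= cons$gc[1] && gcf <= cons$gc[2] &&
          tmw >= cons$tm[1] && tmw <= cons$tm[2] && okhp) {
        brute[[length(brute) + 1]] <- data.frame(start = a, length = m)
      }
    }
  }
  brute <- do.call(rbind, brute)
  got_plus <- unique(cand[cand$strand == "+", c("start", "length")])
  expect_equal(nrow(got_plus), nrow(brute))
  expect_setequal(paste(got_plus$start, got_plus$length),
                  paste(brute$start, brute$length))
  # both strands enumerate the same windows
  got_minus <- unique(cand[cand$strand == "-", c("start", "length")])
  expect_equal(nrow(got_minus), nrow(got_plus))
  # minus-strand bases are the reverse complement of the window
  i <- which(cand$strand == "-")[1]
  w <- substring(refseq, cand$start[i], cand$start[i] + cand$length[i] - 1)
  expect_equal(cand$bases[i], revcomp(w))
})

test_that("pair_primers does coordinate arithmetic and matches a brute-force pairing", {
  cand <- data.frame(
    name = c("F1", "R1"),
    bases = c(paste(rep("A", 20), collapse = ""),
              paste(rep("T", 20), collapse = "")),
    strand = c("+", "-"), start = c(1L, 83L), length = 20L,
    gc = 0.5, tm = 60, diag_count = c(2L, 1L), diag_subs = c(2L, 1L),
    three_prime_diagnostic = FALSE, stringsAsFactors = FALSE)
  mk <- pair_primers(cand, "SpX")
  expect_equal(nrow(mk), 1L)
  # single F starting at 1, R footprint ending at 102 -> amplicon 102
  expect_equal(mk$expected_size, 102L)
  # ">=2 diagnostic substitutions in one primer" rule
  cand2 <- cand; cand2$diag_subs <- c(1L, 1L)
  expect_equal(nrow(pair_primers(cand2, "SpX")), 0L)

  # brute-force oracle on a larger candidate set
  gen <- generate_panel(panel_spec(seed = 12, n_species = 3, n_per_species = 2,
                                   length = 200, conserved_flank = 10))
  cons <- design_constraints()
  cand3 <- enumerate_primers(gen$panel, "Species_B", cons)
  cand3 <- utils::head(cand3, 10)
  got <- pair_primers(cand3, "Species_B", cons)
  fwd <- cand3[cand3$strand == "+", ]; rv <- cand3[cand3$strand == "-", ]
  n_brute <- 0
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rv))) {
      size <- rv$start[j] + rv$length[j] - fwd$start[i]
      disjoint <- fwd$start[i] + fwd$length[i] - 1 < rv$start[j]
      if (disjoint && size >= cons$amplicon[1] && size <= cons$amplicon[2] &&
          max(fwd$diag_subs[i], rv$diag_subs[j]) >= 2) {
        n_brute <- n_brute + 1
      }
    }
  }
  expect_equal(nrow(got), n_brute)
})

test_that("design_marker_set returns a validated, resolvable duplex deterministically", {
  gen <- generate_panel(panel_spec(seed = 6))
  ms1 <- design_marker_set(gen$panel, "Species_A")
  ms2 <- design_marker_set(gen$panel, "Species_A")
  expect_equal(ms1$status, "ok")
  expect_identical(ms1$markers, ms2$markers)
  expect_equal(nrow(ms1$markers), 2L)
  expect_gte(abs(diff(ms1$markers$expected_size)), 20L)
  expect_true(all(pmax(ms1$markers$f_diag_subs, ms1$markers$r_diag_subs) >= 2))
  # both markers amplify every conspecific template and nothing else
  sm <- specificity_matrix(ms1$markers, gen$panel)
  expect_true(all(sm$verdicts == "species_specific"))
})

test_that("designed primers cover planted diagnostic columns", {
  gen <- generate_panel(panel_spec(seed = 13, intra_divergence = c(0, 0)))
  planted <- gen$truth$diagnostic_columns[["Species_B"]]
  ms <- design_marker_set(gen$panel, "Species_B")
  found <- find_diagnostic_sites(gen$panel, "Species_B")
  # zero false negatives: every planted column is discovered
  expect_true(all(planted %in% found$column))
  expect_gte(sum(ms$markers$f_diag_subs) + sum(ms$markers$r_diag_subs), 2)
})

test_that("marker tables round-trip through TSV and pair the published layout", {
  mk <- read_primer_pairs(table3_path())
  expect_equal(nrow(mk), 10L)
  expect_equal(mk$expected_size[mk$marker_id == "CM_F3/CM_R3"], 102L)
  expect_equal(unique(table(mk$species)), 2L)  # two markers per species
  f <- withr::local_tempfile(fileext = ".tsv")
  write_marker_table(mk, f)
  back <- read_primer_pairs(f)
  expect_equal(back$forward_seq, mk$forward_seq)
  expect_equal(back$expected_size, mk$expected_size)
})

test_that("marker BED export converts to 0-based half-open intervals", {
  mk <- data.frame(marker_id = "M1", f_start = 10L, r_end = 109L)
  f <- withr::local_tempfile(fileext = ".bed")
  write_marker_bed(mk, "ref", f)
  bed <- utils::read.delim(f, header = FALSE)
  expect_equal(bed$V2, 9L)
  expect_equal(bed$V3, 109L)
  expect_equal(bed$V3 - bed$V2, 100L)
})
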