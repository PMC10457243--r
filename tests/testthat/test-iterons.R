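test_that("degenerate consensus builds and renders by the majority rule", {
  expect_identical(render_consensus(build_consensus(c("ACG", "ACG",
                                                      "ACT", "ACT"))),
                   "AC(G/T)")
  expect_identical(render_consensus(build_consensus(c("AAA", "AAA", "AAA"))),
                   "AAA")
  # majority first, alphabetical on ties
  expect_identical(render_consensus(build_consensus(c("T", "T", "G"))),
                   "(T/G)")
  expect_identical(render_consensus(build_consensus(c("T", "G"))),
                   "(G/T)")
  expect_error(build_consensus(c("AC", "ACG")), "equal length")
  expect_error(build_consensus("ACG"), "at least 2")
})

test_that("consensus notation round-trips through the parser", {
  strings <- c("ACGT", "AC(G/T)", "CT(A/T)(T/G)ATGACTACAAATCCTTAC",
               "(A/C/G)A(T/A)")
  for (s in strings) {
    expect_identical(render_consensus(parse_consensus(s)), s)
  }
  expect_identical(consensus_length("CT(A/T)(T/G)ATGACTACAAATCCTTAC"), 22L)
  expect_identical(render_consensus(parse_consensus("5'-AC(G/T)-3'")),
                   "AC(G/T)")
  expect_error(parse_consensus("AC(G/U)"), "cannot parse")
})

test_that("an exact tandem array is found with its unit and copy number", {
  unit <- "CATAAAGCTACGTTTAGCGACC"  # 22 bp, 4 copies: the canonical layout
  seq <- paste0(random_dna(150, seed = 21), strrep(unit, 4),
                random_dna(150, seed = 22))
  arr <- find_iteron_arrays(seq)
  expect_length(arr, 1L)
  expect_identical(arr[[1]]$unit_length, 22L)
  expect_identical(arr[[1]]$copy_count, 4L)
  expect_identical(arr[[1]]$copy_starts[1], 151L)
  expect_identical(render_consensus(arr[[1]]$consensus), unit)
  expect_equal(arr[[1]]$mean_mismatch_frac, 0)
})

test_that("low-complexity tracts are suppressed", {
  expect_length(find_iteron_arrays(strrep("A", 200)), 0L)
  expect_length(find_iteron_arrays(strrep("AT", 120)), 0L)
})

test_that("a noisy planted array is recovered and is the only call", {
  unit <- substr(random_dna(21, seed = 31), 1, 21)
  gen <- make_iteron_plasmid(seed = 33, unit = unit, copies = 4,
                             sub_prob = 0.04, len = 1000)
  seq <- gen$record$sequence
  truth <- gen$truth$planted_iterons[[1]]
  arr <- find_iteron_arrays(substr(seq, 1, 500))
  expect_length(arr, 1L)
  expect_identical(arr[[1]]$unit_length, 21L)
  expect_identical(arr[[1]]$copy_count, 4L)
  # tandem arrays are phase-ambiguous: an equally good description may
  # start within one unit of the planted phase, but must cover the array
  expect_lte(abs(arr[[1]]$copy_starts[1] - truth$copy_starts[1]), 21L)
})

test_that("zero-mismatch detection equals the naive exact tandem scan", {
  for (seed in 1:5) {
    gen <- make_iteron_plasmid(seed = seed, unit = 20L, copies = 4,
                               len = 1200)
    seq <- gen$record$sequence
    got <- find_iteron_arrays(seq, min_copies = 3, max_mismatch_frac = 0)
    want <- oracle_exact_tandem(seq, c(18, 24), 3)
    got_keys <- vapply(got, function(a) {
      paste(a$copy_starts[1], a$unit_length, a$copy_count)
    }, "")
    want_keys <- vapply(want, function(w) paste(w[1], w[2], w[3]), "")
    expect_identical(got_keys, want_keys, info = paste("seed", seed))
  }
})

test_that("detection is invariant to circular rotation of the plasmid", {
  gen <- make_iteron_plasmid(seed = 41, unit = 22L, copies = 4, len = 1200)
  seq <- gen$record$sequence
  base <- find_iteron_arrays(seq)
  expect_length(base, 1L)
  for (k in c(300, 700, 1100)) {
    rot <- rotate_sequence(seq, k)
    # rotate so the array is not split by the linearization point
    arr <- find_iteron_arrays(rot)
    expect_length(arr, 1L)
    expect_identical(arr[[1]]$unit_length, base[[1]]$unit_length)
    expect_identical(arr[[1]]$copy_count, base[[1]]$copy_count)
    expect_identical(render_consensus(arr[[1]]$consensus),
                     render_consensus(base[[1]]$consensus))
  }
})

test_that("upstream_window obeys strand and wraps through the origin", {
  seq <- random_dna(2000, seed = 51)
  rec <- plasmid_record("p", seq)
  plus <- list(start = 1000L, end = 1300L, strand = "+")
  expect_identical(upstream_window(rec, plus, 500), substr(seq, 500, 999))
  minus <- list(start = 1000L, end = 1300L, strand = "-")
  expect_identical(upstream_window(rec, minus, 500),
                   revcomp(substr(seq, 1301, 1800)))
  # gene near the origin: the window wraps
  early <- list(start = 100L, end = 400L, strand = "+")
  expect_identical(upstream_window(rec, early, 500),
                   paste0(substr(seq, 1600, 2000), substr(seq, 1, 99)))
  expect_warning(upstream_window(rec, plus, 5000), "truncated")
})

test_that("planted iterons are recovered from the upstream window", {
  unit <- "CATAAAGCTACGTTTAGCGACC"
  gen <- make_iteron_plasmid(seed = 61, unit = unit, copies = 4, len = 2000)
  det <- detect_iterons(gen$record, window = 500)
  fwd <- Filter(function(a) a$strand == "+", det)
  expect_true(length(fwd) >= 1L)
  expect_identical(fwd[[1]]$unit_length, 22L)
  expect_identical(fwd[[1]]$copy_count, 4L)
  expect_identical(render_consensus(fwd[[1]]$consensus), unit)
})

test_that("argument validation fails fast", {
  expect_error(find_iteron_arrays("ACGT", unit_range = c(24, 18)),
               "unit_range")
  expect_error(find_iteron_arrays("ACGT", max_spacer = 99), "max_spacer")
})
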