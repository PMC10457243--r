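test_that("self-alignment gives identity 1, coverage 1, diagonal score", {
  set.seed(201)
  a <- random_protein(100)
  hit <- local_align(a, a)
  expect_equal(hit$identity, 1)
  expect_equal(hit$positives, 1)
  expect_equal(hit$coverage, 1)
  # raw score of a perfect self-alignment = sum of diagonal matrix entries
  diag_sum <- sum(blosum62[cbind(strsplit(a, "")[[1]],
                                 strsplit(a, "")[[1]])])
  expect_equal(hit$raw_score, diag_sum)
  expect_error(local_align("", a), "empty")
})

test_that("scores are symmetric and match the affine-gap DP oracle", {
  set.seed(202)
  for (k in 1:40) {
    a <- random_protein(8)
    b <- random_protein(8)
    s_fwd <- local_align(a, b)$raw_score
    expect_equal(s_fwd, local_align(b, a)$raw_score)
    expect_equal(s_fwd, oracle_local_score(a, b),
                 info = paste(a, b))
  }
  # and on a longer gapped pair
  a <- paste0(random_protein(30), "QQQQQ", random_protein(25))
  b <- sub("QQQQQ", "", a)
  expect_equal(local_align(a, b)$raw_score, oracle_local_score(a, b))
})

test_that("the Karlin-Altschul estimate follows its closed form", {
  expect_equal(estimate_evalue(0, 100, 50), 0.041 * 100 * 50)
  expect_equal(estimate_evalue(30, 100, 200),
               2 * estimate_evalue(30, 100, 100))
  expect_equal(estimate_evalue(40, 100, 100),
               0.041 * 1e4 * exp(-0.267 * 40))
  s <- seq(0, 200, by = 10)
  expect_true(all(diff(estimate_evalue(s, 100, 100)) < 0))
  expect_error(estimate_evalue(10, 0, 100), "positive")
})

test_that("edges require reciprocated similarity above all thresholds", {
  set.seed(203)
  a <- random_protein(150)
  prots <- protein_set(c("A", "B", "C"),
                       c(a, a, random_protein(150)),
                       plasmid_id = c("p1", "p2", "p3"))
  net <- build_network(prots)
  el <- igraph::as_data_frame(net$graph, "edges")
  expect_identical(nrow(el), 1L)
  expect_setequal(unlist(el[, c("from", "to")]), c("A", "B"))
  expect_equal(el$weight, 1)
  comp <- split(names(net$components), net$components)
  expect_setequal(unname(vapply(comp, paste, "", collapse = "+")),
                  c("A+B", "C"))
})

test_that("network edges equal an exhaustive pairwise-check oracle", {
  fam <- generate_protein_families(3, 3, within_identity = 0.80,
                                   between_identity = 0.15,
                                   length = 120, seed = 204)
  prots <- fam$proteins
  net <- build_network(prots)
  got <- igraph::as_data_frame(net$graph, "edges")
  got_keys <- sort(paste(pmin(got$from, got$to), pmax(got$from, got$to)))
  want_keys <- character(0)
  for (i in 1:(nrow(prots) - 1)) {
    for (j in (i + 1):nrow(prots)) {
      f <- local_align(prots[i, ], prots[j, ])
      r <- local_align(prots[j, ], prots[i, ])
      pass <- function(h) h$evalue <= 1e-10 && h$identity >= 0.30 &&
        h$coverage >= 0.90
      if (pass(f) && pass(r)) {
        want_keys <- c(want_keys,
                       paste(pmin(prots$id[i], prots$id[j]),
                             pmax(prots$id[i], prots$id[j])))
      }
    }
  }
  expect_identical(got_keys, sort(want_keys))
})

test_that("edge weights stay within threshold bounds and edges persist", {
  fam <- generate_protein_families(2, 4, within_identity = 0.85,
                                   between_identity = 0.15,
                                   length = 150, seed = 205)
  net <- build_network(fam$proteins)
  w <- igraph::E(net$graph)$weight
  expect_true(all(w >= 0.30 * 0.90 & w <= 1))
  # adding an unrelated protein never removes existing edges
  set.seed(206)
  plus <- rbind(fam$proteins,
                protein_set("odd", random_protein(150)))
  class(plus) <- class(fam$proteins)
  net2 <- build_network(plus)
  e1 <- igraph::as_data_frame(net$graph, "edges")
  e2 <- igraph::as_data_frame(net2$graph, "edges")
  expect_true(all(paste(e1$from, e1$to) %in% paste(e2$from, e2$to)))
})

test_that("component count never increases as thresholds relax", {
  fam <- generate_protein_families(3, 3, within_identity = 0.75,
                                   between_identity = 0.15,
                                   length = 120, seed = 207)
  strict <- build_network(fam$proteins, identity_min = 0.60)
  relaxed <- build_network(fam$proteins, identity_min = 0.30)
  expect_lte(max(relaxed$components), max(strict$components))
})

test_that("reference classification picks the right family", {
  set.seed(208)
  refs <- data.frame(
    id = c("ref_mobP", "ref_mobQ", "ref_mobV"),
    label = c("MOB_P", "MOB_Q", "MOB_V"),
    sequence = c(random_protein(200), random_protein(200),
                 random_protein(200)),
    stringsAsFactors = FALSE)
  # identical query
  expect_identical(classify_protein(refs$sequence[1], refs)$label, "MOB_P")
  # planted MOB_Q-derived variant at 60% identity
  variant <- mutate_to_identity(refs$sequence[2], 0.60, seed = 209)
  expect_identical(classify_protein(variant, refs)$label, "MOB_Q")
  # shuffled residues match nothing
  shuffled <- paste(sample(strsplit(refs$sequence[3], "")[[1]]),
                    collapse = "")
  expect_identical(classify_protein(shuffled, refs)$label, "unclassified")
  expect_error(classify_protein(variant, refs[0, ]), "empty")
})

test_that("reciprocal similarity reports both directions consistently", {
  set.seed(210)
  a <- random_protein(250)
  self <- reciprocal_similarity(a, a)
  expect_equal(self$identity_pct, c(100, 100))
  expect_equal(self$positives_pct, c(100, 100))
  b <- mutate_to_identity(a, 0.70, seed = 211)
  rep <- reciprocal_similarity(a, b)
  expect_identical(nrow(rep), 2L)
  expect_true(all(rep$positives_pct >= rep$identity_pct))
  expect_equal(rep$identity_pct[1], rep$identity_pct[2])
})
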