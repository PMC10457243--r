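test_that("generation is fully deterministic given the seed", {
  g1 <- generate_plasmid(3000, 0.4,
                         modules = list(rep = list(copies = 4), mob = TRUE),
                         seed = 301)
  g2 <- generate_plasmid(3000, 0.4,
                         modules = list(rep = list(copies = 4), mob = TRUE),
                         seed = 301)
  expect_identical(g1$record$sequence, g2$record$sequence)
  expect_identical(g1$record$features, g2$record$features)
  expect_identical(g1$truth$planted_iterons, g2$truth$planted_iterons)
  g3 <- generate_plasmid(3000, 0.4,
                         modules = list(rep = list(copies = 4), mob = TRUE),
                         seed = 302)
  expect_false(identical(g1$record$sequence, g3$record$sequence))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_plasmid(1000, 0.4, seed = 303))
  expect_identical(runif(1), before)
})

test_that("a zero-noise planted array is recovered exactly", {
  unit <- "CATAAAGCTACGTTTAGCGACC"
  gen <- generate_plasmid(5000, 0.4,
                          modules = list(rep = list(iteron_unit = unit,
                                                    copies = 4,
                                                    sub_prob = 0)),
                          seed = 304)
  truth <- gen$truth$planted_iterons[[1]]
  det <- Filter(function(a) a$strand == "+",
                detect_iterons(gen$record, window = 500))
  expect_length(det, 1L)
  expect_identical(det[[1]]$unit_length, truth$unit_length)
  expect_identical(det[[1]]$copy_count, truth$copy_count)
  expect_identical(render_consensus(det[[1]]$consensus), unit)
})

test_that("a requested site-free region screens clean", {
  gen <- generate_plasmid(4000, 0.4,
                          modules = list(site_free = list(start = 3600,
                                                          end = 400)),
                          seed = 305)
  res <- screen_module(gen$record,
                       module_region("synthetic_plasmid", 3600, 400, "REP"))
  expect_length(res$non_cutting, 13L)
})

test_that("realized GC tracks the requested value", {
  # 10-kb replicons: binomial sampling noise (sd ~0.5 points) sits well
  # inside the 2-point contract
  gcs <- vapply(1:50, function(s) {
    gc_content(generate_plasmid(10000, 0.42, seed = s)$record$sequence)
  }, 0)
  expect_true(all(abs(gcs - 42) <= 2))
  expect_lt(abs(mean(gcs) - 42), 0.5)
})

test_that("module requests that cannot fit are rejected", {
  expect_error(generate_plasmid(500, 0.4, seed = 1), "between")
  expect_error(
    generate_plasmid(1000, 0.4,
                     modules = list(rep = list(aa_len = 600)), seed = 1),
    "exceeds")
})

test_that("mutate_to_identity hits its target identity", {
  set.seed(306)
  a <- random_protein(300)
  expect_identical(mutate_to_identity(a, 1.0, seed = 1), a)
  got <- vapply(1:20, function(s) {
    b <- mutate_to_identity(a, 0.8, seed = s)
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    mean(x == y)
  }, 0)
  expect_true(mean(got) >= 0.77 && mean(got) <= 0.83)
  # local alignment identity is at least the global identity
  b <- mutate_to_identity(a, 0.8, seed = 7)
  expect_gte(local_align(a, b)$identity, 0.8 - 1e-9)
  expect_error(mutate_to_identity(a, 0), "target identity")
  expect_error(mutate_to_identity(random_protein(20), 0.8), "shorter")
})

test_that("mutate_to_similarity realizes the wanted positives fraction", {
  set.seed(307)
  a <- random_protein(300)
  b <- mutate_to_similarity(a, 0.87, seed = 308)
  expect_equal(local_align(a, b)$positives, 0.87, tolerance = 0.05)
  expect_error(mutate_to_similarity(a, 0.05), "target positives")
})

test_that("protein families have the requested identity structure", {
  fam <- generate_protein_families(4, 5, within_identity = 0.85,
                                   between_identity = 0.15,
                                   length = 300, seed = 309)
  prots <- fam$proteins
  expect_identical(nrow(prots), 20L)
  expect_identical(unname(fam$truth$family_labels[prots$id]),
                   prots$plasmid_id)
  pid <- function(i, j) {
    x <- strsplit(prots$sequence[i], "")[[1]]
    y <- strsplit(prots$sequence[j], "")[[1]]
    mean(x == y)
  }
  within <- c(pid(1, 2), pid(6, 7), pid(11, 12))
  between <- c(pid(1, 6), pid(6, 11), pid(11, 16))
  expect_true(all(within > 0.75))
  expect_true(all(between < 0.30))
  # single family forms one connected component
  one <- generate_protein_families(1, 4, 0.85, 0.15, length = 150,
                                   seed = 310)
  expect_equal(max(build_network(one$proteins)$components), 1)
  # determinism
  again <- generate_protein_families(4, 5, 0.85, 0.15, length = 300,
                                     seed = 309)
  expect_identical(again$proteins$sequence, prots$sequence)
  expect_error(generate_protein_families(2, 2, 0.3, 0.5), "exceed")
})
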