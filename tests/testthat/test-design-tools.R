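test_that("analog generation enumerates all single substitutions", {
  a <- generate_analogs("GY")
  expect_equal(nrow(a), 38)
  expect_false("GY" %in% a$analog)
  expect_false(anyDuplicated(a$analog) > 0)
  # position-major, alphabetical within a position
  expect_equal(a$position, rep(1:2, each = 19))
  expect_equal(a$substituted[1:3], c("A", "C", "D"))
  # Hamming distance one from the parent, always
  hamming <- vapply(a$analog, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit("GY", "")[[1]])
  }, numeric(1))
  expect_true(all(hamming == 1))

  a3 <- generate_analogs("AAA")
  expect_equal(nrow(a3), 57)
  expect_false("AAA" %in% a3$analog)
  # an analog's analogs can recover the parent
  expect_true("AAA" %in% generate_analogs(a3$analog[1])$analog)
})

test_that("library screening scores valid rows and reports invalid ones", {
  train <- make_classification_set("medium", "non_aht", 8, 15, seed = 31)
  m <- aht_train(encode_aac(train), "label", category = "medium",
                 hyper = list(cost = 10, gamma = 0.05))
  bundle <- aht_bundle(m)
  lib <- c("PPWPAPLP", "GAGAGAGA", "AXBADCEF", "PPWPAPLP")
  expect_warning(out <- screen_library(lib, bundle), "invalid")
  expect_equal(nrow(out), 3)
  expect_equal(nrow(attr(out, "errors")), 1)
  # identical peptides get identical scores; ranking is score-descending
  dup_scores <- out$score[out$sequence == "PPWPAPLP"]
  expect_equal(dup_scores[1], dup_scores[2])
  expect_true(all(diff(out$score) <= 1e-12))
  # physicochemical panel is attached
  expect_true(all(c("mol_weight", "net_charge", "hydropathy") %in% names(out)))
})

test_that("protein scanning tiles every window of every length", {
  train <- make_classification_set("small", "non_aht", 4, 15, seed = 32)
  m <- aht_train(encode_aac(train), "label", category = "small_tetra",
                 hyper = list(cost = 10, gamma = 0.05))
  bundle <- aht_bundle(m)
  protein <- "GYSAQLKPWM"
  hits <- scan_protein(protein, bundle, window_lengths = 4)
  expect_equal(nrow(hits), 7)
  expect_equal(hits$start, 1:7)
  expect_equal(hits$end - hits$start + 1, rep(4, 7))
  # the reported window sequence is the protein substring
  expect_equal(hits$sequence,
               substring(protein, hits$start, hits$end))
  expect_warning(
    short <- scan_protein("GYSA", bundle, window_lengths = c(4, 9)),
    "skipped"
  )
  expect_equal(nrow(short), 1)
})

test_that("negative sampling respects ratio, exclusions and seeds", {
  with_seed_local(33, {
    background <- replicate(30, paste(
      sample(c("A", "G", "L", "S", "V", "P", "K", "X"), 40, TRUE),
      collapse = ""))
  })
  positives <- c("GYSA", "PPKA")
  neg <- sample_negatives(background, w = 4, n = 50,
                          exclusions = positives, seed = 7)
  expect_length(neg, 50)
  expect_equal(nchar(neg), rep(4, 50))
  expect_length(intersect(neg, positives), 0)
  expect_false(any(grepl("X", neg)))
  # determinism: same seed, same sample; another seed, another sample
  expect_identical(neg, sample_negatives(background, 4, 50,
                                         positives, seed = 7))
  expect_false(identical(neg, sample_negatives(background, 4, 50,
                                               positives, seed = 8)))
  expect_error(sample_negatives("AXA", 4, 5),
               class = "ahtpep_error_insufficient_background")
})
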