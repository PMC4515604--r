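test_that("amino-acid composition matches hand counts and sums to 100", {
  aa <- encode_aac(c("AA", "GY", "PPG"))
  expect_equal(aa$aac_A[1], 100)
  expect_equal(sum(aa[1, feature_cols(aa)] != 0), 1)
  expect_equal(aa$aac_G[2], 50)
  expect_equal(aa$aac_Y[2], 50)
  expect_equal(aa$aac_P[3], 200 / 3, tolerance = 1e-9)
  expect_equal(aa$aac_G[3], 100 / 3, tolerance = 1e-9)
  expect_equal(feature_spec(aa)$family, "aac")

  rand <- encode_aac(random_peptides(60, seed = 9))
  expect_equal(rowSums(rand[feature_cols(rand)]), rep(100, 60),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("atomic composition sums residue counts and handles dehydration", {
  # GG raw counts are twice the glycine row; dehydration removes one water
  counts <- ahtpep:::atomic_counts("GG", "residue_sum")
  expect_equal(unname(counts[1, c("C", "H", "N", "O", "S")]),
               c(4, 10, 2, 4, 0))
  dehy <- ahtpep:::atomic_counts("GG", "dehydrated")
  expect_equal(unname(dehy[1, c("C", "H", "N", "O", "S")]), c(4, 8, 2, 3, 0))

  frac <- encode_atomic("GG")
  expect_equal(unname(unlist(frac[1, feature_cols(frac)])),
               c(0.20, 0.50, 0.10, 0.20, 0.0))

  seqs <- random_peptides(40, seed = 10)
  for (mode in c("residue_sum", "dehydrated")) {
    f <- encode_atomic(seqs, mode = mode)
    expect_equal(rowSums(f[paste0("atom_", c("C", "H", "N", "O", "S"))]),
                 rep(1, 40), tolerance = 1e-9, ignore_attr = TRUE)
  }
  # dehydrated total atoms = residue_sum total - 3 per peptide bond
  rs <- rowSums(ahtpep:::atomic_counts(seqs, "residue_sum")[, 1:5])
  dh <- rowSums(ahtpep:::atomic_counts(seqs, "dehydrated")[, 1:5])
  expect_equal(rs - dh, 3 * (nchar(seqs) - 1))
})

test_that("composition encoders are permutation-invariant", {
  a <- c("GYWF", "ILVK")
  b <- c("FWYG", "KVLI")  # anagrams
  expect_equal(encode_aac(a)[feature_cols(encode_aac(a))],
               encode_aac(b)[feature_cols(encode_aac(b))])
  expect_equal(encode_atomic(a)[-1], encode_atomic(b)[-1])
})

test_that("scale encoding pools positions and validates the matrix", {
  sm <- builtin_scale_matrix()
  expect_equal(nrow(sm), 20)
  # homopolymer mean equals the residue's own scale row
  enc <- encode_scales("AAAA", sm, pooling = "mean")
  expect_equal(unname(unlist(enc[1, feature_cols(enc)])),
               unname(unlist(sm[sm$residue == "A", -1])), tolerance = 1e-12)
  # midpoint property for a two-residue peptide
  gy <- encode_scales("GY", sm, pooling = "mean")
  expect_equal(unname(unlist(gy[1, feature_cols(gy)])),
               colMeans(as.matrix(sm[sm$residue %in% c("G", "Y"), -1])),
               ignore_attr = TRUE)
  # concat keeps sequence order
  cc <- encode_scales("GY", sm, pooling = "concat")
  k <- ncol(sm) - 1
  expect_equal(unname(unlist(cc[1, feature_cols(cc)])),
               c(unlist(sm[sm$residue == "G", -1]),
                 unlist(sm[sm$residue == "Y", -1])), ignore_attr = TRUE)
  expect_length(feature_cols(cc), 2 * k)
  expect_error(encode_scales(c("GY", "GYA"), sm, pooling = "concat"),
               class = "ahtpep_error_input")
  expect_error(encode_scales("GY", sm[-3, ]),
               class = "ahtpep_error_incomplete_scale_matrix")
})

test_that("descriptor tables are aligned, validated and row-ordered", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence,d1,d2", "GY,1.5,3", "AW,2.5,3", "PP,0.5,3"), path)
  tab <- load_descriptor_table(path, c("PP", "GY"))
  expect_equal(tab$sequence, c("PP", "GY"))
  expect_equal(tab$d1, c(0.5, 1.5))
  expect_equal(feature_cols(tab), c("d1", "d2"))  # constants retained
  expect_error(load_descriptor_table(path, c("GY", "KK")),
               class = "ahtpep_error_missing_peptide")
  writeLines(c("sequence,d1", "GY,NA"), path)
  expect_error(load_descriptor_table(path, "GY"),
               class = "ahtpep_error_non_numeric_cell")
})

test_that("physicochemical report implements the documented charge and mass model", {
  rep <- physicochemical_report(c("KK", "DD", "GG", "HH"))
  expect_equal(rep$length, c(2, 2, 2, 2))
  expect_equal(rep$net_charge, c(2, -2, 0, 0))
  # histidine charge is configurable
  rep_h <- physicochemical_report("HH", his_charge = 1)
  expect_equal(rep_h$net_charge, 2)
  # glycylglycine monoisotopic mass: 2 x glycine - water
  expect_equal(rep$mol_weight[3], 2 * 75.03203 - 18.01056, tolerance = 1e-4)
  expect_equal(rep$hydropathy[3], -0.4)
})
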