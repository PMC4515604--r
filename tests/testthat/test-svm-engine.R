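toy_classification <- function(n_per_class = 8, seed = 21) {
  with_seed_local(seed, {
    pos <- replicate(n_per_class,
                     paste(sample(c("P", "W", "Y"), 4, TRUE), collapse = ""))
    neg <- replicate(n_per_class,
                     paste(sample(c("G", "A", "S"), 4, TRUE), collapse = ""))
    tibble::tibble(sequence = c(pos, neg),
                   label = rep(c(1L, 0L), each = n_per_class))
  })
}

test_that("training contract: separable data fits, degenerate data errors", {
  d <- encode_aac(toy_classification())
  m <- aht_train(d, "label", hyper = list(cost = 10, gamma = 0.1))
  pr <- predict(m, d)
  expect_equal(pr$call, d$label)
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(glance(m)$task, "classification")

  only_pos <- dplyr::filter(d, label == 1) %>% dplyr::mutate(label = 1L)
  expect_error(aht_train(only_pos, "label", task = "classification"),
               class = "ahtpep_error_single_class")
  expect_error(aht_train(d[c(1:3, 9:11), ], "label"),
               class = "ahtpep_error_too_few_samples")
})

test_that("prediction re-encodes raw sequences via the stored feature spec", {
  d <- encode_aac(toy_classification())
  m <- aht_train(d, "label", hyper = list(cost = 10, gamma = 0.1))
  from_seq <- predict(m, c("PWYP", "GAGA"))
  from_feats <- predict(m, encode_aac(c("PWYP", "GAGA")))
  expect_equal(from_seq, from_feats)
})

test_that("LOOCV produces n held-out predictions, order-invariantly", {
  d <- encode_aac(toy_classification(6, seed = 22))
  ev <- aht_loocv(d, "label", hyper = list(cost = 1, gamma = 0.1))
  expect_equal(nrow(tidy(ev)), 12)
  shuffled <- d[with_seed_local(23, sample(nrow(d))), ]
  ev2 <- aht_loocv(shuffled, "label", hyper = list(cost = 1, gamma = 0.1))
  expect_equal(glance(ev)[c("sn", "sp", "acc", "mcc")],
               glance(ev2)[c("sn", "sp", "acc", "mcc")])
})

test_that("LOOCV equals a literal n-retrain oracle on small datasets", {
  # classification
  d <- encode_aac(toy_classification(7, seed = 24))
  hyper <- list(cost = 5, gamma = 0.2)
  ev <- aht_loocv(d, "label", hyper = hyper)
  oracle <- oracle_loocv(as.matrix(d[feature_cols(d)]), d$label,
                         "classification", hyper)
  expect_equal(tidy(ev)$score, oracle, tolerance = 1e-12)

  # regression
  r <- make_regression_set("dipeptide", 2, n = 12, seed = 25)
  fr <- encode_aac(r)
  hyper_r <- list(cost = 10, gamma = 0.05, epsilon = 0.1)
  evr <- aht_loocv(fr, "pic50", features = feature_cols(fr), hyper = hyper_r)
  oracle_r <- oracle_loocv(as.matrix(fr[feature_cols(fr)]), fr$pic50,
                           "regression", hyper_r)
  expect_equal(tidy(evr)$prediction, oracle_r, tolerance = 1e-12)
})

test_that("regression metrics match their definitions", {
  y <- c(1, 2, 3, 4)
  expect_equal(regression_metrics(y, y), tibble::tibble(r = 1, rmse = 0))
  expect_equal(regression_metrics(y, -y)$r, -1)
  expect_equal(regression_metrics(y, y + c(1, -1, 1, -1))$rmse, 1)
  expect_error(regression_metrics(rep(1, 4), y),
               class = "ahtpep_error_constant_truth")
})

test_that("classification metrics match hand values and behave under swaps", {
  perfect <- classification_metrics(5, 0, 5, 0)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$acc, 100)
  m <- classification_metrics(3, 1, 3, 1)
  expect_equal(m$mcc, 0.5)
  expect_equal(m$acc, 75)
  # independent predictions: tp=fp, tn=fn
  expect_equal(classification_metrics(2, 2, 2, 2)$mcc, 0)
  # swapping classes and predictions together leaves MCC invariant;
  # inverting predictions negates it
  set.seed(26)
  for (i in 1:20) {
    t <- sample(0:12, 4, replace = TRUE) + c(1, 0, 1, 0)  # both classes present
    a <- classification_metrics(t[1], t[2], t[3], t[4])
    swapped <- classification_metrics(t[3], t[4], t[1], t[2])
    inverted <- classification_metrics(t[4], t[3], t[2], t[1])
    expect_equal(a$mcc, swapped$mcc)
    expect_equal(a$mcc, -inverted$mcc)
    expect_gte(a$mcc, -1); expect_lte(a$mcc, 1)
  }
  expect_error(classification_metrics(0, 1, 1, 0),
               class = "ahtpep_error_no_positives")
})

test_that("threshold scan sweeps sensibly and reports optimal thresholds", {
  scores <- c(0.9, 0.8, 0.1, 0.2)
  labels <- c(1, 1, 0, 0)
  tab <- threshold_scan(scores, labels)
  at05 <- tab[which.min(abs(tab$threshold - 0.5)), ]
  expect_equal(at05$sn, 100); expect_equal(at05$sp, 100)
  expect_equal(at05$acc, 100)
  below <- tab[1, ]  # grid starts below all scores
  expect_equal(below$sn, 100); expect_equal(below$sp, 0)
  expect_true(0 %in% tab$threshold)

  # monotone sweep + accuracy identity on random score sets
  set.seed(27)
  for (i in 1:10) {
    s <- rnorm(30)
    l <- rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2) next
    tt <- threshold_scan(s, l)
    expect_true(all(diff(tt$sn) <= 1e-9))
    expect_true(all(diff(tt$sp) >= -1e-9))
    npos <- sum(l); nneg <- sum(1 - l)
    expect_equal(tt$acc, (tt$sn * npos + tt$sp * nneg) / (npos + nneg))
  }
})

test_that("grid-search tuning picks hyperparameters by LOOCV", {
  d <- encode_aac(toy_classification(6, seed = 28))
  m <- aht_train(d, "label", tune = TRUE,
                 grid = list(cost = c(1, 10), gamma = c(0.01, 0.1)))
  expect_true(m$hyper$cost %in% c(1, 10))
  expect_true(m$hyper$gamma %in% c(0.01, 0.1))
  # the deployed threshold is the Acc-maximizing LOOCV threshold
  expect_equal(m$threshold,
               attr(m$loocv$threshold_table, "best_acc_threshold"))
})

test_that("routing sends peptides to their category model", {
  tiny <- make_regression_set("dipeptide", 2, n = 20, seed = 29)
  medium <- make_classification_set("medium", "non_aht", 8, 15, seed = 30)
  m_tiny <- aht_train(encode_aac(tiny), "pic50", category = "tiny_di",
                      hyper = list(cost = 10, gamma = 0.05, epsilon = 0.1))
  m_med <- aht_train(encode_aac(medium), "label", category = "medium",
                     hyper = list(cost = 10, gamma = 0.05))
  bundle <- aht_bundle(m_tiny, m_med)
  out <- route_and_predict(c("GY", "PPWPAPLP"), bundle)
  expect_equal(out$category, c("tiny_di", "medium"))
  expect_false(is.na(out$pic50[1]))
  expect_true(is.na(out$pic50[2]))
  expect_false(is.na(out$score[2]))
  expect_equal(out$ic50_uM[1], pic50_to_ic50(out$pic50[1]))
  expect_error(route_and_predict("PPPP", bundle),
               class = "ahtpep_error_missing_model")
})
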