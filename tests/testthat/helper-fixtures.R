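# Shared fixtures and independent oracles used across test files.

# Atom/bond accounting of the 20 free amino acids as printed in the
# standard reference table; frozen here as the expected values the packaged
# molecular graphs must reproduce.
REFERENCE_ATOM_TABLE <- tibble::tribble(
  ~residue, ~C, ~H, ~N, ~O, ~S, ~total_bonds, ~single_bonds, ~double_bonds,
  "A", 3, 7, 1, 2, 0, 12, 11, 1,
  "C", 3, 7, 1, 2, 1, 13, 12, 1,
  "D", 4, 7, 1, 4, 0, 15, 13, 2,
  "E", 5, 9, 1, 4, 0, 18, 16, 2,
  "F", 9, 11, 1, 2, 0, 23, 19, 4,
  "G", 2, 5, 1, 2, 0, 9, 8, 1,
  "H", 6, 9, 3, 2, 0, 20, 17, 3,
  "I", 6, 13, 1, 2, 0, 21, 20, 1,
  "K", 6, 14, 2, 2, 0, 23, 22, 1,
  "L", 6, 13, 1, 2, 0, 21, 20, 1,
  "M", 5, 11, 1, 2, 1, 19, 18, 1,
  "N", 4, 8, 2, 3, 0, 16, 14, 2,
  "P", 5, 9, 1, 2, 0, 17, 16, 1,
  "Q", 5, 10, 2, 3, 0, 19, 17, 2,
  "R", 6, 14, 4, 2, 0, 25, 23, 2,
  "S", 3, 7, 1, 3, 0, 13, 12, 1,
  "T", 4, 9, 1, 3, 0, 16, 15, 1,
  "V", 5, 11, 1, 2, 0, 18, 17, 1,
  "W", 11, 12, 2, 2, 0, 28, 23, 5,
  "Y", 9, 11, 1, 3, 0, 24, 20, 4
)

# ring counts of the free amino acids (imidazole, benzene, indole = 2 fused)
RESIDUE_RINGS <- c(A = 0, C = 0, D = 0, E = 0, F = 1, G = 0, H = 1, I = 0,
                   K = 0, L = 0, M = 0, N = 0, P = 1, Q = 0, R = 0, S = 0,
                   T = 0, V = 0, W = 2, Y = 1)

# Independent classification-metric oracle: expand a contingency table into
# explicit truth/prediction vectors and compute everything from first
# principles (MCC as the Pearson correlation of the two binary vectors).
oracle_classification_metrics <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(1, fn), rep(0, tn), rep(0, fp))
  pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  mcc <- suppressWarnings(stats::cor(truth, pred))
  if (is.na(mcc)) mcc <- 0
  list(sn = 100 * mean(pred[truth == 1] == 1),
       sp = 100 * mean(pred[truth == 0] == 0),
       acc = 100 * mean(truth == pred),
       mcc = mcc)
}

# Literal n-retrain LOOCV oracle, written independently of aht_loocv():
# its own fold loop, its own scaling, direct e1071 calls.
oracle_loocv <- function(X, y, task, hyper) {
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    mu <- colMeans(tr)
    sdv <- apply(tr, 2, sd)
    sdv[sdv == 0] <- 1
    trs <- sweep(sweep(tr, 2, mu), 2, sdv, "/")
    tes <- sweep(sweep(X[i, , drop = FALSE], 2, mu), 2, sdv, "/")
    if (task == "regression") {
      fit <- e1071::svm(trs, y[-i], type = "eps-regression", kernel = "radial",
                        cost = hyper$cost, gamma = hyper$gamma,
                        epsilon = hyper$epsilon, scale = FALSE)
      out[i] <- as.numeric(predict(fit, tes))
    } else {
      fit <- e1071::svm(trs, factor(y[-i], levels = c(0, 1)),
                        type = "C-classification", kernel = "radial",
                        cost = hyper$cost, gamma = hyper$gamma, scale = FALSE)
      pr <- predict(fit, tes, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      out[i] <- if (colnames(dv)[1] == "0/1") -as.numeric(dv) else as.numeric(dv)
    }
  }
  out
}

# exhaustive CFS best-subset oracle for small feature counts
oracle_best_subset_merit <- function(X, y, features) {
  k <- length(features)
  best <- -Inf
  for (m in seq_len(2^k - 1)) {
    s <- features[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
    best <- max(best, cfs_merit(X, y, s))
  }
  best
}

random_peptides <- function(n, lengths = 2:12, seed = 1) {
  with_seed_local(seed, {
    vapply(sample(lengths, n, replace = TRUE), function(L) {
      paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                     "R","S","T","V","W","Y"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
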