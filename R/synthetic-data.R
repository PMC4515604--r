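# Synthetic datasets with the statistical structure the models assume:
# composition-biased positives per length class, background-like negatives,
# and pIC50 values from a planted linear model on encodable features. These
# stand in for the curated activity databases so the whole pipeline is
# testable offline.

# Percent amino-acid composition of antihypertensive peptides by length
# class, and of background (Swiss-Prot-like) peptides. Columns sum to ~100
# up to printed rounding; composition_profile() renormalizes exactly.
TABLE2_COMPOSITION <- tibble::tribble(
  ~residue, ~dipeptide, ~tripeptide, ~small, ~medium, ~large, ~non_aht,
  "A", 8.02, 7.64, 6.61, 5.33, 3.46, 8.26,
  "C", 0.38, 0.33, 1.09, 0.48, 0.21, 1.37,
  "D", 3.44, 0.65, 2.24, 2.29, 2.87, 5.46,
  "E", 2.67, 1.46, 4.01, 4.72, 6.27, 6.74,
  "F", 8.02, 6.67, 3.87, 5.41, 6.41, 3.86,
  "G", 13.74, 6.99, 5.83, 6.49, 6.72, 7.08,
  "H", 2.67, 2.11, 3.41, 2.51, 2.49, 2.27,
  "I", 3.05, 7.32, 5.48, 4.97, 5.12, 5.94,
  "K", 5.73, 6.02, 5.47, 5.55, 4.61, 5.83,
  "L", 5.73, 9.76, 9.80, 8.45, 8.73, 9.66,
  "M", 3.44, 1.79, 1.41, 1.75, 1.26, 2.41,
  "N", 2.67, 1.95, 2.66, 3.42, 3.36, 4.05,
  "P", 6.87, 15.45, 14.93, 16.76, 16.50, 4.71,
  "Q", 1.91, 2.11, 5.73, 5.52, 6.38, 3.93,
  "R", 6.11, 4.72, 4.62, 3.67, 2.80, 5.53,
  "S", 2.67, 1.79, 3.20, 3.44, 5.75, 6.58,
  "T", 2.29, 2.93, 3.55, 3.73, 5.52, 5.34,
  "V", 4.20, 8.13, 7.19, 8.99, 7.75, 6.87,
  "W", 7.63, 3.74, 2.31, 1.43, 0.55, 1.09,
  "Y", 8.78, 8.46, 6.58, 5.11, 3.26, 2.92
)

#' Built-in residue composition profiles
#'
#' Percent amino-acid composition of antihypertensive peptides by length
#' class (dipeptide, tripeptide, small, medium, large) and of background
#' non-AHT peptides. The AHT classes are strongly proline-enriched (and,
#' for dipeptides, Trp/Tyr-enriched) relative to background -- the bias
#' the composition-based classifiers exploit.
#'
#' @return `builtin_profiles()`: a 20-row tibble of percent compositions.
#' @export
builtin_profiles <- function() TABLE2_COMPOSITION

#' @rdname builtin_profiles
#' @param id One of `"dipeptide"`, `"tripeptide"`, `"small"`, `"medium"`,
#'   `"large"`, `"non_aht"`.
#' @return `composition_profile()`: a named 20-vector of probabilities
#'   summing to 1 (printed percentages renormalized to remove rounding
#'   error).
#' @export
composition_profile <- function(id) {
  id <- match.arg(id, setdiff(names(TABLE2_COMPOSITION), "residue"))
  p <- TABLE2_COMPOSITION[[id]]
  names(p) <- TABLE2_COMPOSITION$residue
  p / sum(p)
}

check_profile <- function(profile) {
  if (is.character(profile) && length(profile) == 1) {
    profile <- composition_profile(profile)
  }
  stopifnot(is.numeric(profile), setequal(names(profile), AMINO_ACIDS),
            all(profile >= 0), abs(sum(profile) - 1) < 1e-9)
  profile[AMINO_ACIDS]
}

#' Sample peptides from a residue composition profile
#'
#' Residues are drawn i.i.d. from the profile -- positional structure is
#' deliberately absent, matching what composition-based encoders can see.
#'
#' @param profile Named probability vector over the 20 amino acids (sums to
#'   1), or a profile id accepted by [composition_profile()].
#' @param length Peptide length (>= 2).
#' @param n Number of peptides.
#' @param seed Integer seed; same seed, same peptides.
#' @return Character vector of n sequences.
#' @examples
#' sample_peptides("medium", length = 8, n = 3, seed = 1)
#' @export
sample_peptides <- function(profile, length, n, seed = 1L) {
  profile <- check_profile(profile)
  stopifnot(length >= 2, n >= 1)
  with_seed(seed, {
    m <- matrix(sample(AMINO_ACIDS, n * length, replace = TRUE, prob = profile),
                nrow = n)
    apply(m, 1, paste, collapse = "")
  })
}

#' Build a balanced classification dataset
#'
#' Samples `n_per_class` positives and negatives from two composition
#' profiles at a fixed 1:1 class ratio (the convention for sequence-based
#' binary models). Sequences colliding across classes are resampled so the
#' two classes are disjoint as sets.
#'
#' @param pos_profile,neg_profile Profiles (vectors or ids) for the
#'   positive and negative class.
#' @param length Peptide length.
#' @param n_per_class Examples per class.
#' @param seed Integer seed.
#' @return A tibble with `id`, `sequence`, `label` (1 = AHT positive).
#' @export
make_classification_set <- function(pos_profile, neg_profile, length,
                                    n_per_class, seed = 1L) {
  pos_profile <- check_profile(pos_profile)
  neg_profile <- check_profile(neg_profile)
  pos <- sample_peptides(pos_profile, length, n_per_class, seed)
  neg <- sample_peptides(neg_profile, length, n_per_class, seed + 1L)
  tries <- 0
  while (any(neg %in% pos) && tries < 100) {
    clash <- which(neg %in% pos)
    neg[clash] <- sample_peptides(neg_profile, length, length(clash),
                                  seed + 2L + tries)
    tries <- tries + 1
  }
  if (any(neg %in% pos)) {
    abort("Could not make classes disjoint; profiles too degenerate.",
          class = "ahtpep_error_input")
  }
  tibble::tibble(
    id = sprintf("s%d", seq_len(2 * n_per_class)),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), each = n_per_class)
  )
}

#' Define a planted linear activity model
#'
#' @param weights Named numeric vector over feature names (e.g. `aac_P`).
#' @param intercept Baseline pIC50.
#' @param sigma Standard deviation of the Gaussian noise added to pIC50.
#' @return A `planted_model` list.
#' @export
planted_model <- function(weights, intercept = 4, sigma = 0.1) {
  stopifnot(is.numeric(weights), !is.null(names(weights)), sigma >= 0)
  structure(list(weights = weights, intercept = intercept, sigma = sigma),
            class = "ahtpep_planted_model")
}

default_planted_model <- function() {
  # hydrophobic/aromatic-favoring linear activity on amino-acid composition
  # (percent units, hence small weights)
  planted_model(
    weights = c(aac_W = 0.03, aac_Y = 0.025, aac_P = 0.02, aac_F = 0.015,
                aac_E = -0.02, aac_D = -0.015),
    intercept = 4, sigma = 0.1
  )
}

#' Build a regression dataset from a planted linear model
#'
#' Samples tiny peptides from a composition profile and assigns
#' `pIC50 = w . features + intercept + N(0, sigma)`, with features encoded
#' by amino-acid composition; the corresponding IC50 in micromolar is
#' back-computed. This emulates the structure of a di/tripeptide activity
#' dataset with a known ground-truth signal, so recovery can be asserted.
#'
#' @param profile Profile (vector or id) to sample sequences from.
#' @param length Peptide length, 2 or 3.
#' @param n Number of peptides.
#' @param planted A [planted_model()] (default: a documented
#'   hydrophobic/aromatic-favoring model on AAC features).
#' @param seed Integer seed.
#' @return A tibble with `id`, `sequence`, `pic50`, `ic50_uM` and attribute
#'   `planted` (the generating model).
#' @export
make_regression_set <- function(profile, length = 2, n = 150,
                                planted = default_planted_model(),
                                seed = 1L) {
  stopifnot(length %in% c(2, 3), inherits(planted, "ahtpep_planted_model"))
  seqs <- sample_peptides(check_profile(profile), length, n, seed)
  feats <- encode_aac(seqs)
  missing <- setdiff(names(planted$weights), names(feats))
  if (length(missing) > 0) {
    abort(sprintf("Planted weights reference unknown feature(s): %s",
                  paste(missing, collapse = ", ")), class = "ahtpep_error_input")
  }
  signal <- as.numeric(as.matrix(feats[names(planted$weights)]) %*%
                         planted$weights) + planted$intercept
  noise <- with_seed(seed + 1L, stats::rnorm(n, 0, planted$sigma))
  pic50 <- signal + noise
  out <- tibble::tibble(
    id = sprintf("r%d", seq_len(n)),
    sequence = seqs,
    pic50 = pic50,
    ic50_uM = pic50_to_ic50(pic50)
  )
  attr(out, "planted") <- planted
  out
}
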