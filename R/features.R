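# Peptide feature encoders: amino-acid composition, atomic composition,
# scale-based descriptors, and ingestion of externally computed descriptor
# tables. Every encoder is a pure function of (feature spec, sequence), takes
# a data frame (or character vector) first and returns a tibble whose
# non-sequence columns are the feature matrix; the spec used is attached as
# the "feature_spec" attribute so trained models can refuse mismatched input.

as_sequence_tbl <- function(data) {
  if (is.character(data)) data <- tibble::tibble(sequence = data)
  stopifnot(is.data.frame(data), "sequence" %in% names(data))
  bad <- data$sequence[!grepl(sprintf("^[%s]{2,}$", paste(AMINO_ACIDS, collapse = "")),
                              data$sequence)]
  if (length(bad) > 0) {
    abort(sprintf("Invalid peptide sequence(s): %s. Run validate_peptides() first.",
                  paste(utils::head(bad, 3), collapse = ", ")),
          class = "ahtpep_error_input")
  }
  tibble::as_tibble(data)
}

new_feature_spec <- function(family, names, params = list()) {
  stopifnot(!anyDuplicated(names))
  structure(list(family = family, names = names, params = params),
            class = "ahtpep_feature_spec")
}

#' @export
print.ahtpep_feature_spec <- function(x, ...) {
  cat(sprintf("<feature spec: %s, %d features>\n", x$family, length(x$names)))
  invisible(x)
}

#' Retrieve the feature spec and feature columns of an encoded tibble
#' @param x A tibble returned by one of the `encode_*()` functions.
#' @return `feature_spec()`: the spec; `feature_cols()`: feature column names.
#' @export
feature_spec <- function(x) attr(x, "feature_spec", exact = TRUE)

#' @rdname feature_spec
#' @export
feature_cols <- function(x) feature_spec(x)$names

set_spec <- function(tbl, spec) {
  attr(tbl, "feature_spec") <- spec
  tbl
}

#' Amino-acid composition (percent)
#'
#' The classic 20-vector: component *i* is 100 times the count of amino
#' acid *i* divided by peptide length, so every row sums to 100.
#'
#' @param data Data frame with a `sequence` column, or a character vector.
#' @return The input tibble extended with columns `aac_A` ... `aac_Y`.
#' @examples
#' encode_aac(c("GY", "PPG"))
#' @export
encode_aac <- function(data) {
  data <- as_sequence_tbl(data)
  counts <- t(vapply(
    split_residues(data$sequence),
    function(ch) tabulate(factor(ch, levels = AMINO_ACIDS), nbins = 20L),
    integer(20)
  ))
  pct <- 100 * counts / nchar(data$sequence)
  colnames(pct) <- paste0("aac_", AMINO_ACIDS)
  out <- dplyr::bind_cols(data, tibble::as_tibble(pct))
  set_spec(out, new_feature_spec("aac", colnames(pct)))
}

atomic_counts <- function(sequence, mode = c("residue_sum", "dehydrated")) {
  mode <- match.arg(mode)
  tab <- residue_atom_table()
  m <- as.matrix(tab[, c("C", "H", "N", "O", "S",
                         "total_bonds", "single_bonds", "double_bonds")])
  rownames(m) <- tab$residue
  counts <- t(vapply(
    split_residues(sequence),
    function(ch) colSums(m[ch, , drop = FALSE]),
    numeric(8)
  ))
  if (mode == "dehydrated") {
    # peptide-bond formation releases one water per bond
    nb <- nchar(sequence) - 1
    counts[, "H"] <- counts[, "H"] - 2 * nb
    counts[, "O"] <- counts[, "O"] - nb
  }
  counts
}

#' Atomic composition features
#'
#' Sums the C/H/N/O/S atom counts of the constituent residues (free
#' amino-acid counts from the packaged molecular graphs) and reports each
#' element's fraction of the total atom count, so peptides of different
#' lengths are comparable. `mode = "dehydrated"` removes one water
#' (2 H + 1 O) per peptide bond before computing fractions;
#' `"residue_sum"` (the default) does not. With `include_bonds = TRUE`
#' the per-residue-summed total/single/double bond counts are appended as
#' bond-type fractions.
#'
#' @param data Data frame with a `sequence` column, or a character vector.
#' @param mode `"residue_sum"` (default) or `"dehydrated"`.
#' @param include_bonds Append bond-type fractions (default `FALSE`).
#' @return The input tibble extended with `atom_C` ... `atom_S` (and
#'   optionally `bond_total_per_atom`, `bond_single_frac`, `bond_double_frac`).
#' @examples
#' encode_atomic("GG")
#' @export
encode_atomic <- function(data, mode = c("residue_sum", "dehydrated"),
                          include_bonds = FALSE) {
  mode <- match.arg(mode)
  data <- as_sequence_tbl(data)
  counts <- atomic_counts(data$sequence, mode)
  atoms <- counts[, c("C", "H", "N", "O", "S"), drop = FALSE]
  total <- rowSums(atoms)
  frac <- atoms / total
  colnames(frac) <- paste0("atom_", colnames(atoms))
  out <- tibble::as_tibble(frac)
  if (include_bonds) {
    out$bond_total_per_atom <- counts[, "total_bonds"] / total
    out$bond_single_frac <- counts[, "single_bonds"] / counts[, "total_bonds"]
    out$bond_double_frac <- counts[, "double_bonds"] / counts[, "total_bonds"]
  }
  res <- dplyr::bind_cols(data, out)
  set_spec(res, new_feature_spec("atomic", names(out),
                                 params = list(mode = mode,
                                               include_bonds = include_bonds)))
}

# Kyte-Doolittle hydropathy index (standard published scale)
KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                   H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                   P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
                   W = -0.9, Y = -1.3)

#' Built-in amino-acid scale matrix (synthetic placeholder)
#'
#' An eight-column scale matrix assembled from properties the package
#' computes itself: Kyte-Doolittle hydropathy, monoisotopic residue mass,
#' side-chain charge at pH 7, aromaticity, and the C/N/O/S atom fractions,
#' each standardized to zero mean and unit variance over the 20 residues.
#' It is a synthetic stand-in with the same shape as published
#' multivariate amino-acid scale sets (z-scales, G-scales, ...); no
#' numerical equivalence to any published scale set is claimed, and any
#' user matrix in the same format (a `residue` column plus k numeric
#' columns) can be used instead.
#'
#' @return A 20-row tibble: `residue` plus eight standardized scale columns.
#' @export
builtin_scale_matrix <- function() {
  tab <- residue_atom_table()
  atoms <- as.matrix(tab[, c("C", "H", "N", "O", "S")])
  raw <- cbind(
    hydropathy = unname(KD_HYDROPATHY[tab$residue]),
    mass = as.numeric(atoms %*% ELEMENT_MASS),
    charge = ifelse(tab$residue %in% c("K", "R"), 1,
                    ifelse(tab$residue %in% c("D", "E"), -1, 0)),
    aromatic = as.numeric(tab$residue %in% c("F", "H", "W", "Y")),
    frac_C = atoms[, "C"] / rowSums(atoms),
    frac_N = atoms[, "N"] / rowSums(atoms),
    frac_O = atoms[, "O"] / rowSums(atoms),
    frac_S = atoms[, "S"] / rowSums(atoms)
  )
  scaled <- scale(raw)
  out <- tibble::as_tibble(as.data.frame(scaled))
  dplyr::bind_cols(tibble::tibble(residue = tab$residue), out)
}

check_scale_matrix <- function(scales) {
  stopifnot(is.data.frame(scales), "residue" %in% names(scales))
  missing <- setdiff(AMINO_ACIDS, scales$residue)
  if (length(missing) > 0) {
    abort(sprintf("Scale matrix is missing residue(s): %s",
                  paste(missing, collapse = ", ")),
          class = "ahtpep_error_incomplete_scale_matrix")
  }
  cols <- setdiff(names(scales), "residue")
  if (length(cols) == 0 || !all(vapply(scales[cols], is.numeric, logical(1)))) {
    abort("Scale matrix needs at least one numeric scale column.",
          class = "ahtpep_error_incomplete_scale_matrix")
  }
  scales
}

#' Scale-based peptide descriptors
#'
#' Maps each position of the peptide to its residue's row of a k-column
#' amino-acid scale matrix. `pooling = "mean"` averages over positions,
#' giving a length-independent k-vector; `pooling = "concat"` concatenates
#' the per-position rows in sequence order (all peptides in `data` must
#' then share one length, as in the fixed-length di/tri/tetra... models).
#'
#' @param data Data frame with a `sequence` column, or a character vector.
#' @param scales Scale matrix: `residue` column plus k numeric columns
#'   (default [builtin_scale_matrix()]).
#' @param pooling `"mean"` or `"concat"`.
#' @return The input tibble extended with the scale feature columns.
#' @examples
#' encode_scales("GY", pooling = "concat")
#' @export
encode_scales <- function(data, scales = builtin_scale_matrix(),
                          pooling = c("mean", "concat")) {
  pooling <- match.arg(pooling)
  data <- as_sequence_tbl(data)
  scales <- check_scale_matrix(scales)
  cols <- setdiff(names(scales), "residue")
  m <- as.matrix(scales[cols])
  rownames(m) <- scales$residue
  if (pooling == "mean") {
    vals <- t(vapply(split_residues(data$sequence),
                     function(ch) colMeans(m[ch, , drop = FALSE]),
                     numeric(length(cols))))
    colnames(vals) <- paste0("scale_", cols)
  } else {
    lens <- unique(nchar(data$sequence))
    if (length(lens) != 1) {
      abort("concat pooling requires all peptides to have the same length.",
            class = "ahtpep_error_input")
    }
    vals <- t(vapply(split_residues(data$sequence),
                     function(ch) as.numeric(t(m[ch, , drop = FALSE])),
                     numeric(lens * length(cols))))
    colnames(vals) <- paste0("scale_p", rep(seq_len(lens), each = length(cols)),
                             "_", rep(cols, lens))
  }
  out <- dplyr::bind_cols(data, tibble::as_tibble(vals))
  set_spec(out, new_feature_spec("scales", colnames(vals),
                                 params = list(pooling = pooling,
                                               k = length(cols))))
}

#' Load an externally computed descriptor table
#'
#' Reads a CSV keyed by a `sequence` column (e.g. PaDEL output exported per
#' peptide) and aligns its rows to the requested peptides, preserving the
#' table's column order. Constant columns are kept -- filtering is the job
#' of the selection pipeline. Missing peptides and non-numeric cells are
#' hard errors with coordinates, never silent.
#'
#' @param path CSV file with a `sequence` column and numeric descriptor columns.
#' @param peptides Character vector of sequences (or data frame with a
#'   `sequence` column) to align to.
#' @return A tibble: `sequence` plus the descriptor columns, one row per
#'   requested peptide in the requested order.
#' @export
load_descriptor_table <- function(path, peptides) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(sequence = readr::col_character(),
                                                 .default = readr::col_character()))
  if (!"sequence" %in% names(tab)) {
    abort("Descriptor table must have a 'sequence' column.",
          class = "ahtpep_error_input")
  }
  missing <- setdiff(peptides, tab$sequence)
  if (length(missing) > 0) {
    abort(sprintf("Descriptor table is missing peptide(s): %s",
                  paste(utils::head(missing, 5), collapse = ", ")),
          class = "ahtpep_error_missing_peptide")
  }
  cols <- setdiff(names(tab), "sequence")
  for (cl in cols) {
    parsed <- suppressWarnings(as.numeric(tab[[cl]]))
    bad <- which(is.na(parsed) & !is.na(tab[[cl]]) | is.na(tab[[cl]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric cell at row %d, column '%s': '%s'",
                    bad[1], cl, tab[[cl]][bad[1]]),
            class = "ahtpep_error_non_numeric_cell")
    }
    tab[[cl]] <- parsed
  }
  out <- tab[match(peptides, tab$sequence), , drop = FALSE]
  out <- tibble::as_tibble(out)
  set_spec(out, new_feature_spec("external", cols,
                                 params = list(source = as.character(path))))
}

#' Physicochemical property report
#'
#' The per-peptide property panel shown alongside predictions: length,
#' molecular weight (monoisotopic, residue masses minus one water per
#' peptide bond), integer net charge at pH 7 (+1 per K/R, -1 per D/E,
#' histidine neutral by default, +1 N-terminus, -1 C-terminus), mean
#' Kyte-Doolittle hydropathy, and the C/H/N/O/S atom fractions.
#'
#' @param data Data frame with a `sequence` column, or a character vector.
#' @param his_charge Charge assigned to each histidine (default 0).
#' @return The input tibble extended with `length`, `mol_weight`,
#'   `net_charge`, `hydropathy`, `atom_C` ... `atom_S`.
#' @examples
#' physicochemical_report(c("KK", "DD", "GG"))
#' @export
physicochemical_report <- function(data, his_charge = 0) {
  data <- as_sequence_tbl(data)
  residues <- split_residues(data$sequence)
  len <- nchar(data$sequence)
  mw <- vapply(residues, function(ch) sum(residue_mass(ch)), numeric(1)) -
    (len - 1) * WATER_MASS
  charge <- vapply(residues, function(ch) {
    sum(ch %in% c("K", "R")) - sum(ch %in% c("D", "E")) +
      his_charge * sum(ch == "H")
  }, numeric(1)) + 1 - 1  # +1 N-terminus, -1 C-terminus
  hyd <- vapply(residues, function(ch) mean(KD_HYDROPATHY[ch]), numeric(1))
  frac <- encode_atomic(data$sequence)
  out <- dplyr::bind_cols(
    data,
    tibble::tibble(length = len, mol_weight = mw, net_charge = charge,
                   hydropathy = hyd),
    frac[, paste0("atom_", c("C", "H", "N", "O", "S"))]
  )
  tibble::as_tibble(out)
}
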