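#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data := %||%
#' @importFrom dplyr %>%
NULL

# 20 natural amino acids, alphabetical one-letter codes
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate a single peptide sequence
#'
#' A valid peptide is at least two residues long and uses only the 20
#' natural amino acids (case-insensitive on input, uppercased on return).
#' Peptides with non-natural residues (X, B, Z, U, gaps, ...) are rejected,
#' as are single residues: the shortest peptides with reported
#' antihypertensive activity are dipeptides.
#'
#' @param raw A single character string.
#' @return The validated, uppercased sequence.
#' @examples
#' validate_peptide("gy")
#' @export
validate_peptide <- function(raw) {
  if (!is.character(raw) || length(raw) != 1 || is.na(raw) || !nzchar(raw)) {
    abort("`raw` must be a single non-empty string.", class = "ahtpep_error_input")
  }
  seq <- toupper(raw)
  if (nchar(seq) < 2) {
    abort(
      sprintf("Peptide '%s' is too short: length must be >= 2.", seq),
      class = "ahtpep_error_too_short"
    )
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AMINO_ACIDS)
  if (length(bad) > 0) {
    abort(
      sprintf(
        "Non-natural residue '%s' at position %d in '%s'.",
        chars[bad[1]], bad[1], seq
      ),
      class = "ahtpep_error_non_natural"
    )
  }
  seq
}

#' Validate a batch of peptides, collecting per-record errors
#'
#' Takes a data frame with a `sequence` column (or a bare character vector)
#' and returns one row per input record with the uppercased sequence, its
#' length, length category and model task. Invalid records are never dropped
#' silently: they are returned with `valid = FALSE` and the error message.
#'
#' @param data A data frame with a `sequence` column, or a character vector.
#' @param keep_invalid Keep invalid rows (default) or drop them with a warning.
#' @return A tibble with columns `id`, `sequence`, `valid`, `error`,
#'   `length`, `category`, `task`.
#' @examples
#' validate_peptides(c("GY", "AXA", "P"))
#' @export
validate_peptides <- function(data, keep_invalid = TRUE) {
  if (is.character(data)) {
    data <- tibble::tibble(sequence = data)
  }
  stopifnot(is.data.frame(data), "sequence" %in% names(data))
  if (!"id" %in% names(data)) {
    data$id <- sprintf("pep%d", seq_len(nrow(data)))
  }
  checked <- purrr::map(data$sequence, function(s) {
    tryCatch(
      list(sequence = validate_peptide(s), error = NA_character_),
      error = function(e) list(sequence = toupper(as.character(s)),
                               error = conditionMessage(e))
    )
  })
  out <- tibble::tibble(
    id = as.character(data$id),
    sequence = purrr::map_chr(checked, "sequence"),
    valid = purrr::map_lgl(checked, ~ is.na(.x$error)),
    error = purrr::map_chr(checked, "error")
  )
  out$length <- ifelse(out$valid, nchar(out$sequence), NA_integer_)
  out$category <- ifelse(out$valid, as.character(categorize_length(out$length)),
                         NA_character_)
  out$task <- ifelse(out$valid, category_task(out$category), NA_character_)
  if (!keep_invalid && any(!out$valid)) {
    warn(sprintf("Dropping %d invalid peptide record(s).", sum(!out$valid)))
    out <- dplyr::filter(out, .data$valid)
  }
  out
}

#' Length categories and their prediction task
#'
#' Peptides are stratified by length into seven categories, each served by
#' its own model: dipeptides (`tiny_di`) and tripeptides (`tiny_tri`) get
#' pIC50 regression; tetra/penta/hexapeptides (`small_*`), 7--12-mers
#' (`medium`) and everything longer (`large`) get binary classification.
#' The partition is total over lengths >= 2 with no upper bound.
#'
#' @param length Integer vector of peptide lengths (each >= 2).
#' @return Character vector of category names.
#' @examples
#' categorize_length(c(2, 5, 9, 20))
#' @export
categorize_length <- function(length) {
  length <- as.integer(length)
  if (any(!is.na(length) & length < 2)) {
    abort("Peptide lengths must be >= 2.", class = "ahtpep_error_too_short")
  }
  dplyr::case_when(
    length == 2 ~ "tiny_di",
    length == 3 ~ "tiny_tri",
    length == 4 ~ "small_tetra",
    length == 5 ~ "small_penta",
    length == 6 ~ "small_hexa",
    length <= 12 ~ "medium",
    length > 12 ~ "large"
  )
}

#' @rdname categorize_length
#' @param category Character vector of category names.
#' @export
category_task <- function(category) {
  ifelse(category %in% c("tiny_di", "tiny_tri"), "regression", "classification")
}

#' All supported length category names
#' @return Character vector of the seven category names in length order.
#' @export
length_categories <- function() {
  c("tiny_di", "tiny_tri", "small_tetra", "small_penta", "small_hexa",
    "medium", "large")
}

#' Convert IC50 (in micromolar) to pIC50 and back
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50; with IC50
#' expressed in micromolar this is `6 - log10(IC50_uM)`. The conversion
#' compresses the wide span of reported activities (fractions of a
#' micromolar up to tens of millimolar) onto a scale suitable for
#' regression.
#'
#' @param ic50_uM Positive numeric vector, IC50 in micromolar.
#' @return Numeric vector of pIC50 values (dimensionless).
#' @examples
#' to_pic50(1)      # 6
#' to_pic50(0.04)   # 7.398
#' pic50_to_ic50(6) # 1
#' @export
to_pic50 <- function(ic50_uM) {
  if (!is.numeric(ic50_uM) || any(is.na(ic50_uM)) || any(ic50_uM <= 0)) {
    abort("IC50 values must be positive (micromolar).",
          class = "ahtpep_error_non_positive_activity")
  }
  6 - log10(ic50_uM)
}

#' @rdname to_pic50
#' @param pic50 Numeric vector of pIC50 values.
#' @export
pic50_to_ic50 <- function(pic50) {
  10^(6 - pic50)
}

split_residues <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)
}
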