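# File-format plumbing: FASTA in/out (via Biostrings), the CSV dataset
# dialect (header row; `sequence,label` with label 1/0, or
# `sequence,ic50_uM` in micromolar), and report writing with embedded
# provenance.

#' Read a FASTA file
#'
#' Accepts wrapped or single-line records; the record id is the header up
#' to the first whitespace; sequence lines are concatenated and uppercased
#' on ingest.
#'
#' @param path FASTA file.
#' @return A tibble with `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_fasta() needs the Biostrings package.")
  }
  first <- readLines(path, n = 1)
  if (length(first) > 0 && !startsWith(first, ">")) {
    abort(sprintf("Malformed FASTA: '%s' does not start with a '>' header.", path),
          class = "ahtpep_error_malformed_fasta")
  }
  ss <- Biostrings::readBStringSet(path)
  tibble::tibble(
    id = unname(sub("\\s.*$", "", names(ss))),
    sequence = unname(toupper(as.character(ss)))
  )
}

#' Write sequences to FASTA
#'
#' @param data Data frame with `id` and `sequence` columns.
#' @param path Output file.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(data)))
  lines <- unlist(purrr::map2(data$id, data$sequence, function(id, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a peptide dataset CSV
#'
#' The dataset dialect is a header row plus either `sequence,label`
#' (label 1/0) or `sequence,ic50_uM` (positive, micromolar; a `pic50`
#' column is derived on read). Duplicate sequences keep their first
#' occurrence; later occurrences are dropped with a warning naming them,
#' since the source databases do not state how conflicting activity
#' records were merged.
#'
#' @param path CSV file.
#' @return A tibble with `id`, `sequence` and `label` or
#'   `ic50_uM` + `pic50`.
#' @export
read_peptide_dataset <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (!"sequence" %in% names(tab)) {
    abort(sprintf("Dataset '%s' lacks a 'sequence' column.", path),
          class = "ahtpep_error_input")
  }
  tab$sequence <- toupper(tab$sequence)
  dup <- duplicated(tab$sequence)
  if (any(dup)) {
    warn(sprintf("Dropping %d duplicate sequence record(s): %s", sum(dup),
                 paste(utils::head(unique(tab$sequence[dup]), 5), collapse = ", ")))
    tab <- tab[!dup, , drop = FALSE]
  }
  if (!"id" %in% names(tab)) tab$id <- sprintf("pep%d", seq_len(nrow(tab)))
  if ("label" %in% names(tab)) {
    if (!all(tab$label %in% c(0, 1))) {
      abort("Labels must be 0 or 1.", class = "ahtpep_error_input")
    }
    tab$label <- as.integer(tab$label)
  } else if ("ic50_uM" %in% names(tab)) {
    tab$pic50 <- to_pic50(tab$ic50_uM)
  } else {
    abort("Dataset needs a 'label' or 'ic50_uM' column.",
          class = "ahtpep_error_input")
  }
  tibble::as_tibble(tab)
}

#' Write a report table with embedded provenance
#'
#' Writes a CSV preceded by `#`-prefixed header lines recording the
#' package version and any provenance the caller supplies (seed, config,
#' dataset hash), so every artifact records how it was produced. Files
#' written this way round-trip through [readr::read_csv()] with
#' `comment = "#"` (and through [read_peptide_dataset()]).
#'
#' @param data Data frame to write.
#' @param path Output file.
#' @param meta Named list of provenance fields.
#' @return `path`, invisibly.
#' @export
write_report <- function(data, path, meta = list()) {
  meta <- c(list(generator = paste0("ahtpep ",
                                    as.character(utils::packageVersion("ahtpep")))),
            meta)
  header <- sprintf("# %s: %s", names(meta),
                    vapply(meta, function(v) paste(format(v), collapse = " "),
                           character(1)))
  writeLines(header, path)
  readr::write_csv(data, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write fixture datasets to disk
#'
#' Convenience wrapper around the synthetic-data generators that writes a
#' classification or regression fixture in the standard dataset dialect.
#'
#' @param path Output CSV.
#' @param kind `"classification"` or `"regression"`.
#' @param length Peptide length.
#' @param n Per-class size (classification) or total size (regression).
#' @param seed Integer seed.
#' @return The dataset tibble, invisibly.
#' @export
make_fixture <- function(path, kind = c("classification", "regression"),
                         length = 8, n = 100, seed = 1L) {
  kind <- match.arg(kind)
  data <- if (kind == "classification") {
    profile <- if (length <= 2) "dipeptide" else if (length == 3) "tripeptide"
      else if (length <= 6) "small" else if (length <= 12) "medium" else "large"
    make_classification_set(profile, "non_aht", length, n, seed)
  } else {
    make_regression_set(if (length == 2) "dipeptide" else "tripeptide",
                        length = min(length, 3), n = n, seed = seed)
  }
  write_report(data[setdiff(names(data), "pic50")], path,
               meta = list(seed = seed, kind = kind, length = length, n = n))
  invisible(data)
}
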