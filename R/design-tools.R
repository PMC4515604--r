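# Application modes mirroring the web platform: single-substitution analog
# design, library screening, protein window scanning, and background
# negative sampling for classifier training.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Enumerate all single-substitution analogs of a peptide
#'
#' Every position is substituted by each of the other 19 amino acids,
#' giving exactly `19 * nchar(p)` analogs, enumerated position-major and
#' alphabetically within a position. The parent itself is never included;
#' every analog is at Hamming distance 1 from it. Terminal insertions and
#' deletions are deliberately excluded: they change the length category and
#' hence the model, making scores incomparable with the parent's.
#'
#' @param p A valid peptide sequence (single string).
#' @return A tibble with columns `analog`, `position`, `original`,
#'   `substituted`; the parent sequence is attached as attribute `parent`.
#' @examples
#' nrow(generate_analogs("GY"))  # 38
#' @export
generate_analogs <- function(p) {
  p <- validate_peptide(p)
  chars <- strsplit(p, "", fixed = TRUE)[[1]]
  rows <- purrr::map(seq_along(chars), function(pos) {
    subs <- setdiff(AMINO_ACIDS, chars[pos])
    analogs <- vapply(subs, function(aa) {
      tmp <- chars
      tmp[pos] <- aa
      paste(tmp, collapse = "")
    }, character(1))
    tibble::tibble(analog = unname(analogs), position = pos,
                   original = chars[pos], substituted = subs)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "parent") <- p
  out
}

#' Design analogs and rank them by predicted activity
#'
#' Generates all single-substitution analogs of a parent peptide, scores
#' parent and analogs with the routed model, and returns them ranked (by
#' predicted pIC50 for tiny peptides, decision score otherwise).
#'
#' @param p Parent peptide sequence.
#' @param bundle An `ahtpep_bundle` covering the peptide's category.
#' @return A tibble of parent (position 0) and analogs with predictions,
#'   sorted best-first.
#' @export
design_analogs <- function(p, bundle) {
  analogs <- generate_analogs(p)
  all_seqs <- tibble::tibble(
    sequence = c(attr(analogs, "parent"), analogs$analog),
    position = c(0L, analogs$position),
    original = c(NA_character_, analogs$original),
    substituted = c(NA_character_, analogs$substituted)
  )
  scored <- route_and_predict(all_seqs, bundle)
  key <- if ("pic50" %in% names(scored)) "pic50" else "score"
  dplyr::arrange(scored, dplyr::desc(.data[[key]]))
}

#' Screen a peptide library
#'
#' Routes every peptide in a library to its length-category model, scores
#' it, and attaches the physicochemical property panel. Rows are sorted by
#' predicted strength (decision score, or pIC50 for tiny peptides) within
#' each category. Invalid records are never silently dropped: they are
#' returned in the `errors` attribute (a tibble with the per-record
#' message) and reported via a warning.
#'
#' @param data Data frame with `sequence` (and optionally `id`) columns, or
#'   a character vector.
#' @param bundle An `ahtpep_bundle`.
#' @param properties Attach the physicochemical panel (default `TRUE`).
#' @return A tibble of scored rows; attribute `errors` holds the invalid
#'   records.
#' @export
screen_library <- function(data, bundle, properties = TRUE) {
  checked <- validate_peptides(data)
  bad <- dplyr::filter(checked, !.data$valid)
  good <- dplyr::filter(checked, .data$valid)
  if (nrow(bad) > 0) {
    warn(sprintf("%d invalid peptide record(s) set aside; see attr(, 'errors').",
                 nrow(bad)))
  }
  if (nrow(good) == 0) {
    out <- tibble::tibble()
    attr(out, "errors") <- bad[c("id", "sequence", "error")]
    return(out)
  }
  scored <- route_and_predict(good[c("id", "sequence")], bundle)
  if (properties) {
    props <- physicochemical_report(good["sequence"])
    scored <- dplyr::left_join(
      scored,
      dplyr::distinct(props, .data$sequence, .keep_all = TRUE),
      by = "sequence"
    )
  }
  s <- if ("score" %in% names(scored)) scored$score else rep(NA_real_, nrow(scored))
  p <- if ("pic50" %in% names(scored)) scored$pic50 else rep(NA_real_, nrow(scored))
  scored$..rank <- dplyr::coalesce(s, p)
  out <- scored %>%
    dplyr::arrange(.data$category, dplyr::desc(.data$..rank)) %>%
    dplyr::select(-"..rank")
  attr(out, "errors") <- bad[c("id", "sequence", "error")]
  out
}

#' Scan a protein for antihypertensive regions
#'
#' Slides windows of the requested lengths along the protein (step 1) and
#' scores every window with the category-appropriate model. For a protein
#' of length N and window length w there are exactly N - w + 1 windows;
#' coordinates are 1-based inclusive. Window lengths longer than the
#' protein are skipped with a warning.
#'
#' @param protein Protein sequence (single string) or a one-row data frame
#'   with `id` and `sequence`.
#' @param bundle An `ahtpep_bundle`.
#' @param window_lengths Integer vector of window lengths (default 2:6).
#' @param id Protein identifier used in the output.
#' @return A tibble of window hits: `protein`, `start`, `end`, `length`,
#'   `sequence`, `category`, predictions, and `hit` (above-threshold call;
#'   for tiny windows, `hit` is `NA` -- regression reports pIC50 instead).
#' @export
scan_protein <- function(protein, bundle, window_lengths = 2:6,
                         id = "protein") {
  if (is.data.frame(protein)) {
    id <- protein$id[1] %||% id
    protein <- protein$sequence[1]
  }
  protein <- validate_peptide(protein)
  N <- nchar(protein)
  window_lengths <- sort(unique(as.integer(window_lengths)))
  too_long <- window_lengths[window_lengths > N]
  if (length(too_long) > 0) {
    warn(sprintf("Window length(s) %s exceed protein length %d; skipped.",
                 paste(too_long, collapse = ", "), N))
    window_lengths <- setdiff(window_lengths, too_long)
  }
  windows <- purrr::map(window_lengths, function(w) {
    starts <- seq_len(N - w + 1)
    seqs <- substring(protein, starts, starts + w - 1)
    tibble::tibble(protein = id, start = starts, end = starts + w - 1,
                   length = w, sequence = seqs)
  })
  windows <- dplyr::bind_rows(windows)
  scored <- route_and_predict(windows, bundle)
  scored$hit <- if ("call" %in% names(scored)) {
    ifelse(scored$task == "classification", scored$call == 1, NA)
  } else NA
  dplyr::select(scored, -dplyr::any_of(c("task")))
}

#' Sample background negative peptides
#'
#' Draws length-w fragments uniformly over all (protein, offset) positions
#' of a background protein set -- the standard stand-in for experimentally
#' validated non-AHT peptides -- excluding any fragment found in the
#' positive set and any fragment containing non-natural letters. Sampling
#' is seed-deterministic. Distinct fragments are preferred; duplicates are
#' only emitted (with a warning) when the unique pool is smaller than `n`.
#'
#' @param background Character vector of protein sequences.
#' @param w Fragment length.
#' @param n Number of negatives (use the positive-set size for a 1:1 ratio).
#' @param exclusions Character vector of forbidden sequences (the positives).
#' @param seed Integer seed.
#' @return Character vector of n peptide sequences.
#' @export
sample_negatives <- function(background, w, n, exclusions = character(),
                             seed = 1L) {
  stopifnot(n >= 1, w >= 2)
  background <- toupper(background)
  frags <- unlist(purrr::map(background, function(pr) {
    N <- nchar(pr)
    if (N < w) return(character())
    starts <- seq_len(N - w + 1)
    substring(pr, starts, starts + w - 1)
  }))
  pattern <- sprintf("^[%s]+$", paste(AMINO_ACIDS, collapse = ""))
  valid <- frags[grepl(pattern, frags) & !frags %in% toupper(exclusions)]
  if (length(valid) == 0) {
    abort("Background yields no valid fragments.",
          class = "ahtpep_error_insufficient_background")
  }
  with_seed(seed, {
    shuffled <- valid[sample.int(length(valid))]
    uniq <- unique(shuffled)
    if (length(uniq) >= n) {
      uniq[seq_len(n)]
    } else {
      warn(sprintf("Unique fragment pool (%d) smaller than n = %d; duplicates included.",
                   length(uniq), n))
      if (length(valid) < n) {
        abort("Background too small even with duplicates.",
              class = "ahtpep_error_insufficient_background")
      }
      shuffled[seq_len(n)]
    }
  })
}
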