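# Atom and bond accounting for the 20 free (unpolymerized) amino acids,
# computed from packaged explicit-hydrogen molecular graphs rather than
# transcribed constants, so the chemistry is verifiable.

the <- new.env(parent = emptyenv())

#' Read a molecular-graph fixture file
#'
#' Parses the line-oriented graph format used for the packaged amino-acid
#' structures: a `RESIDUE <code>` header, an `ATOMS` line of element
#' symbols (explicit hydrogens), and `BOND i j order` lines with 0-based
#' atom indices and order 1 (single) or 2 (double). Aromatic rings are
#' stored in a fixed Kekule form.
#'
#' @param path Path to a graph fixture file.
#' @return Named list of molecular graphs, each a list with `atoms`
#'   (character vector) and `bonds` (data frame `i`, `j`, `order`).
#' @export
read_molecular_graphs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  graphs <- list()
  current <- NULL
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (parts[1] == "RESIDUE") {
      current <- parts[2]
      graphs[[current]] <- list(atoms = character(),
                                bonds = data.frame(i = integer(), j = integer(),
                                                   order = integer()))
    } else if (parts[1] == "ATOMS") {
      graphs[[current]]$atoms <- parts[-1]
    } else if (parts[1] == "BOND") {
      b <- as.integer(parts[2:4])
      graphs[[current]]$bonds <- rbind(graphs[[current]]$bonds,
                                       data.frame(i = b[1], j = b[2], order = b[3]))
    } else {
      abort(sprintf("Unrecognized graph line: '%s'", ln),
            class = "ahtpep_error_graph_format")
    }
  }
  lapply(graphs, validate_graph)
}

validate_graph <- function(g) {
  n <- length(g$atoms)
  b <- g$bonds
  if (any(b$i < 0 | b$i >= n | b$j < 0 | b$j >= n)) {
    abort("Bond index out of range.", class = "ahtpep_error_graph_format")
  }
  if (any(b$i == b$j)) {
    abort("Self-loop bond.", class = "ahtpep_error_graph_format")
  }
  key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  if (anyDuplicated(key)) {
    abort("Duplicate bond.", class = "ahtpep_error_graph_format")
  }
  if (!all(b$order %in% c(1L, 2L))) {
    abort("Bond order must be 1 or 2.", class = "ahtpep_error_invalid_bond_order")
  }
  g
}

#' The packaged molecular graphs of the 20 amino acids
#'
#' @return Named list of 20 molecular graphs (see [read_molecular_graphs()]).
#' @export
residue_graphs <- function() {
  if (is.null(the$graphs)) {
    path <- system.file("extdata", "residue_graphs.txt", package = "ahtpep",
                        mustWork = TRUE)
    g <- read_molecular_graphs(path)
    if (!setequal(names(g), AMINO_ACIDS)) {
      abort("Graph fixture must cover exactly the 20 natural amino acids.")
    }
    the$graphs <- g[AMINO_ACIDS]
  }
  the$graphs
}

#' Count bonds in a molecular graph
#'
#' Edges are counted by order: single (1) and double (2); aromatic rings are
#' expected in Kekule form so every edge has a definite order. The graph
#' must be connected.
#'
#' @param graph A molecular graph (list with `atoms`, `bonds`).
#' @return A list with `total`, `single`, `double` bond counts.
#' @examples
#' water <- list(atoms = c("O", "H", "H"),
#'               bonds = data.frame(i = c(0, 0), j = c(1, 2), order = c(1, 1)))
#' count_bonds(water)
#' @export
count_bonds <- function(graph) {
  graph <- validate_graph(graph)
  if (!graph_connected(graph)) {
    abort("Molecular graph is not connected.",
          class = "ahtpep_error_disconnected_graph")
  }
  total <- nrow(graph$bonds)
  double <- sum(graph$bonds$order == 2L)
  list(total = total, single = total - double, double = double)
}

graph_connected <- function(graph) {
  n <- length(graph$atoms)
  if (n <= 1) return(TRUE)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[k] + 1L
    j <- graph$bonds$j[k] + 1L
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  all(seen)
}

#' Atomic composition of amino-acid residues
#'
#' Returns, for each requested residue, the C/H/N/O/S atom counts and the
#' total/single/double bond counts of the free amino acid, computed from
#' the packaged molecular graph. With no argument, returns the full 20-row
#' table.
#'
#' @param residue Character vector of one-letter codes, or `NULL` for all 20.
#' @return A tibble with columns `residue`, `C`, `H`, `N`, `O`, `S`,
#'   `total_bonds`, `single_bonds`, `double_bonds`.
#' @examples
#' residue_atoms("G")
#' residue_atoms()
#' @export
residue_atoms <- function(residue = NULL) {
  tab <- residue_atom_table()
  if (is.null(residue)) return(tab)
  residue <- toupper(residue)
  bad <- setdiff(unique(residue), AMINO_ACIDS)
  if (length(bad) > 0) {
    abort(sprintf("Unknown residue code(s): %s", paste(bad, collapse = ", ")),
          class = "ahtpep_error_unknown_residue")
  }
  tab[match(residue, tab$residue), ]
}

residue_atom_table <- function() {
  if (is.null(the$atom_table)) {
    g <- residue_graphs()
    rows <- purrr::imap(g, function(graph, code) {
      bonds <- count_bonds(graph)
      counts <- table(factor(graph$atoms, levels = c("C", "H", "N", "O", "S")))
      tibble::tibble(
        residue = code,
        C = as.integer(counts["C"]), H = as.integer(counts["H"]),
        N = as.integer(counts["N"]), O = as.integer(counts["O"]),
        S = as.integer(counts["S"]),
        total_bonds = bonds$total,
        single_bonds = bonds$single,
        double_bonds = bonds$double
      )
    })
    the$atom_table <- dplyr::bind_rows(rows)
  }
  the$atom_table
}

# Monoisotopic element masses (u); molecular weight of a free residue is the
# mass-weighted sum of its atom counts.
ELEMENT_MASS <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069)
WATER_MASS <- 2 * ELEMENT_MASS[["H"]] + ELEMENT_MASS[["O"]]

residue_mass <- function(residue) {
  tab <- residue_atoms(residue)
  as.numeric(as.matrix(tab[, c("C", "H", "N", "O", "S")]) %*% ELEMENT_MASS)
}
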