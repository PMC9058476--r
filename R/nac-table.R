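# NAC tables: one row per atom-in-material, one column per charge assignment
# method, plus the metadata columns molecule_id / atom_index / element /
# net_charge. Held as an ordinary tibble with class "nac_table" so dplyr
# verbs keep working on it.

.nac_meta_cols <- c("molecule_id", "atom_index", "element", "net_charge")

#' Construct a NAC table from a data frame
#'
#' A NAC (net atomic charge) table records, for each atom in a collection of
#' molecules or ions, the partial charge (in units of elementary charge e)
#' assigned by each of several charge-assignment methods. The required
#' metadata columns are `molecule_id`, `atom_index` (0-based within each
#' molecule), `element`, and `net_charge` (the integer net charge of the
#' whole molecule); all remaining columns are treated as method columns.
#'
#' @param x A data frame with the four metadata columns and at least one
#'   numeric method column. Missing NAC entries are `NA`.
#' @return A `nac_table` tibble.
#' @examples
#' tbl <- as_nac_table(data.frame(
#'   molecule_id = "m1", atom_index = 0:1, element = c("O", "O"),
#'   net_charge = 0L, methA = c(-0.2, 0.2), methB = c(-0.25, 0.25)
#' ))
#' nac_methods(tbl)
#' @export
as_nac_table <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(.nac_meta_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("NAC table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  methods <- setdiff(names(x), .nac_meta_cols)
  if (length(methods) == 0) {
    abort("NAC table has no method columns.")
  }
  if (!all(vapply(x[methods], is.numeric, logical(1)))) {
    abort("All method columns must be numeric.")
  }
  x$molecule_id <- as.character(x$molecule_id)
  x$atom_index <- as.integer(x$atom_index)
  if (any(x$net_charge != round(x$net_charge), na.rm = TRUE)) {
    abort("net_charge must be integer-valued for every molecule.")
  }
  x$net_charge <- as.integer(round(x$net_charge))
  key <- paste(x$molecule_id, x$atom_index)
  if (anyDuplicated(key)) {
    abort("Duplicate (molecule_id, atom_index) pairs found.")
  }
  per_mol <- tapply(x$net_charge, x$molecule_id, function(q) length(unique(q)))
  if (any(per_mol > 1)) {
    abort("net_charge must be constant within each molecule.")
  }
  class(x) <- c("nac_table", class(x))
  x
}

#' @rdname as_nac_table
#' @export
is_nac_table <- function(x) inherits(x, "nac_table")

#' Method columns of a NAC table
#'
#' @param table A `nac_table` (or compatible data frame).
#' @return Character vector of method names, in column order.
#' @export
nac_methods <- function(table) {
  setdiff(names(table), .nac_meta_cols)
}

#' Extract the atoms-by-methods value matrix
#'
#' @param table A `nac_table`.
#' @return Numeric matrix, one row per atom record, one column per method.
#' @export
nac_values <- function(table) {
  as.matrix(table[nac_methods(table)])
}

#' Per-molecule integer net charges
#'
#' @param table A `nac_table`.
#' @return A tibble with one row per molecule: `molecule_id`, `n_atoms`,
#'   `net_charge`.
#' @export
nac_net_charges <- function(table) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(table), .data$molecule_id),
                   n_atoms = dplyr::n(),
                   net_charge = .data$net_charge[1], .groups = "drop")
}

#' Read a NAC table from CSV
#'
#' The expected layout is a header row
#' `molecule_id,atom_index,element,net_charge,<method1>,<method2>,...`
#' with UTF-8 encoding and "." as the decimal separator. Empty cells become
#' missing NAC entries. Corrections, if supplied, are applied declaratively
#' (never as silent edits) and each applied action is recorded in the
#' returned table's `"corrections_applied"` attribute.
#'
#' @param path Path to a CSV file.
#' @param one_based_atoms If `TRUE`, atom indices in the file are 1-based and
#'   are shifted to the internal 0-based convention.
#' @param corrections Optional path to a YAML or JSON corrections file: a
#'   list of actions, each `{action: set_value, molecule_id, atom_index,
#'   method, value}` or `{action: drop_molecule, molecule_id}`.
#' @return A `nac_table`.
#' @examples
#' path <- system.file("extdata", "synthetic_nac_example.csv",
#'                     package = "confluentq")
#' tbl <- read_nac_table(path)
#' nac_methods(tbl)
#' @export
read_nac_table <- function(path, one_based_atoms = FALSE, corrections = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(.nac_meta_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Malformed header: missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (one_based_atoms) raw$atom_index <- raw$atom_index - 1L
  tbl <- as_nac_table(raw)
  if (!is.null(corrections)) {
    tbl <- apply_corrections(tbl, read_corrections(corrections))
  }
  tbl
}

#' Write a NAC table to CSV
#'
#' @param table A `nac_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nac_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, na = "", progress = FALSE)
  invisible(path)
}

read_corrections <- function(path) {
  if (!file.exists(path)) abort(paste0("Corrections file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Apply declarative corrections to a NAC table
#'
#' @param table A `nac_table`.
#' @param corrections A list of correction actions (see [read_nac_table()]).
#' @return The corrected `nac_table`; applied actions are recorded in its
#'   `"corrections_applied"` attribute.
#' @export
apply_corrections <- function(table, corrections) {
  applied <- list()
  for (corr in corrections) {
    act <- corr$action %||% abort("Correction entry lacks an 'action' field.")
    if (act == "drop_molecule") {
      if (!corr$molecule_id %in% table$molecule_id) {
        abort(paste0("drop_molecule: unknown molecule_id ", corr$molecule_id))
      }
      table <- table[table$molecule_id != corr$molecule_id, ]
    } else if (act == "set_value") {
      row <- which(table$molecule_id == corr$molecule_id &
                     table$atom_index == corr$atom_index)
      if (length(row) != 1 || !corr$method %in% nac_methods(table)) {
        abort("set_value: no such (molecule_id, atom_index, method) cell.")
      }
      table[[corr$method]][row] <- as.numeric(corr$value)
    } else {
      abort(paste0("Unknown correction action: ", act))
    }
    applied <- c(applied, list(corr))
  }
  attr(table, "corrections_applied") <- applied
  table
}

#' Partition molecules into contiguous blocks of roughly equal size
#'
#' Molecules are never split: whole molecules are assigned, in order of first
#' appearance, to consecutive blocks that are closed once they reach
#' `target_size` atoms. Closed blocks therefore hold at least `target_size`
#' atoms (the final block may be smaller) and at most `target_size` plus the
#' largest molecule's atom count minus one.
#'
#' @param table A `nac_table`.
#' @param target_size Target atoms per block (default 500).
#' @return A tibble with one row per molecule: `block_id`, `molecule_id`,
#'   `n_atoms`.
#' @export
partition_blocks <- function(table, target_size = 500) {
  if (target_size < 1) abort("target_size must be >= 1.")
  mols <- dplyr::count(tibble::as_tibble(table), .data$molecule_id,
                       name = "n_atoms", sort = FALSE)
  # dplyr::count sorts by group; restore file order of first appearance
  mols <- mols[match(unique(table$molecule_id), mols$molecule_id), ]
  block_id <- integer(nrow(mols))
  current <- 1L
  size <- 0L
  for (i in seq_len(nrow(mols))) {
    block_id[i] <- current
    size <- size + mols$n_atoms[i]
    if (size >= target_size) {
      current <- current + 1L
      size <- 0L
    }
  }
  tibble::tibble(block_id = block_id, molecule_id = mols$molecule_id,
                 n_atoms = mols$n_atoms)
}

#' Integer running-sum consistency check
#'
#' Because every molecule or ion carries an integer net charge, the sum of
#' NACs over any block of whole molecules must reach an integer (the summed
#' net charge of the block), up to small numerical integration error, and
#' this must hold for every charge-assignment method independently. Each
#' (block, method) residual from the nearest integer is classified as
#' negligible, suspect, or fatal; a block whose nearest integer disagrees
#' with the known summed net charge of its molecules is always fatal.
#'
#' @param table A `nac_table`.
#' @param target_size Atoms per block passed to [partition_blocks()].
#' @param tol_negligible Residual (e) below which no flag is raised.
#' @param tol_fatal Residual (e) above which a flag is fatal.
#' @return A `consistency_report`: list with `blocks` (the block
#'   definitions), `sums` (per block x method running-sum residuals),
#'   `flags` (tibble sorted by descending residual magnitude), and
#'   `missing_entries`.
#' @export
check_block_sums <- function(table, target_size = 500,
                             tol_negligible = 0.01, tol_fatal = 0.05) {
  if (!(tol_negligible < tol_fatal)) {
    abort("tol_negligible must be smaller than tol_fatal.")
  }
  blocks <- partition_blocks(table, target_size)
  methods <- nac_methods(table)
  tbl <- tibble::as_tibble(table)
  tbl$block_id <- blocks$block_id[match(tbl$molecule_id, blocks$molecule_id)]

  vals <- nac_values(table)
  miss_idx <- which(is.na(vals), arr.ind = TRUE)
  missing_entries <- tibble::tibble(
    molecule_id = tbl$molecule_id[miss_idx[, 1]],
    atom_index = tbl$atom_index[miss_idx[, 1]],
    method = methods[miss_idx[, 2]]
  )

  block_net <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(tbl, .data$block_id, .data$molecule_id,
                                    .data$net_charge), .data$block_id),
    net_charge = sum(.data$net_charge), .groups = "drop")

  long <- tidyr::pivot_longer(tbl[c("block_id", methods)],
                              dplyr::all_of(methods),
                              names_to = "method", values_to = "nac")
  sums <- dplyr::summarise(dplyr::group_by(long, .data$block_id, .data$method),
                           total = sum(.data$nac, na.rm = TRUE),
                           n_missing = sum(is.na(.data$nac)),
                           .groups = "drop")
  sums <- dplyr::left_join(sums, block_net, by = "block_id")
  sums$residual <- abs(sums$total - round(sums$total))
  sums$integer_mismatch <- round(sums$total) != sums$net_charge

  sums$severity <- dplyr::case_when(
    sums$integer_mismatch ~ "fatal",
    sums$residual > tol_fatal ~ "fatal",
    sums$residual > tol_negligible ~ "suspect",
    TRUE ~ "negligible"
  )
  flags <- sums[sums$severity != "negligible",
                c("block_id", "method", "residual", "severity")]
  flags <- flags[order(-flags$residual), ]

  structure(list(blocks = blocks, sums = sums, flags = flags,
                 missing_entries = missing_entries,
                 tol_negligible = tol_negligible, tol_fatal = tol_fatal),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("NAC running-sum consistency report\n")
  cat("  blocks:", max(x$blocks$block_id), "  methods:",
      length(unique(x$sums$method)), "\n")
  cat("  flags:", nrow(x$flags), " (",
      sum(x$flags$severity == "fatal"), "fatal )\n")
  cat("  missing entries:", nrow(x$missing_entries), "\n")
  if (nrow(x$flags) > 0) print(head(x$flags, 10))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.consistency_report <- function(x, ...) x$flags

#' Validate physical bounds on NACs (and optionally atomic spin moments)
#'
#' A net atomic charge q larger than the atomic number Z would leave the atom
#' with a negative number of electrons (Z - q < 0), which is unphysical.
#' When per-atom atomic spin moments (ASMs) are supplied, the remaining
#' electron count Z - q must be at least |ASM|: e.g. a hydrogen atom cannot
#' simultaneously carry a NAC of 0.75 (0.25 electrons remaining) and an ASM
#' of 0.9.
#'
#' @param table A `nac_table`.
#' @param asm Optional numeric vector of atomic spin moments, one per atom
#'   row (method-independent).
#' @param tol Numerical slack on both comparisons.
#' @return A tibble of violations: `molecule_id`, `atom_index`, `element`,
#'   `method`, `rule` (`negative_electron_count` or `nac_asm_inconsistent`),
#'   `detail`.
#' @export
validate_physical_bounds <- function(table, asm = NULL, tol = 1e-8) {
  methods <- nac_methods(table)
  z <- atomic_number(table$element)
  if (!is.null(asm) && length(asm) != nrow(table)) {
    abort("asm must have one entry per atom row.")
  }
  out <- purrr::map_dfr(methods, function(m) {
    q <- table[[m]]
    neg <- which(!is.na(q) & q > z + tol)
    rows <- tibble::tibble(
      molecule_id = table$molecule_id[neg],
      atom_index = table$atom_index[neg],
      element = table$element[neg],
      method = m,
      rule = "negative_electron_count",
      detail = sprintf("NAC %.4f > Z = %d (%.4f electrons)",
                       q[neg], z[neg], z[neg] - q[neg])
    )
    if (!is.null(asm)) {
      inc <- which(!is.na(q) & (z - q) + tol < abs(asm))
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        molecule_id = table$molecule_id[inc],
        atom_index = table$atom_index[inc],
        element = table$element[inc],
        method = m,
        rule = "nac_asm_inconsistent",
        detail = sprintf("Z - q = %.4f electrons < |ASM| = %.4f",
                         z[inc] - q[inc], abs(asm[inc]))
      ))
    }
    rows
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
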