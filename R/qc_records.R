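#' Structure-summary record of an electronic-structure calculation
#'
#' A `qc_record` is the single container every downstream stage consumes:
#' orbital energies with occupancies for descriptor and DOS work, a dipole
#' vector, harmonic frequencies for vibrational analysis, and (optionally)
#' per-orbital population weights over named atom groups for projected DOS.
#'
#' Canonical units are fixed and never converted implicitly: orbital energies
#' in eV, total energy in hartree, dipole components in Debye, frequencies in
#' cm^-1. A negative frequency encodes an imaginary mode; it is carried with a
#' warning flag rather than dropped.
#'
#' @param label Non-empty structure identifier.
#' @param orbital_energies Numeric vector of orbital energies (eV). Stored
#'   sorted ascending together with `occupied`.
#' @param occupied Logical vector, one flag per orbital (`TRUE` = occupied).
#'   Occupancy is stored explicitly because records may be truncated
#'   frontier-region summaries for which electron counting is meaningless.
#' @param method,basis Free-text tags for the computation family and basis set.
#' @param total_energy Total energy in hartree, or `NULL` if not available.
#' @param dipole Numeric length-3 dipole vector in Debye, or a single
#'   magnitude, or `NULL`.
#' @param frequencies Harmonic frequencies in cm^-1 (negative = imaginary
#'   mode), or `NULL`.
#' @param population_weights Numeric matrix (orbitals x groups) of population
#'   fractions with named columns; each row must sum to 1 within 1e-6. `NULL`
#'   if no population analysis is attached. Rows are reordered together with
#'   the orbital sort.
#'
#' @return An object of class `qc_record`.
#'
#' @details Validation enforces: label non-empty, equal orbital/occupancy
#' lengths, at least the sortedness of orbital energies (the constructor sorts
#' for you), and the frontier condition that every occupied orbital lies below
#' every virtual orbital — a record violating it is rejected, since HOMO/LUMO
#' and the occupied/virtual DOS split would be ill-defined.
#'
#' @examples
#' rec <- qc_record("cellulose",
#'                  orbital_energies = c(-8, -6.502, 1.442, 3),
#'                  occupied = c(TRUE, TRUE, FALSE, FALSE))
#' homo_lumo(rec)
#' @export
qc_record <- function(label, orbital_energies, occupied,
                      method = "unknown", basis = "unknown",
                      total_energy = NULL, dipole = NULL,
                      frequencies = NULL, population_weights = NULL) {
  if (!is.character(label) || length(label) != 1L || is.na(label) || !nzchar(label))
    stop("'label' must be a non-empty string")
  orbital_energies <- as.numeric(orbital_energies)
  occupied <- as.logical(occupied)
  if (length(orbital_energies) != length(occupied))
    stop("'orbital_energies' and 'occupied' must have the same length")
  if (anyNA(orbital_energies) || anyNA(occupied))
    stop("orbital energies and occupancies must not contain NA")

  ord <- order(orbital_energies)
  orbital_energies <- orbital_energies[ord]
  occupied <- occupied[ord]

  if (!is.null(population_weights)) {
    population_weights <- as.matrix(population_weights)
    if (nrow(population_weights) != length(orbital_energies))
      stop("'population_weights' must have one row per orbital")
    if (is.null(colnames(population_weights)))
      colnames(population_weights) <- paste0("group", seq_len(ncol(population_weights)))
    rs <- rowSums(population_weights)
    bad <- which(abs(rs - 1) > 1e-6)
    if (length(bad))
      stop(sprintf("population weight row %d sums to %.8g, not 1", bad[1L], rs[bad[1L]]))
    population_weights <- population_weights[ord, , drop = FALSE]
  }

  if (any(occupied) && any(!occupied)) {
    if (max(orbital_energies[occupied]) >= min(orbital_energies[!occupied]))
      stop(sprintf("record '%s': an occupied orbital lies at or above a virtual orbital", label))
  }

  if (!is.null(total_energy)) {
    total_energy <- as.numeric(total_energy)
    stopifnot(length(total_energy) == 1L, is.finite(total_energy))
  }
  if (!is.null(dipole)) {
    dipole <- as.numeric(dipole)
    if (!length(dipole) %in% c(1L, 3L))
      stop("'dipole' must be a 3-vector or a scalar magnitude")
  }
  has_imaginary <- FALSE
  if (!is.null(frequencies)) {
    frequencies <- as.numeric(frequencies)
    has_imaginary <- any(frequencies < 0)
    if (has_imaginary)
      warning(sprintf("record '%s' carries %d imaginary mode(s) (negative wavenumbers)",
                      label, sum(frequencies < 0)))
  }

  structure(
    list(label = label, method = method, basis = basis,
         total_energy = total_energy,
         orbital_energies = orbital_energies, occupied = occupied,
         dipole = dipole, frequencies = frequencies,
         population_weights = population_weights,
         has_imaginary = has_imaginary),
    class = "qc_record")
}

#' @export
print.qc_record <- function(x, ...) {
  cat(sprintf("<qc_record> %s  [%s/%s]\n", x$label, x$method, x$basis))
  n_occ <- sum(x$occupied); n_vir <- sum(!x$occupied)
  cat(sprintf("  orbitals: %d occupied, %d virtual", n_occ, n_vir))
  if (n_occ && n_vir) {
    hl <- homo_lumo(x)
    cat(sprintf("  (HOMO %.3f eV, LUMO %.3f eV)", hl[1L], hl[2L]))
  }
  cat("\n")
  if (!is.null(x$total_energy))
    cat(sprintf("  total energy: %.6f hartree\n", x$total_energy))
  if (!is.null(x$dipole))
    cat(sprintf("  dipole magnitude: %.3f D\n", dipole_magnitude(x$dipole)))
  if (!is.null(x$frequencies))
    cat(sprintf("  frequencies: %d modes%s\n", length(x$frequencies),
                if (x$has_imaginary) " (imaginary present)" else ""))
  if (!is.null(x$population_weights))
    cat(sprintf("  population groups: %s\n",
                paste(colnames(x$population_weights), collapse = ", ")))
  invisible(x)
}

#' Frontier orbital energies of a record
#'
#' @param record A [qc_record].
#' @return Named numeric vector `c(homo = , lumo = )` in eV: the highest
#'   occupied and lowest virtual orbital energies.
#' @examples
#' rec <- qc_record("x", c(-8, -6.502, 1.442, 3), c(TRUE, TRUE, FALSE, FALSE))
#' homo_lumo(rec)  # -6.502, 1.442
#' @export
homo_lumo <- function(record) {
  stopifnot(inherits(record, "qc_record"))
  occ <- record$orbital_energies[record$occupied]
  vir <- record$orbital_energies[!record$occupied]
  if (!length(occ)) stop(sprintf("record '%s' has no occupied orbital", record$label))
  if (!length(vir)) stop(sprintf("record '%s' has no virtual orbital", record$label))
  c(homo = max(occ), lumo = min(vir))
}

#' Split a record's orbitals into occupied and virtual energies
#'
#' @param record A [qc_record].
#' @return List with sorted numeric vectors `occupied` and `virtual` (eV).
#'   Either may be empty for truncated records.
#' @export
split_occupied_virtual <- function(record) {
  stopifnot(inherits(record, "qc_record"))
  list(occupied = sort(record$orbital_energies[record$occupied]),
       virtual  = sort(record$orbital_energies[!record$occupied]))
}

# ---- serialization -----------------------------------------------------------

#' Serialize a record to canonical JSON
#'
#' The canonical form has a fixed key order and full-precision floats, so two
#' calls on the same record are byte-identical and golden-file tests are
#' stable. Optional fields (`total_energy`, `dipole`, `frequencies`,
#' `population_weights`) are omitted when absent.
#'
#' @param record A [qc_record].
#' @param path Optional file path; when given the JSON text is also written
#'   there (UTF-8, LF line endings).
#' @return The JSON text, invisibly when `path` is given.
#' @seealso [read_qc_record()]
#' @export
write_qc_record <- function(record, path = NULL) {
  stopifnot(inherits(record, "qc_record"))
  x <- list(label = record$label, method = record$method, basis = record$basis)
  if (!is.null(record$total_energy)) x$total_energy <- record$total_energy
  x$orbital_energies <- record$orbital_energies
  x$occupied <- record$occupied
  if (!is.null(record$dipole)) x$dipole <- record$dipole
  if (!is.null(record$frequencies)) x$frequencies <- record$frequencies
  if (!is.null(record$population_weights)) {
    pw <- record$population_weights
    x$population_groups <- colnames(pw)
    x$population_weights <- unname(lapply(seq_len(nrow(pw)), function(i) unname(pw[i, ])))
  }
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(txt, con, eos = NULL, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Parse a record from its JSON serialization
#'
#' Accepts a file path or a JSON string (UTF-8; LF or CRLF). All `qc_record`
#' invariants are re-validated on parse, so a hand-edited file with, say, a
#' population row summing to 0.8 or an occupied orbital above a virtual one is
#' rejected with a message naming the offending field.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @return A [qc_record].
#' @export
read_qc_record <- function(source) {
  x <- tryCatch(jsonlite::fromJSON(source, simplifyVector = TRUE),
                error = function(e) stop("record parse error: ", conditionMessage(e)))
  for (f in c("label", "orbital_energies", "occupied"))
    if (is.null(x[[f]])) stop(sprintf("record parse error: missing field '%s'", f))
  pw <- NULL
  if (!is.null(x$population_weights)) {
    pw <- x$population_weights
    if (is.list(pw)) pw <- do.call(rbind, pw)
    pw <- as.matrix(pw)
    if (!is.null(x$population_groups)) colnames(pw) <- x$population_groups
  }
  qc_record(label = x$label,
            orbital_energies = x$orbital_energies,
            occupied = x$occupied,
            method = if (is.null(x$method)) "unknown" else x$method,
            basis = if (is.null(x$basis)) "unknown" else x$basis,
            total_energy = x$total_energy,
            dipole = x$dipole,
            frequencies = x$frequencies,
            population_weights = pw)
}

# ---- record sets -------------------------------------------------------------

#' Collect records into a labelled set
#'
#' @param records List of [qc_record] objects with unique labels.
#' @param provenance Free-text metadata carried with the set.
#' @return A `record_set`: a named list of records plus provenance.
#' @export
record_set <- function(records = list(), provenance = "") {
  stopifnot(all(vapply(records, inherits, logical(1), "qc_record")))
  labels <- vapply(records, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate record label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  names(records) <- labels
  structure(list(records = records, provenance = provenance), class = "record_set")
}

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf("<record_set> %d record(s)\n", length(x$records)))
  for (lab in names(x$records)) cat("  -", lab, "\n")
  invisible(x)
}

#' @export
length.record_set <- function(x) length(x$records)

#' Write / read a record set as a keyed JSON collection
#'
#' @param rs A [record_set].
#' @param path File path.
#' @return `read_record_set` returns a [record_set]; `write_record_set`
#'   returns `path` invisibly.
#' @export
write_record_set <- function(rs, path) {
  stopifnot(inherits(rs, "record_set"))
  entries <- vapply(rs$records, function(r) {
    txt <- write_qc_record(r)
    sub("\n$", "", txt)
  }, character(1))
  body <- paste0("{\n\"provenance\": ", jsonlite::toJSON(rs$provenance, auto_unbox = TRUE),
                 ",\n\"records\": [\n", paste(entries, collapse = ",\n"), "\n]\n}\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(body, con, eos = NULL, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_record_set
#' @export
read_record_set <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  recs <- lapply(x$records, function(r)
    read_qc_record(as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))))
  record_set(recs, provenance = if (is.null(x$provenance)) "" else x$provenance)
}
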