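# Energy datasets: lists of (geometry, energy, optional gradient, level
# tag) records sharing one atom count and order, plus an optional
# reference (geometry + energy) defining the energy origin.

#' Create an energy dataset
#'
#' @param records list of records; each is a list with fields `geometry`
#'   (a [geometry()]), `energy` (hartree), optional `gradient` (flattened
#'   3N vector, hartree/bohr) and `level` (character tag).
#' @param reference optional list with `geometry` and `energy`, the
#'   energy origin of the dataset.
#' @return object of class `energy_dataset`.
#' @export
energy_dataset <- function(records = list(), reference = NULL) {
  if (length(records) > 0) {
    n <- nrow(records[[1]]$geometry$coords)
    for (i in seq_along(records)) {
      r <- records[[i]]
      if (!inherits(r$geometry, "mol_geometry")) {
        stop(sprintf("record %d: geometry is not a mol_geometry", i))
      }
      if (nrow(r$geometry$coords) != n) {
        stop(sprintf("record %d: atom count %d differs from first record's %d",
                     i, nrow(r$geometry$coords), n))
      }
      if (!is.finite(r$energy)) stop(sprintf("record %d: non-finite energy", i))
    }
  }
  structure(list(records = records, reference = reference),
            class = "energy_dataset")
}

#' @export
length.energy_dataset <- function(x) length(x$records)

#' @export
print.energy_dataset <- function(x, ...) {
  lv <- unique(vapply(x$records, function(r) r$level %||% "?", ""))
  cat(sprintf("<energy_dataset> %d records (level: %s)%s\n",
              length(x$records), paste(lv, collapse = ","),
              if (is.null(x$reference)) "" else "; with reference"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Energies of a dataset
#'
#' @param ds an [energy_dataset()].
#' @return numeric vector of record energies (hartree).
#' @export
dataset_energies <- function(ds) {
  vapply(ds$records, function(r) r$energy, numeric(1))
}

#' Subset a dataset by record index
#'
#' @param ds an [energy_dataset()].
#' @param idx integer indices.
#' @return an [energy_dataset()] keeping the reference.
#' @export
dataset_subset <- function(ds, idx) {
  energy_dataset(ds$records[idx], reference = ds$reference)
}
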