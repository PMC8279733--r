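# Delta-machine-learning workflow: difference datasets (high-level energy
# minus low-level surface), training-set selection rules (stride,
# near-reference clustering, energy cap, seeded random pick) and database
# diagnostics (energy histograms, difference-vs-low scatter, coordinate
# scatter). The composite surface itself lives in compose_surfaces().

#' Build the difference dataset for a correction fit
#'
#' For every high-level record, computes
#' (E_high - E_high(ref)) - (V_LL - V_LL(ref)): both levels are
#' re-referenced at the reference geometry (the convention is a zero of
#' energy for both levels at the low-level global-minimum structure)
#' before subtraction.
#'
#' @param high high-level [energy_dataset()].
#' @param low_surface the low-level surface.
#' @param ref_geom reference geometry; defaults to the dataset's own
#'   reference geometry.
#' @param ref_energy_high high-level energy at `ref_geom` (hartree). When
#'   `NULL`, taken from the dataset reference, or from a record whose
#'   coordinates match `ref_geom`; an error otherwise.
#' @return an [energy_dataset()] of difference energies (level `"diff"`).
#' @export
difference_dataset <- function(high, low_surface, ref_geom = NULL,
                               ref_energy_high = NULL) {
  if (is.null(ref_geom)) ref_geom <- high$reference$geometry
  if (is.null(ref_geom)) stop("no reference geometry available")
  xref <- coords_vector(ref_geom)
  if (is.null(ref_energy_high)) ref_energy_high <- high$reference$energy
  if (is.null(ref_energy_high)) {
    for (r in high$records) {
      if (max(abs(coords_vector(r$geometry) - xref)) < 1e-10) {
        ref_energy_high <- r$energy
        break
      }
    }
  }
  if (is.null(ref_energy_high)) {
    stop("reference geometry absent from the high-level dataset and no reference energy supplied")
  }
  v_ref <- surface_energy(low_surface, xref)
  recs <- lapply(high$records, function(r) {
    de <- (r$energy - ref_energy_high) -
      (surface_energy(low_surface, coords_vector(r$geometry)) - v_ref)
    list(geometry = r$geometry, energy = de, gradient = NULL, level = "diff")
  })
  energy_dataset(recs, reference = list(geometry = ref_geom, energy = 0))
}

#' Stride selection of training and test subsets
#'
#' Takes every `stride`-th record (0-based indices 0, k, 2k, ...) as the
#' training set and the remainder as the test set; the two are disjoint
#' and their union is the dataset. Selecting every 3rd point of 2151
#' records yields 717 training records.
#'
#' @param ds an [energy_dataset()].
#' @param stride integer k >= 1; `stride = 1` trains on everything.
#' @return list with `train` and `test` [energy_dataset()]s.
#' @export
select_training <- function(ds, stride) {
  if (length(ds) == 0) stop("dataset is empty")
  stride <- as.integer(stride)
  if (stride < 1) stop("stride must be >= 1")
  idx <- seq(1L, length(ds), by = stride)
  list(train = dataset_subset(ds, idx),
       test = dataset_subset(ds, setdiff(seq_len(length(ds)), idx)))
}

#' Keep records structurally close to a reference geometry
#'
#' Clusters records near a reference: the RMS difference over all C(n,2)
#' internuclear distances against `ref_geom` must be below `cutoff`
#' (angstroms).
#'
#' @param ds an [energy_dataset()].
#' @param ref_geom reference [geometry()] (default: dataset reference).
#' @param cutoff RMS distance-difference cutoff in angstroms.
#' @return filtered [energy_dataset()].
#' @export
filter_near_reference <- function(ds, cutoff, ref_geom = NULL) {
  if (is.null(ref_geom)) ref_geom <- ds$reference$geometry
  if (is.null(ref_geom)) stop("no reference geometry available")
  if (cutoff <= 0) stop("cutoff must be positive")
  keep <- vapply(ds$records, function(r) {
    as.numeric(structure_rms(r$geometry, ref_geom)) < cutoff
  }, logical(1))
  dataset_subset(ds, which(keep))
}

#' Drop records above an energy cap
#'
#' Discards records whose energy relative to the dataset reference (or to
#' the dataset minimum when no reference is set) exceeds `cap_cm`.
#'
#' @param ds an [energy_dataset()].
#' @param cap_cm energy cap in cm^-1 above the reference.
#' @return filtered [energy_dataset()].
#' @export
filter_energy_cap <- function(ds, cap_cm) {
  e <- dataset_energies(ds)
  ref <- ds$reference$energy %||% min(e)
  keep <- (e - ref) * hartree_to_cm <= cap_cm
  dataset_subset(ds, which(keep))
}

#' Seeded random selection of records
#'
#' Draws `n` records uniformly without replacement, deterministically for
#' a given seed (the randomized part of the high-level database
#' construction: random positions in the remaining low-level list).
#'
#' @param ds an [energy_dataset()].
#' @param n number of records to draw.
#' @param seed RNG seed (default 0).
#' @return selected [energy_dataset()].
#' @export
select_random <- function(ds, n, seed = 0) {
  if (n > length(ds)) stop("cannot draw more records than the dataset holds")
  set.seed(seed)
  dataset_subset(ds, sort(sample.int(length(ds), n)))
}

# histogram with bin edges starting at the data minimum
.edge_histogram <- function(values_cm, bin_cm) {
  lo <- min(values_cm)
  nbin <- max(1L, ceiling((max(values_cm) - lo) / bin_cm + 1e-12))
  edges <- lo + bin_cm * (0:nbin)
  idx <- pmin(findInterval(values_cm, edges, rightmost.closed = TRUE), nbin)
  counts <- tabulate(idx, nbin)
  list(edges = edges, counts = counts, bin_cm = bin_cm)
}

#' Database diagnostics for a low-level / difference dataset pair
#'
#' Characterizes the fitting databases: a histogram of low-level energies
#' (default bin 500 cm^-1, relative to the dataset minimum), a histogram
#' of difference energies (default bin 80 cm^-1), a scatter table of
#' difference energy against low-level energy for geometries present in
#' both datasets (matched by coordinates; empty when the sets do not
#' intersect), and optionally a two-distance coordinate scatter (e.g. the
#' two O-H distances of a transferring hydrogen) for each dataset.
#'
#' @param low low-level [energy_dataset()].
#' @param diff difference [energy_dataset()].
#' @param bin_low_cm,bin_diff_cm histogram bin sizes (cm^-1).
#' @param scatter_pairs optional 2 x 2 matrix of atom index pairs, one row
#'   per distance, for the coordinate scatter.
#' @return object of class `delta_diagnostics` with `hist_low`,
#'   `hist_diff`, `scatter` (data frame), `coord_scatter` and
#'   `diff_range_cm`.
#' @export
database_diagnostics <- function(low, diff, bin_low_cm = 500, bin_diff_cm = 80,
                                 scatter_pairs = NULL) {
  if (length(low) == 0 || length(diff) == 0) stop("datasets must be nonempty")
  e_low <- dataset_energies(low)
  e_low_cm <- (e_low - min(e_low)) * hartree_to_cm
  e_diff_cm <- dataset_energies(diff) * hartree_to_cm
  h_low <- .edge_histogram(e_low_cm, bin_low_cm)
  h_diff <- .edge_histogram(e_diff_cm - min(e_diff_cm), bin_diff_cm)
  key <- function(g) paste(signif(coords_vector(g), 12), collapse = "|")
  low_map <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(low$records)) low_map[[key(low$records[[i]]$geometry)]] <- i
  rows <- list()
  for (j in seq_along(diff$records)) {
    i <- low_map[[key(diff$records[[j]]$geometry)]]
    if (!is.null(i)) {
      rows[[length(rows) + 1L]] <- c(e_low_cm[i], e_diff_cm[j])
    }
  }
  scatter <- if (length(rows) > 0) {
    df <- as.data.frame(do.call(rbind, rows))
    names(df) <- c("E_low_cm", "E_diff_cm")
    df
  } else {
    data.frame(E_low_cm = numeric(0), E_diff_cm = numeric(0))
  }
  coord_scatter <- NULL
  if (!is.null(scatter_pairs)) {
    dists <- function(ds) {
      t(vapply(ds$records, function(r) {
        cm <- r$geometry$coords
        c(sqrt(sum((cm[scatter_pairs[1, 1], ] - cm[scatter_pairs[1, 2], ])^2)),
          sqrt(sum((cm[scatter_pairs[2, 1], ] - cm[scatter_pairs[2, 2], ])^2)))
      }, numeric(2)))
    }
    coord_scatter <- list(low = dists(low), diff = dists(diff))
  }
  structure(list(hist_low = h_low, hist_diff = h_diff, scatter = scatter,
                 coord_scatter = coord_scatter,
                 diff_range_cm = range(e_diff_cm)),
            class = "delta_diagnostics")
}

#' @export
print.delta_diagnostics <- function(x, ...) {
  cat(sprintf("<delta_diagnostics> low: %d records in %d bins of %g cm^-1; diff range [%.1f, %.1f] cm^-1\n",
              sum(x$hist_low$counts), length(x$hist_low$counts),
              x$hist_low$bin_cm, x$diff_range_cm[1], x$diff_range_cm[2]))
  invisible(x)
}

#' Write diagnostics as tabular text files
#'
#' @param diag a [database_diagnostics()] result.
#' @param prefix output file prefix; writes `<prefix>_hist_low.tsv`,
#'   `<prefix>_hist_diff.tsv` and `<prefix>_scatter.tsv`.
#' @return invisibly, the written paths.
#' @export
write_diagnostics <- function(diag, prefix) {
  paths <- character(0)
  hist_df <- function(h) data.frame(edge_lo = h$edges[-length(h$edges)],
                                    edge_hi = h$edges[-1], count = h$counts)
  p <- paste0(prefix, "_hist_low.tsv")
  utils::write.table(hist_df(diag$hist_low), p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_hist_diff.tsv")
  utils::write.table(hist_df(diag$hist_diff), p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_scatter.tsv")
  utils::write.table(diag$scatter, p, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(paths, p))
}
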