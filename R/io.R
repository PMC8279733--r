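# File formats: extended XYZ datasets (angstrom coordinates, hartree
# energies, optional hartree/bohr force columns), JSON surface containers
# with a version tag, and YAML run configuration. Values are written with
# 17 significant digits so numeric round trips are lossless at stored
# precision.

.parse_kv <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  kv <- list()
  for (t in toks) {
    parts <- strsplit(t, "=", fixed = TRUE)[[1]]
    if (length(parts) == 2) kv[[parts[1]]] <- parts[2]
  }
  kv
}

#' Read an extended-XYZ dataset
#'
#' Frames are: an atom-count line; a comment line with `key=value` pairs
#' (`energy=<hartree>`, `level=<tag>`, optionally `role=reference`); then
#' one line per atom with the element label, x, y, z in angstroms and
#' optionally three force columns in hartree/bohr (stored as gradients,
#' i.e. negated). Coordinates are converted to bohr on read. A frame
#' tagged `role=reference` becomes the dataset reference instead of a
#' record. An empty file yields an empty dataset.
#'
#' @param path file path.
#' @return an [energy_dataset()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  records <- list()
  reference <- NULL
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    frame <- frame + 1L
    if (is.na(n) || n < 1) {
      stop(sprintf("malformed frame %d at line %d: expected an atom count, got '%s'",
                   frame, i, trimws(lines[i])))
    }
    if (i + 1L + n > length(lines)) {
      stop(sprintf("malformed frame %d at line %d: file ends before %d atom lines",
                   frame, i, n))
    }
    kv <- .parse_kv(lines[i + 1L])
    labels <- character(n)
    coords <- matrix(0, n, 3)
    grad <- NULL
    for (a in seq_len(n)) {
      ln <- i + 1L + a
      toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (!(length(toks) %in% c(4L, 7L))) {
        stop(sprintf("malformed frame %d at line %d: expected 4 or 7 columns, got %d",
                     frame, ln, length(toks)))
      }
      vals <- suppressWarnings(as.numeric(toks[-1]))
      if (anyNA(vals)) {
        stop(sprintf("malformed frame %d at line %d: non-numeric coordinate", frame, ln))
      }
      labels[a] <- toks[1]
      coords[a, ] <- vals[1:3] / bohr_to_angstrom
      if (length(toks) == 7L) {
        if (is.null(grad)) grad <- matrix(0, n, 3)
        grad[a, ] <- -vals[4:6]            # force columns -> gradient
      }
    }
    energy <- if (!is.null(kv$energy)) as.numeric(kv$energy) else NA_real_
    geom <- geometry(labels, coords)
    if (identical(kv$role, "reference")) {
      reference <- list(geometry = geom, energy = energy)
    } else {
      records[[length(records) + 1L]] <-
        list(geometry = geom, energy = energy,
             gradient = if (is.null(grad)) NULL else as.vector(t(grad)),
             level = kv$level %||% NA_character_)
    }
    i <- i + 2L + n
  }
  energy_dataset(records, reference = reference)
}

.write_frame <- function(con, geom, energy, gradient, level, role = NULL) {
  n <- nrow(geom$coords)
  writeLines(as.character(n), con)
  kv <- sprintf("energy=%.17g", energy)
  if (!is.null(level) && !is.na(level)) kv <- paste(kv, sprintf("level=%s", level))
  if (!is.null(role)) kv <- paste(kv, sprintf("role=%s", role))
  writeLines(kv, con)
  ang <- geom$coords * bohr_to_angstrom
  for (a in seq_len(n)) {
    if (is.null(gradient)) {
      writeLines(sprintf("%s %.17g %.17g %.17g", geom$labels[a],
                         ang[a, 1], ang[a, 2], ang[a, 3]), con)
    } else {
      f <- -gradient[3L * (a - 1L) + 1:3]
      writeLines(sprintf("%s %.17g %.17g %.17g %.17g %.17g %.17g",
                         geom$labels[a], ang[a, 1], ang[a, 2], ang[a, 3],
                         f[1], f[2], f[3]), con)
    }
  }
}

#' Write an extended-XYZ dataset
#'
#' Inverse of [read_xyz()]; the dataset reference, when present, is
#' written as an extra frame tagged `role=reference`.
#'
#' @param ds an [energy_dataset()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_xyz <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(ds$reference)) {
    .write_frame(con, ds$reference$geometry, ds$reference$energy %||% NA_real_,
                 NULL, NULL, role = "reference")
  }
  for (r in ds$records) {
    .write_frame(con, r$geometry, r$energy, r$gradient, r$level)
  }
  invisible(path)
}

# ---- surface serialization -------------------------------------------------

.surface_to_list <- function(s) {
  if (inherits(s, "pip_surface")) {
    list(type = "pip", group_sizes = s$basis$group_sizes,
         max_degree = s$basis$max_degree, n_p = s$basis$n_p,
         lambda = s$lambda, coeffs = s$coeffs)
  } else if (inherits(s, "poly1d_surface")) {
    list(type = "poly1d", coeffs = s$coeffs)
  } else if (inherits(s, "composite_surface")) {
    list(type = "composite", low = .surface_to_list(s$low),
         corr = .surface_to_list(s$corr))
  } else if (inherits(s, "harmonic_surface")) {
    list(type = "harmonic", freqs_cm = s$known$freqs_cm, masses = s$masses)
  } else if (inherits(s, "double_well_1d")) {
    list(type = "double_well_1d", a = s$a, b = s$b, mass = s$mass)
  } else if (inherits(s, "proton_transfer_toy")) {
    list(type = "proton_transfer_toy", params = s$params)
  } else {
    stop("cannot serialize surface of class ", class(s)[1])
  }
}

.surface_from_list <- function(l) {
  switch(l$type,
    pip = {
      basis <- pip_basis(unlist(l$group_sizes), l$max_degree)
      if (basis$n_p != l$n_p) {
        stop(sprintf("surface file inconsistent: stored n_p %d, enumerated %d",
                     l$n_p, basis$n_p))
      }
      pip_surface(basis, unlist(l$coeffs), l$lambda)
    },
    poly1d = poly1d_surface(unlist(l$coeffs)),
    composite = compose_surfaces(.surface_from_list(l$low),
                                 .surface_from_list(l$corr)),
    harmonic = harmonic_surface(unlist(l$freqs_cm), unlist(l$masses)),
    double_well_1d = double_well_1d(l$a, l$b, l$mass),
    proton_transfer_toy = do.call(proton_transfer_toy, l$params),
    stop("unknown surface type in file: ", l$type)
  )
}

#' Write a surface to a JSON container
#'
#' Serializes PIP, 1d-polynomial, composite and analytic surfaces to a
#' versioned JSON container. PIP bases are stored as (designation, degree,
#' coefficient vector): enumeration order is deterministic, so the basis
#' is rebuilt on read and validated against the stored orbit count.
#'
#' @param surface a serializable surface.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_surface <- function(surface, path) {
  obj <- list(format = "deltapes-surface", version = 1L,
              surface = .surface_to_list(surface))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a surface from a JSON container
#'
#' @param path path written by [write_surface()].
#' @return the surface object.
#' @export
read_surface <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "deltapes-surface")) {
    stop("not a surface container: ", path)
  }
  .surface_from_list(obj$surface)
}

# ---- run configuration -----------------------------------------------------

#' Create a run configuration
#'
#' A light container for pipeline settings. Every stochastic stage must
#' receive an explicit seed, so a top-level `seed` is required. The units
#' policy is fixed (file coordinates in angstrom, file energies in
#' hartree, internal atomic units) and recorded in the object.
#'
#' @param seed integer master seed.
#' @param ... named per-stage parameter blocks.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed, ...) {
  if (missing(seed) || is.null(seed)) stop("run_config requires an explicit seed")
  structure(c(list(seed = as.integer(seed),
                   units = list(file_coords = "angstrom",
                                file_energy = "hartree",
                                internal = "atomic")),
              list(...)),
            class = "run_config")
}

#' Read / write run configurations (YAML)
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  l <- yaml::read_yaml(path)
  if (is.null(l$seed)) stop("configuration lacks a seed")
  do.call(run_config, c(list(seed = l$seed),
                        l[setdiff(names(l), c("seed", "units"))]))
}
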