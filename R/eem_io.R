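# Wavelength grids, EEM landscapes, datasets, and the CSV on-disk format.

#' Construct a wavelength grid
#'
#' A grid holds the excitation and emission wavelength axes (in nm) on which
#' every EEM landscape of a study is recorded. Both axes must be strictly
#' increasing with constant spacing; equality of two grids is exact, not
#' tolerance-based.
#'
#' @param excitation Numeric vector of excitation wavelengths (nm).
#' @param emission Numeric vector of emission wavelengths (nm).
#' @return An object of class `wavelength_grid` with elements `excitation`
#'   and `emission`.
#' @seealso [default_grid()] for the standard 200-600 nm, 10 nm-step grid.
#' @export
wavelength_grid <- function(excitation, emission) {
  check_axis <- function(x, name) {
    if (!is.numeric(x) || length(x) < 2L) {
      stop(sprintf("'%s' must be a numeric vector of length >= 2", name),
           call. = FALSE)
    }
    d <- diff(x)
    if (any(d <= 0)) {
      stop(sprintf("'%s' must be strictly increasing", name), call. = FALSE)
    }
    if (max(d) - min(d) > 1e-9) {
      stop(sprintf("'%s' must have constant spacing", name), call. = FALSE)
    }
    as.numeric(x)
  }
  structure(
    list(excitation = check_axis(excitation, "excitation"),
         emission   = check_axis(emission, "emission")),
    class = "wavelength_grid"
  )
}

#' Default 200-600 nm wavelength grid
#'
#' Both monochromators scanned from 200 nm to 600 nm in 10 nm steps, giving
#' 41 points per axis -- the grid on which a full landscape is a 41 x 41
#' intensity matrix.
#'
#' @param start,stop,step Scan range and step in nm.
#' @return A `wavelength_grid`.
#' @export
default_grid <- function(start = 200, stop = 600, step = 10) {
  ax <- seq(start, stop, by = step)
  wavelength_grid(ax, ax)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> excitation %g-%g nm (%d pts), emission %g-%g nm (%d pts)\n",
              min(x$excitation), max(x$excitation), length(x$excitation),
              min(x$emission), max(x$emission), length(x$emission)))
  invisible(x)
}

grids_identical <- function(a, b) {
  identical(a$excitation, b$excitation) && identical(a$emission, b$emission)
}

#' Construct an EEM landscape
#'
#' One sample's fluorescence landscape: an intensity matrix with emission
#' wavelengths along rows and excitation wavelengths along columns.
#'
#' @param grid A `wavelength_grid`.
#' @param intensity Numeric matrix, `length(grid$emission)` rows by
#'   `length(grid$excitation)` columns. NA values are only permitted
#'   transiently between scatter excision and infilling.
#' @param sample_id Character label for the sample.
#' @param allow_na Allow NA intensities (used internally between excision
#'   and infilling).
#' @return An object of class `eem_landscape`.
#' @export
eem_landscape <- function(grid, intensity, sample_id = "sample", allow_na = FALSE) {
  stopifnot(inherits(grid, "wavelength_grid"))
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(grid$emission) ||
      ncol(intensity) != length(grid$excitation)) {
    stop(sprintf("intensity must be %d x %d (emission x excitation), got %d x %d",
                 length(grid$emission), length(grid$excitation),
                 nrow(intensity), ncol(intensity)), call. = FALSE)
  }
  if (!allow_na && !all(is.finite(intensity))) {
    stop("intensity contains non-finite values", call. = FALSE)
  }
  dimnames(intensity) <- list(as.character(grid$emission),
                              as.character(grid$excitation))
  structure(list(grid = grid, intensity = intensity,
                 sample_id = as.character(sample_id)),
            class = "eem_landscape")
}

#' @export
print.eem_landscape <- function(x, ...) {
  cat(sprintf("<eem_landscape> '%s': %d x %d (em x ex), intensity range [%.4g, %.4g]\n",
              x$sample_id, nrow(x$intensity), ncol(x$intensity),
              min(x$intensity, na.rm = TRUE), max(x$intensity, na.rm = TRUE)))
  invisible(x)
}

#' Read an EEM landscape from CSV
#'
#' The dialect stores the literal `em\\ex` in cell (1,1), excitation
#' wavelengths across the first row, emission wavelengths down the first
#' column, and intensities in the body; comma-separated, "." decimal.
#'
#' @param path Path to a CSV file.
#' @param sample_id Sample label; defaults to the file name without extension.
#' @return An `eem_landscape`.
#' @export
read_eem_csv <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("malformed EEM CSV: fewer than 3 rows", call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    stop(sprintf("malformed EEM CSV: ragged rows (row %d has %d columns, expected %d)",
                 which(widths != widths[1])[1], widths[widths != widths[1]][1],
                 widths[1]), call. = FALSE)
  }
  header <- cells[[1]]
  if (!identical(trimws(header[1]), "em\\ex")) {
    stop("malformed EEM CSV: cell (1,1) must be 'em\\ex'", call. = FALSE)
  }
  parse_num <- function(x, row, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !(trimws(x) %in% c("NA", "NaN")))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row %d, column %d: '%s'",
                   row[bad[1]], col[bad[1]], x[bad[1]]), call. = FALSE)
    }
    v
  }
  ex <- parse_num(header[-1], rep(1L, length(header) - 1L), seq_along(header)[-1])
  body <- cells[-1]
  em <- parse_num(vapply(body, `[`, "", 1L), seq_along(body) + 1L,
                  rep(1L, length(body)))
  intensity <- matrix(NA_real_, nrow = length(em), ncol = length(ex))
  for (i in seq_along(body)) {
    intensity[i, ] <- parse_num(body[[i]][-1], rep(i + 1L, length(ex)),
                                seq_along(ex) + 1L)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  eem_landscape(wavelength_grid(ex, em), intensity, sample_id = sample_id)
}

#' Write an EEM landscape to CSV
#'
#' Inverse of [read_eem_csv()]; values are serialized with 12 significant
#' digits so a write/read round trip preserves intensities to well below
#' 1e-9 relative error.
#'
#' @param landscape An `eem_landscape`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_eem_csv <- function(landscape, path) {
  stopifnot(inherits(landscape, "eem_landscape"))
  g <- landscape$grid
  fmt <- function(x) sprintf("%.12g", x)
  header <- paste(c("em\\ex", fmt(g$excitation)), collapse = ",")
  rows <- vapply(seq_along(g$emission), function(i) {
    paste(c(fmt(g$emission[i]), fmt(landscape$intensity[i, ])), collapse = ",")
  }, "")
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop(sprintf("cannot open '%s' for writing: %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Construct an EEM dataset (three-way cube)
#'
#' Internal constructor; most users reach this through [assemble_cube()] or
#' [generate_dataset()]. The cube is indexed (sample, emission, excitation).
#'
#' @param cube 3-way numeric array, samples x emission x excitation.
#' @param grid A `wavelength_grid`.
#' @param concentrations Data frame with a `sample_id` column and one numeric
#'   column per analyte (ug/ml).
#' @param roles Character vector per sample: one of `"calibration"`,
#'   `"prediction"`, `"real"`, `"spiked"`.
#' @return An object of class `eem_dataset`.
#' @export
eem_dataset <- function(cube, grid, concentrations,
                        roles = rep("calibration", dim(cube)[1])) {
  stopifnot(inherits(grid, "wavelength_grid"), is.array(cube),
            length(dim(cube)) == 3L)
  if (dim(cube)[1] != nrow(concentrations)) {
    stop("cube first dimension must equal the number of concentration rows",
         call. = FALSE)
  }
  if (dim(cube)[2] != length(grid$emission) ||
      dim(cube)[3] != length(grid$excitation)) {
    stop("cube emission/excitation dimensions do not match the grid", call. = FALSE)
  }
  if (!"sample_id" %in% names(concentrations)) {
    stop("concentration table must have a 'sample_id' column", call. = FALSE)
  }
  ana <- analyte_names(concentrations)
  if (length(ana) == 0L) stop("concentration table has no analyte columns", call. = FALSE)
  conc_vals <- as.matrix(concentrations[ana])
  if (any(conc_vals < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  roles <- as.character(roles)
  if (length(roles) != dim(cube)[1]) stop("one role per sample required", call. = FALSE)
  structure(list(cube = cube, grid = grid,
                 concentrations = as.data.frame(concentrations),
                 roles = roles),
            class = "eem_dataset")
}

analyte_names <- function(concentrations) {
  setdiff(names(concentrations), c("sample_id", "role"))
}

#' @export
print.eem_dataset <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<eem_dataset> %d samples x %d emission x %d excitation; analytes: %s\n",
              d[1], d[2], d[3],
              paste(analyte_names(x$concentrations), collapse = ", ")))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$roles)), table(x$roles)),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a dataset
#' @param dataset An `eem_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) dim(dataset$cube)[1]

#' Extract one sample from a dataset as a landscape
#' @param dataset An `eem_dataset`.
#' @param i Sample index.
#' @return An `eem_landscape`.
#' @export
dataset_landscape <- function(dataset, i) {
  eem_landscape(dataset$grid, dataset$cube[i, , ],
                sample_id = dataset$concentrations$sample_id[i],
                allow_na = TRUE)
}

#' Subset a dataset by sample index
#' @param dataset An `eem_dataset`.
#' @param idx Integer sample indices.
#' @return An `eem_dataset` with those samples, in the given order.
#' @export
dataset_subset <- function(dataset, idx) {
  eem_dataset(dataset$cube[idx, , , drop = FALSE], dataset$grid,
              dataset$concentrations[idx, , drop = FALSE],
              roles = dataset$roles[idx])
}

#' Assemble landscapes into a three-way cube
#'
#' Stacks per-sample landscapes into a (samples x emission x excitation)
#' array aligned to a concentration table, the layout on which the trilinear
#' N-PLS model operates. Samples are stacked in the table's row order.
#'
#' @param landscapes List of `eem_landscape` objects sharing one grid.
#' @param concentration_table Data frame with `sample_id`, optionally `role`,
#'   and one numeric column per analyte (ug/ml). `sample_id`s must match the
#'   landscapes one-to-one.
#' @return An `eem_dataset`.
#' @export
assemble_cube <- function(landscapes, concentration_table) {
  if (length(landscapes) == 0L) stop("no landscapes supplied", call. = FALSE)
  if (!all(vapply(landscapes, inherits, TRUE, "eem_landscape"))) {
    stop("all elements must be eem_landscape objects", call. = FALSE)
  }
  grid <- landscapes[[1]]$grid
  for (l in landscapes[-1]) {
    if (!grids_identical(grid, l$grid)) {
      stop(sprintf("incompatible grids: sample '%s' differs from sample '%s'",
                   l$sample_id, landscapes[[1]]$sample_id), call. = FALSE)
    }
  }
  ids <- vapply(landscapes, `[[`, "", "sample_id")
  tab_ids <- as.character(concentration_table$sample_id)
  if (anyDuplicated(ids)) stop("duplicate sample_ids among landscapes", call. = FALSE)
  missing_l <- setdiff(tab_ids, ids)
  extra_l <- setdiff(ids, tab_ids)
  if (length(missing_l) || length(extra_l)) {
    stop(sprintf("sample_id alignment failure: missing landscapes [%s]; unmatched landscapes [%s]",
                 paste(missing_l, collapse = ", "),
                 paste(extra_l, collapse = ", ")), call. = FALSE)
  }
  ord <- match(tab_ids, ids)
  cube <- array(NA_real_, dim = c(length(ord), length(grid$emission),
                                  length(grid$excitation)))
  for (i in seq_along(ord)) cube[i, , ] <- landscapes[[ord[i]]]$intensity
  roles <- if ("role" %in% names(concentration_table)) {
    as.character(concentration_table$role)
  } else {
    rep("calibration", length(ord))
  }
  eem_dataset(cube, grid, concentration_table, roles = roles)
}

#' Write a concentration manifest CSV
#'
#' Columns: `sample_id`, `role`, then one column per analyte in ug/ml.
#'
#' @param dataset An `eem_dataset`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_manifest_csv <- function(dataset, path) {
  tab <- dataset$concentrations
  tab$role <- dataset$roles
  ana <- analyte_names(tab)
  tab <- tab[c("sample_id", "role", ana)]
  write_numeric_csv(tab, path)
  invisible(path)
}

#' Read a concentration manifest CSV
#' @param path Path to a manifest written by [write_manifest_csv()].
#' @return Data frame with `sample_id`, `role`, and analyte columns.
#' @export
read_manifest_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# CSV writer with stable 12-significant-digit numeric formatting, so that
# identical inputs produce byte-identical files.
write_numeric_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.12g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
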