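# Scatter excision and infilling, contour extraction, calibration split.

#' Build a Rayleigh/Raman scatter mask
#'
#' Marks the cells of an EEM landscape that lie on scatter ridges, which
#' carry no analyte information: first-order Rayleigh (`|em - ex| <= w1`),
#' second-order Rayleigh (`|em - 2 ex| <= w2`), and the solvent Raman band
#' at a fixed wavenumber shift from excitation (`|em - em_Raman(ex)| <= wR`).
#' A width of zero keeps exactly the cells on the ridge line (for Raman the
#' line rarely hits grid points, so `wR = 0` usually masks nothing).
#'
#' @param grid A `wavelength_grid`.
#' @param w1,w2,wR Half-widths in nm for the three ridges; all >= 0.
#' @param raman_shift_cm1 Raman shift in wavenumbers (default 3400, aqueous).
#' @return A `scatter_mask` with a logical emission x excitation matrix
#'   (`TRUE` = excise).
#' @export
build_scatter_mask <- function(grid, w1 = 15, w2 = 15, wR = 10,
                               raman_shift_cm1 = 3400) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (w1 < 0 || w2 < 0 || wR < 0) stop("widths must be >= 0", call. = FALSE)
  em <- grid$emission
  ex <- grid$excitation
  eps <- 1e-9
  first  <- abs(outer(em, ex, `-`)) <= w1 + eps
  second <- abs(outer(em, 2 * ex, `-`)) <= w2 + eps
  raman  <- abs(outer(em, raman_emission_nm(ex, raman_shift_cm1), `-`)) <= wR + eps
  structure(list(grid = grid, mask = first | second | raman,
                 components = list(first_order = first, second_order = second,
                                   raman = raman),
                 widths = c(w1 = w1, w2 = w2, wR = wR),
                 raman_shift_cm1 = raman_shift_cm1),
            class = "scatter_mask")
}

#' @export
print.scatter_mask <- function(x, ...) {
  cat(sprintf("<scatter_mask> %d of %d cells excised (w1=%g, w2=%g, wR=%g nm)\n",
              sum(x$mask), length(x$mask),
              x$widths["w1"], x$widths["w2"], x$widths["wR"]))
  invisible(x)
}

#' Excise masked cells and infill by interpolation
#'
#' Scatter cells are removed and refilled with values consistent with the
#' surrounding fluorescence: a one-dimensional natural cubic spline along
#' the emission axis through the unmasked cells of each excitation column,
#' evaluated at the masked wavelengths (values beyond the outermost anchors
#' are held constant). Interpolation only ever reads unmasked cells, so the
#' operation is exactly idempotent and exact on affine intensity surfaces;
#' the spline's curvature tracking keeps the error small where a scatter
#' band cuts across a fluorescence band apex, which is where straight-line
#' infill is visibly biased. A fully masked excitation column has no
#' anchors and falls back to zero fill with a warning.
#'
#' @param landscape An `eem_landscape`.
#' @param mask A `scatter_mask` on the same grid.
#' @return An `eem_landscape` with no NA values; unmasked cells unchanged.
#' @seealso [zero_nonfluorescent()] for the below-diagonal cleanup applied
#'   by [preprocess_dataset()].
#' @export
excise_and_interpolate <- function(landscape, mask) {
  stopifnot(inherits(landscape, "eem_landscape"), inherits(mask, "scatter_mask"))
  if (!grids_identical(landscape$grid, mask$grid)) {
    stop("mask grid does not match landscape grid", call. = FALSE)
  }
  em <- landscape$grid$emission
  ex <- landscape$grid$excitation
  M <- mask$mask
  out <- landscape$intensity
  for (k in seq_along(ex)) {
    mk <- M[, k]
    if (!any(mk)) next
    anchors <- which(!mk)
    if (length(anchors) == 0L) {
      warning(sprintf("excitation column %g nm fully masked; zero-filled", ex[k]),
              call. = FALSE)
      out[, k] <- 0
      next
    }
    out[mk, k] <- infill_column(em[anchors], out[anchors, k], em[mk])
  }
  eem_landscape(landscape$grid, out, sample_id = landscape$sample_id)
}

# natural cubic spline through the anchors, clamped to constant beyond the
# outermost anchors; degenerates gracefully for < 3 anchors
infill_column <- function(x, y, xout) {
  xq <- pmin(pmax(xout, min(x)), max(x))
  if (length(x) == 1L) return(rep(y, length(xout)))
  if (length(x) == 2L) return(stats::approx(x, y, xout = xq, rule = 2)$y)
  stats::spline(x, y, xout = xq, method = "natural")$y
}

#' Zero the non-fluorescent below-diagonal triangle
#'
#' Cells with emission wavelength shorter than the excitation wavelength
#' cannot contain (Stokes) fluorescence; outside the masked scatter bands
#' they are set to zero so that residual baseline there never enters the
#' calibration models.
#'
#' @param landscape An `eem_landscape`.
#' @param mask A `scatter_mask` whose band cells are left untouched.
#' @return An `eem_landscape`.
#' @export
zero_nonfluorescent <- function(landscape, mask) {
  stopifnot(inherits(landscape, "eem_landscape"), inherits(mask, "scatter_mask"))
  out <- landscape$intensity
  tri <- outer(landscape$grid$emission, landscape$grid$excitation, `<`) &
    !mask$mask
  out[tri] <- 0
  eem_landscape(landscape$grid, out, sample_id = landscape$sample_id)
}

#' Apply scatter excision, infilling, and triangle zeroing to a dataset
#'
#' Runs [excise_and_interpolate()] on every sample and then
#' [zero_nonfluorescent()], the standard preparation before contour
#' extraction or cube modelling. The spline infill is a fixed linear map of
#' the unmasked cells (it depends only on the mask geometry), so it is
#' precomputed per excitation column and reused across samples.
#'
#' @param dataset An `eem_dataset`.
#' @param mask A `scatter_mask` on the dataset grid.
#' @return An `eem_dataset` with every landscape processed.
#' @export
preprocess_dataset <- function(dataset, mask) {
  stopifnot(inherits(dataset, "eem_dataset"), inherits(mask, "scatter_mask"))
  if (!grids_identical(dataset$grid, mask$grid)) {
    stop("mask grid does not match dataset grid", call. = FALSE)
  }
  em <- dataset$grid$emission
  ex <- dataset$grid$excitation
  M <- mask$mask
  tri <- outer(em, ex, `<`) & !M
  # per-column infill operators: masked values = S %*% values[anchors]
  maps <- lapply(seq_along(ex), function(k) {
    mk <- which(M[, k])
    if (length(mk) == 0L) return(NULL)
    anchors <- which(!M[, k])
    if (length(anchors) == 0L) {
      warning(sprintf("excitation column %g nm fully masked; zero-filled", ex[k]),
              call. = FALSE)
      return(list(masked = mk, zerofill = TRUE))
    }
    S <- vapply(seq_along(anchors), function(a) {
      basis <- numeric(length(anchors))
      basis[a] <- 1
      infill_column(em[anchors], basis, em[mk])
    }, numeric(length(mk)))
    list(masked = mk, zerofill = FALSE, anchors = anchors,
         S = matrix(S, nrow = length(mk)))
  })
  cube <- dataset$cube
  for (i in seq_len(n_samples(dataset))) {
    mat <- cube[i, , ]
    for (k in seq_along(ex)) {
      mp <- maps[[k]]
      if (is.null(mp)) next
      if (mp$zerofill) {
        mat[mp$masked, k] <- 0
      } else {
        mat[mp$masked, k] <- as.numeric(mp$S %*% mat[mp$anchors, k])
      }
    }
    mat[tri] <- 0
    cube[i, , ] <- mat
  }
  eem_dataset(cube, dataset$grid, dataset$concentrations, roles = dataset$roles)
}

#' Contour extraction policy
#'
#' Contour values reduce a landscape to the emission vector at one fixed
#' excitation wavelength. `fixed` uses a stated excitation; `max_energy`
#' chooses the excitation column with the largest summed intensity (over
#' the calibration set when applied to a dataset, so no information leaks
#' from held-out samples).
#'
#' @param type `"fixed"` or `"max_energy"`.
#' @param excitation Excitation wavelength in nm (required for `"fixed"`).
#' @return A `contour_policy`.
#' @export
contour_policy <- function(type = c("max_energy", "fixed"), excitation = NULL) {
  type <- match.arg(type)
  if (type == "fixed" && is.null(excitation)) {
    stop("fixed policy requires an excitation wavelength", call. = FALSE)
  }
  structure(list(type = type, excitation = excitation), class = "contour_policy")
}

resolve_excitation_column <- function(grid, policy, energy_per_column) {
  if (policy$type == "fixed") {
    k <- which(grid$excitation == policy$excitation)
    if (length(k) != 1L) {
      stop(sprintf("excitation %g nm is not on the grid", policy$excitation),
           call. = FALSE)
    }
    k
  } else {
    which.max(energy_per_column)
  }
}

#' Extract the contour vector of one landscape
#'
#' @param landscape An `eem_landscape`.
#' @param policy A `contour_policy`; with `max_energy` the column is chosen
#'   from this landscape alone (use [extract_contours()] for a dataset-level
#'   choice).
#' @return A `contour_vector`: emission-wavelength intensities at the chosen
#'   excitation, with `excitation_used` recorded.
#' @export
extract_contour <- function(landscape, policy = contour_policy()) {
  stopifnot(inherits(landscape, "eem_landscape"), inherits(policy, "contour_policy"))
  k <- resolve_excitation_column(landscape$grid, policy,
                                 colSums(landscape$intensity))
  structure(list(values = as.numeric(landscape$intensity[, k]),
                 emission = landscape$grid$emission,
                 excitation_used = landscape$grid$excitation[k],
                 sample_id = landscape$sample_id),
            class = "contour_vector")
}

#' Extract contour vectors for every sample of a dataset
#'
#' With the `max_energy` policy the excitation column is chosen once, from
#' the summed intensity of the calibration-role samples only, and applied
#' to every sample.
#'
#' @param dataset An `eem_dataset`.
#' @param policy A `contour_policy`.
#' @param cal_idx Sample indices used to choose the column under
#'   `max_energy`; defaults to samples with role `"calibration"` (all
#'   samples if none are tagged).
#' @return A list with `X` (samples x emission matrix, rows named by
#'   sample_id, columns by emission nm) and `excitation_used` (nm).
#' @export
extract_contours <- function(dataset, policy = contour_policy(), cal_idx = NULL) {
  stopifnot(inherits(dataset, "eem_dataset"))
  if (is.null(cal_idx)) {
    cal_idx <- which(dataset$roles == "calibration")
    if (length(cal_idx) == 0L) cal_idx <- seq_len(n_samples(dataset))
  }
  energy <- colSums(apply(dataset$cube[cal_idx, , , drop = FALSE], c(2, 3), sum))
  k <- resolve_excitation_column(dataset$grid, policy, energy)
  X <- dataset$cube[, , k, drop = FALSE]
  dim(X) <- dim(dataset$cube)[1:2]
  dimnames(X) <- list(dataset$concentrations$sample_id,
                      as.character(dataset$grid$emission))
  list(X = X, excitation_used = dataset$grid$excitation[k])
}

#' Split a dataset into calibration and prediction sets
#'
#' The calibration size is `round-half-up(cal_fraction * n)`, clamped to
#' `[1, n - 1]`; 21 samples at 3/4 give the conventional 16/5 split. The
#' selection is deterministic and concentration-stratified: samples are
#' ranked by the target analyte's concentration and every `floor(n/n_pred)`-th
#' rank goes to the prediction set, so held-out samples span the whole
#' concentration range.
#'
#' @param dataset An `eem_dataset` with >= 2 samples.
#' @param cal_fraction Fraction in (0, 1); default 3/4.
#' @param analyte Analyte whose concentration drives the stratification;
#'   defaults to the first analyte column.
#' @return List with elements `calibration` and `prediction`, both
#'   `eem_dataset`s whose roles are set accordingly.
#' @export
split_calibration <- function(dataset, cal_fraction = 3 / 4, analyte = NULL) {
  stopifnot(inherits(dataset, "eem_dataset"))
  n <- n_samples(dataset)
  if (n < 2) stop("need at least 2 samples to split", call. = FALSE)
  if (cal_fraction <= 0 || cal_fraction >= 1) {
    stop("cal_fraction must be in (0, 1)", call. = FALSE)
  }
  n_cal <- floor(cal_fraction * n + 0.5)  # round half up
  n_cal <- min(max(n_cal, 1L), n - 1L)
  n_pred <- n - n_cal
  if (is.null(analyte)) analyte <- analyte_names(dataset$concentrations)[1]
  conc <- dataset$concentrations[[analyte]]
  if (is.null(conc)) stop(sprintf("unknown analyte '%s'", analyte), call. = FALSE)
  ranks <- order(conc)  # stable for ties
  stride <- floor(n / n_pred)
  pred_idx <- sort(ranks[stride * seq_len(n_pred)])
  cal_idx <- setdiff(seq_len(n), pred_idx)
  cal <- dataset_subset(dataset, cal_idx)
  pred <- dataset_subset(dataset, pred_idx)
  cal$roles <- rep("calibration", length(cal_idx))
  pred$roles <- rep("prediction", length(pred_idx))
  list(calibration = cal, prediction = pred)
}
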