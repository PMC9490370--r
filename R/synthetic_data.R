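# Synthetic EEM generation: trilinear two-fluorophore signals with
# Rayleigh/Raman scatter ridges, additive noise, and spiked/unspiked pairs.

#' Spectral profile on one grid axis
#'
#' A non-negative excitation or emission band shape, rescaled to unit
#' maximum so that an analyte's absolute intensity is carried entirely by
#' its sensitivity.
#'
#' @param values Non-negative numeric vector on the grid axis.
#' @param axis `"emission"` or `"excitation"`.
#' @return A `spectral_profile`.
#' @export
spectral_profile <- function(values, axis = c("emission", "excitation")) {
  axis <- match.arg(axis)
  values <- as.numeric(values)
  if (any(values < 0)) stop("profile values must be >= 0", call. = FALSE)
  m <- max(values)
  if (m <= 0) stop("profile must have a positive maximum", call. = FALSE)
  structure(list(axis = axis, values = values / m), class = "spectral_profile")
}

#' Gaussian band profile
#'
#' `values[j] = exp(-(lambda_j - center)^2 / (2 width^2))`, rescaled to unit
#' maximum over the grid points. `width` is the Gaussian sigma in nm.
#'
#' @param center_nm Band center (nm).
#' @param width_nm Gaussian sigma (nm), must be positive.
#' @param axis `"emission"` or `"excitation"`.
#' @param grid A `wavelength_grid`.
#' @return A `spectral_profile`.
#' @export
make_gaussian_profile <- function(center_nm, width_nm,
                                  axis = c("emission", "excitation"),
                                  grid = default_grid()) {
  axis <- match.arg(axis)
  if (width_nm <= 0) stop("width_nm must be positive", call. = FALSE)
  lam <- if (axis == "emission") grid$emission else grid$excitation
  spectral_profile(exp(-(lam - center_nm)^2 / (2 * width_nm^2)), axis = axis)
}

#' Analyte specification for simulation
#'
#' @param name Analyte name.
#' @param emission_profile,excitation_profile `spectral_profile` objects on
#'   the simulation grid.
#' @param sensitivity Intensity units per (ug/ml); must be positive.
#' @return An `analyte_spec`.
#' @export
analyte_spec <- function(name, emission_profile, excitation_profile, sensitivity) {
  stopifnot(inherits(emission_profile, "spectral_profile"),
            inherits(excitation_profile, "spectral_profile"))
  if (emission_profile$axis != "emission" || excitation_profile$axis != "excitation") {
    stop("profiles supplied on the wrong axes", call. = FALSE)
  }
  if (sensitivity <= 0) stop("sensitivity must be positive", call. = FALSE)
  structure(list(name = as.character(name),
                 emission_profile = emission_profile,
                 excitation_profile = excitation_profile,
                 sensitivity = as.numeric(sensitivity)),
            class = "analyte_spec")
}

#' Simulation design
#'
#' Describes a synthetic EEM study: the grid, the analytes with their band
#' shapes and sensitivities, concentration ranges, sample counts, scatter
#' ridge parameters, and the noise level. The defaults emulate a
#' two-coumarin mixture study: 41 x 41 landscapes on the 200-600 nm / 10 nm
#' grid, two heavily overlapping fluorophores (emission-profile correlation
#' above 0.9), standard concentrations spanning 0.002-1.020 ug/ml and
#' 0.009-4.000 ug/ml, 21 mixed standards, first- and second-order Rayleigh
#' plus water-Raman scatter ridges, and 1% additive Gaussian noise.
#'
#' @param grid A `wavelength_grid`.
#' @param analytes List of `analyte_spec`; default two overlapping Gaussians
#'   (A: em 340/35 nm, ex 300/30 nm; B: em 360/40 nm, ex 310/35 nm).
#' @param concentration_ranges Named list of `c(lo, hi)` per analyte (ug/ml).
#' @param n_samples Number of mixed standard samples (>= 2).
#' @param noise_sd Additive Gaussian noise sd as a fraction of the design's
#'   maximum clean signal (`max` over analytes of sensitivity x hi).
#' @param scatter List with elements `rayleigh1`, `rayleigh2`, `raman`, each
#'   `c(amplitude, width)`: amplitude as a fraction of the maximum clean
#'   signal, Gaussian cross-section sigma in nm. `raman_shift_cm1` is the
#'   Raman wavenumber shift from excitation (aqueous solvent, 3400 cm-1).
#' @param interferent Optional `analyte_spec` for an uncalibrated background
#'   fluorophore, with `interferent_range = c(lo, hi)`.
#' @param interferent_range Concentration range of the interferent (ug/ml).
#' @param n_spiked_pairs Number of real-sample surrogate pairs: each pair is
#'   one unspiked sample plus the same sample with a known spike added.
#' @param spike_amounts Named per-analyte spike amount (ug/ml) used for the
#'   spiked member of each pair.
#' @param seed Integer seed; all randomness of [generate_dataset()] and
#'   [simulate_eem()] flows from it.
#' @return A `simulation_design`.
#' @export
simulation_design <- function(grid = default_grid(),
                              analytes = default_analytes(grid),
                              concentration_ranges = list(A = c(0.002, 1.020),
                                                          B = c(0.009, 4.000)),
                              n_samples = 21,
                              noise_sd = 0.01,
                              scatter = list(rayleigh1 = c(0.50, 5),
                                             rayleigh2 = c(0.50, 5),
                                             raman = c(0.05, 5)),
                              raman_shift_cm1 = 3400,
                              interferent = NULL,
                              interferent_range = c(0, 0),
                              n_spiked_pairs = 0,
                              spike_amounts = c(A = 0.48, B = 2.00),
                              seed = 1L) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  nm <- vapply(analytes, `[[`, "", "name")
  names(analytes) <- nm
  if (!setequal(names(concentration_ranges), nm)) {
    stop("concentration_ranges must name every analyte", call. = FALSE)
  }
  for (a in nm) {
    r <- concentration_ranges[[a]]
    if (r[1] < 0 || r[2] <= r[1]) {
      stop(sprintf("invalid concentration range for '%s': need 0 <= lo < hi", a),
           call. = FALSE)
    }
  }
  if (!is.null(interferent) && !inherits(interferent, "analyte_spec")) {
    stop("interferent must be an analyte_spec or NULL", call. = FALSE)
  }
  structure(list(grid = grid, analytes = analytes,
                 concentration_ranges = concentration_ranges,
                 n_samples = as.integer(n_samples),
                 noise_sd = noise_sd, scatter = scatter,
                 raman_shift_cm1 = raman_shift_cm1,
                 interferent = interferent,
                 interferent_range = interferent_range,
                 n_spiked_pairs = as.integer(n_spiked_pairs),
                 spike_amounts = spike_amounts,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Default pair of strongly overlapping analytes
#'
#' Two single-Gaussian fluorophores whose emission bands overlap heavily
#' (Pearson correlation of the profiles > 0.9), the failure mode that makes
#' univariate fluorescence quantification impossible and motivates
#' multivariate calibration. Sensitivities are set so both analytes reach a
#' comparable maximum signal at the top of their concentration ranges.
#'
#' @param grid A `wavelength_grid`.
#' @return List of two `analyte_spec` objects named `A` and `B`.
#' @export
default_analytes <- function(grid = default_grid()) {
  list(
    A = analyte_spec("A",
                     make_gaussian_profile(340, 35, "emission", grid),
                     make_gaussian_profile(300, 30, "excitation", grid),
                     sensitivity = 1000),
    B = analyte_spec("B",
                     make_gaussian_profile(360, 40, "emission", grid),
                     make_gaussian_profile(310, 35, "excitation", grid),
                     sensitivity = 250)
  )
}

# Reference intensity scale of a design: the largest clean signal any single
# analyte can reach (sensitivity x top of range). Noise sd and scatter
# amplitudes are fractions of this, so they do not depend on the particular
# sample's concentrations (scatter is physically concentration-independent).
design_signal_scale <- function(design) {
  hi <- vapply(names(design$analytes),
               function(a) design$concentration_ranges[[a]][2], 0)
  sens <- vapply(design$analytes, `[[`, 0, "sensitivity")
  max(sens * hi)
}

# Clean trilinear signal for one sample: sum over analytes of
# c * s * em-profile (outer) ex-profile.
clean_signal <- function(concentrations, design) {
  J <- length(design$grid$emission)
  K <- length(design$grid$excitation)
  S <- matrix(0, J, K)
  for (a in names(design$analytes)) {
    spec <- design$analytes[[a]]
    c_a <- concentrations[[a]]
    if (c_a > 0) {
      S <- S + c_a * spec$sensitivity *
        tcrossprod(spec$emission_profile$values, spec$excitation_profile$values)
    }
  }
  if (!is.null(design$interferent) && !is.null(concentrations[["interferent"]])) {
    spec <- design$interferent
    S <- S + concentrations[["interferent"]] * spec$sensitivity *
      tcrossprod(spec$emission_profile$values, spec$excitation_profile$values)
  }
  S
}

# Emission wavelength of the solvent Raman band for a given excitation, at a
# fixed wavenumber shift: 1/lambda_em = 1/lambda_ex - shift.
raman_emission_nm <- function(lambda_ex, shift_cm1) {
  shift_nm1 <- shift_cm1 * 1e-7  # cm^-1 -> nm^-1
  1 / (1 / lambda_ex - shift_nm1)
}

# Scatter ridge surface: Gaussian cross-sections along the first-order
# Rayleigh line (em = ex), second-order line (em = 2 ex) and the Raman line.
scatter_signal <- function(design) {
  em <- design$grid$emission
  ex <- design$grid$excitation
  scale <- design_signal_scale(design)
  ridge <- function(target_em, amp, width) {
    if (amp <= 0) return(matrix(0, length(em), length(ex)))
    d <- outer(em, target_em, `-`)
    amp * scale * exp(-d^2 / (2 * width^2))
  }
  s <- design$scatter
  ridge(ex, s$rayleigh1[1], s$rayleigh1[2]) +
    ridge(2 * ex, s$rayleigh2[1], s$rayleigh2[2]) +
    ridge(raman_emission_nm(ex, design$raman_shift_cm1), s$raman[1], s$raman[2])
}

#' Simulate one EEM landscape
#'
#' Intensity is the trilinear analyte signal plus concentration-independent
#' scatter ridges plus i.i.d. additive Gaussian noise:
#' `I(j,k) = sum_a c_a s_a em_a[j] ex_a[k] + scatter(j,k) + eps(j,k)` with
#' `sd(eps) = noise_sd x` the design's maximum clean signal. Reproducible
#' from `seed`.
#'
#' @param concentrations Named list/vector, one value per analyte (plus
#'   `interferent` if the design has one), all >= 0, in ug/ml.
#' @param design A `simulation_design`.
#' @param sample_id Label for the landscape.
#' @param seed Integer seed; defaults to the design seed.
#' @return An `eem_landscape`.
#' @export
simulate_eem <- function(concentrations, design, sample_id = "sim",
                         seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  simulate_eem_impl(concentrations, design, sample_id, seed,
                    scatter = scatter_signal(design),
                    noise_scale = design_signal_scale(design))
}

# workhorse shared with generate_dataset(), which precomputes the
# concentration-independent scatter surface and the noise scale once
simulate_eem_impl <- function(concentrations, design, sample_id, seed,
                              scatter, noise_scale) {
  concentrations <- as.list(concentrations)
  for (a in names(design$analytes)) {
    if (is.null(concentrations[[a]])) {
      stop(sprintf("missing concentration for analyte '%s'", a), call. = FALSE)
    }
    if (concentrations[[a]] < 0) {
      stop(sprintf("negative concentration for analyte '%s'", a), call. = FALSE)
    }
  }
  S <- clean_signal(concentrations, design) + scatter
  if (design$noise_sd > 0) {
    sdv <- design$noise_sd * noise_scale
    S <- S + with_seed(seed, matrix(stats::rnorm(length(S), sd = sdv),
                                    nrow(S), ncol(S)))
  }
  eem_landscape(design$grid, S, sample_id = sample_id)
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's RNG afterwards so simulation never perturbs ambient randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic child seed for sample i of a design (kept below 2^31).
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919) %% 2147483647)
}

#' Generate a full synthetic EEM dataset
#'
#' Draws per-analyte concentrations independently and log-uniformly over the
#' configured ranges (the ranges span about three orders of magnitude, so a
#' uniform draw would starve the low end), simulates every landscape, and
#' assembles the cube. When `n_spiked_pairs > 0`, the design's pairs of
#' real-sample surrogates are appended: for each pair the unspiked member
#' (role `"real"`) has a random base concentration and the spiked member
#' (role `"spiked"`) has base + spike, with the spike amount recorded by
#' [spike_table()].
#'
#' @param design A `simulation_design`.
#' @return An `eem_dataset`; standards carry role `"calibration"`.
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  if (design$n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  ana <- names(design$analytes)
  n_std <- design$n_samples
  n_pair <- design$n_spiked_pairs

  draw <- with_seed(design$seed, {
    conc <- sapply(ana, function(a) {
      r <- design$concentration_ranges[[a]]
      lo <- max(r[1], 1e-12)
      exp(stats::runif(n_std + n_pair, log(lo), log(r[2])))
    })
    conc <- matrix(conc, ncol = length(ana),
                   dimnames = list(NULL, ana))
    intf <- if (!is.null(design$interferent)) {
      stats::runif(n_std + n_pair, design$interferent_range[1],
                   design$interferent_range[2])
    } else NULL
    list(conc = conc, intf = intf)
  })

  scatter <- scatter_signal(design)
  noise_scale <- design_signal_scale(design)
  rows <- list(); landscapes <- list(); roles <- character(0)
  add_sample <- function(id, conc_row, role, idx) {
    conc_list <- as.list(conc_row[ana])
    if (!is.null(draw$intf)) conc_list$interferent <- draw$intf[idx]
    l <- simulate_eem_impl(conc_list, design, sample_id = id,
                           seed = child_seed(design$seed, length(landscapes) + 1L),
                           scatter = scatter, noise_scale = noise_scale)
    landscapes[[length(landscapes) + 1L]] <<- l
    rows[[length(rows) + 1L]] <<- c(list(sample_id = id), as.list(conc_row[ana]))
    roles[length(roles) + 1L] <<- role
  }

  for (i in seq_len(n_std)) {
    add_sample(sprintf("std%02d", i), draw$conc[i, ], "calibration", i)
  }
  for (p in seq_len(n_pair)) {
    i <- n_std + p
    base <- draw$conc[i, ]
    add_sample(sprintf("real%02d", p), base, "real", i)
    spiked <- base + design$spike_amounts[ana]
    add_sample(sprintf("spiked%02d", p), spiked, "spiked", i)
  }

  tab <- do.call(rbind, lapply(rows, as.data.frame))
  tab$sample_id <- as.character(tab$sample_id)
  assemble_cube(landscapes, cbind(tab, role = roles))
}

#' Spike bookkeeping table for a generated dataset
#'
#' @param design The `simulation_design` used to generate the dataset.
#' @return Data frame with one row per (pair, analyte): unspiked and spiked
#'   sample ids and the spike amount in ug/ml; zero rows if the design has
#'   no pairs.
#' @export
spike_table <- function(design) {
  ana <- names(design$analytes)
  n_pair <- design$n_spiked_pairs
  if (n_pair == 0L) {
    return(data.frame(pair = integer(0), analyte = character(0),
                      unspiked_id = character(0), spiked_id = character(0),
                      spike = numeric(0)))
  }
  expand <- expand.grid(analyte = ana, pair = seq_len(n_pair),
                        stringsAsFactors = FALSE)
  data.frame(pair = expand$pair, analyte = expand$analyte,
             unspiked_id = sprintf("real%02d", expand$pair),
             spiked_id = sprintf("spiked%02d", expand$pair),
             spike = as.numeric(design$spike_amounts[expand$analyte]))
}
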