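# Synthetic-data generators with known ground truth: idealized 7-helix
# Calpha bundles and two-cluster structure families, transient-absorption
# surfaces from a sequential photocycle with Gaussian-band state spectra,
# beta-sheet hydrogen-bond fixtures, and sigmoidal thermal-unfolding curves.
# Every generator is deterministic given its seed.

#' Build an idealized transmembrane helical bundle
#'
#' Ideal alpha-helix backbone geometry (1.5 angstrom rise and 100 degrees
#' twist per residue, Calpha helix radius 2.3 angstrom) placed on a ring
#' with alternating up/down helix orientation — a caricature of a
#' 7-transmembrane rhodopsin fold. Poly-alanine with N, CA, C and O atoms so
#' the result also feeds hydrogen-bond and surface-area code.
#'
#' @param n_helices Number of helices (default 7).
#' @param residues_per_helix Residues per helix (default 25).
#' @param ring_radius Ring radius in angstrom (default 12).
#' @param id Model label.
#' @return A [structure_model()] with a single chain A.
#' @export
make_helical_bundle <- function(n_helices = 7, residues_per_helix = 25,
                                ring_radius = 12, id = "bundle") {
  stopifnot(n_helices >= 1, residues_per_helix >= 2, ring_radius > 0)
  rise <- 1.5
  twist <- 100 * pi / 180
  # backbone atoms on cylinders: radius, phase offset (rad), z offset
  geom <- list(
    N  = c(r = 1.60, dphi = -28 * pi / 180, dz = -0.60),
    CA = c(r = 2.30, dphi = 0,              dz = 0),
    C  = c(r = 1.70, dphi = 26 * pi / 180,  dz = 0.55),
    O  = c(r = 2.00, dphi = 30 * pi / 180,  dz = 1.70)
  )
  elements <- c(N = "N", CA = "C", C = "C", O = "O")
  rows <- vector("list", n_helices)
  resno0 <- 0L
  half_len <- rise * (residues_per_helix - 1) / 2
  for (h in seq_len(n_helices)) {
    ang <- 2 * pi * (h - 1) / n_helices
    centre <- c(ring_radius * cos(ang), ring_radius * sin(ang), 0)
    up <- h %% 2 == 1
    per_res <- lapply(seq_len(residues_per_helix), function(i) {
      phi <- (i - 1) * twist
      z <- (i - 1) * rise - half_len
      at <- lapply(names(geom), function(a) {
        g <- geom[[a]]
        local <- c(g[["r"]] * cos(phi + g[["dphi"]]),
                   g[["r"]] * sin(phi + g[["dphi"]]),
                   z + g[["dz"]])
        if (!up) local <- c(local[1], -local[2], -local[3])
        tibble(resno = resno0 + i, resid = "ALA", elety = a,
               element = elements[[a]],
               x = centre[1] + local[1], y = centre[2] + local[2],
               z = centre[3] + local[3])
      })
      bind_rows(at)
    })
    rows[[h]] <- bind_rows(per_res)
    resno0 <- resno0 + residues_per_helix
  }
  atoms <- bind_rows(rows) |>
    mutate(chain = "A", ins = "", het = FALSE, o = 1, b = 0) |>
    select("chain", "resno", "ins", "resid", "het", "elety", "element",
           "x", "y", "z", "o", "b")
  structure_model(atoms, id = id)
}

#' Specification of a two-cluster synthetic structure family
#'
#' @param n_per_cluster Members per cluster (default 5).
#' @param sigma_within Isotropic per-atom Gaussian coordinate noise within a
#'   cluster, angstrom (default 0.3).
#' @param between_displacement Rigid displacement (angstrom) applied to a
#'   subset of helices of the second template, creating the between-cluster
#'   structural difference (default 3).
#' @param n_helices,residues_per_helix Bundle geometry (defaults 7 and 25).
#' @param displaced_helices Indices of helices displaced in template B
#'   (default the odd-numbered helices).
#' @param seed Integer RNG seed.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_per_cluster = 5, sigma_within = 0.3,
                        between_displacement = 3, n_helices = 7,
                        residues_per_helix = 25,
                        displaced_helices = NULL, seed = 1) {
  stopifnot(n_per_cluster >= 1, sigma_within >= 0, between_displacement >= 0)
  structure(list(
    n_per_cluster = n_per_cluster, sigma_within = sigma_within,
    between_displacement = between_displacement, n_helices = n_helices,
    residues_per_helix = residues_per_helix,
    displaced_helices = displaced_helices %||%
      seq(1, n_helices, by = 2),
    seed = as.integer(seed)
  ), class = "family_spec")
}

rotation_about_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(u)
}

random_rotation <- function() {
  # uniform rotation from a random unit quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Generate a two-cluster family of helical bundles with planted labels
#'
#' Template A is an ideal bundle; template B displaces a subset of its
#' helices radially by `between_displacement`. Each member is its template
#' plus isotropic per-atom Gaussian noise (`sigma_within`) followed by a
#' random rigid motion, so that superposition must genuinely undo the
#' motion. The planted cluster labels are returned alongside the models.
#'
#' @param spec A [family_spec()].
#' @return A list with `models` (list of [structure_model()]s named
#'   `A1..An, B1..Bn`) and `labels` (tibble `id`, `cluster`).
#' @export
make_structure_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  templ_a <- make_helical_bundle(spec$n_helices, spec$residues_per_helix,
                                 id = "templateA")
  templ_b <- templ_a
  templ_b$id <- "templateB"
  if (spec$between_displacement > 0) {
    # each displaced helix is shifted radially by a third of the nominal
    # displacement and tilted about its centre so the extra displacement
    # grows toward the helix ends; the maximum total Calpha displacement is
    # ~`between_displacement`. Distributing the divergence along the helix
    # emulates how homologous folds actually differ (gradual, not a block
    # shift that outlier rejection would simply discard).
    rph <- spec$residues_per_helix
    half_len <- 1.5 * (rph - 1) / 2
    shift_mag <- spec$between_displacement / 3
    theta <- (spec$between_displacement - shift_mag) / half_len
    for (h in spec$displaced_helices) {
      res_range <- seq((h - 1) * rph + 1, h * rph)
      sel <- templ_b$atoms$resno %in% res_range
      xyz <- as.matrix(templ_b$atoms[sel, c("x", "y", "z")])
      centre <- colMeans(xyz)
      ang <- 2 * pi * (h - 1) / spec$n_helices
      radial <- c(cos(ang), sin(ang), 0)
      R <- rotation_about_axis(radial, theta)  # tilt axis radial, helix axis z
      xyz <- sweep(sweep(xyz, 2, centre) %*% t(R), 2, centre + shift_mag * radial,
                   `+`)
      templ_b$atoms$x[sel] <- xyz[, 1]
      templ_b$atoms$y[sel] <- xyz[, 2]
      templ_b$atoms$z[sel] <- xyz[, 3]
    }
  }
  perturb <- function(templ, new_id) {
    at <- templ$atoms
    n <- nrow(at)
    xyz <- as.matrix(at[, c("x", "y", "z")]) +
      matrix(rnorm(3 * n, sd = spec$sigma_within), n, 3)
    R <- random_rotation()
    t_vec <- runif(3, -20, 20)
    xyz <- sweep(xyz %*% t(R), 2, t_vec, `+`)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    structure_model(at, id = new_id)
  }
  models <- c(
    lapply(seq_len(spec$n_per_cluster), function(i)
      perturb(templ_a, paste0("A", i))),
    lapply(seq_len(spec$n_per_cluster), function(i)
      perturb(templ_b, paste0("B", i)))
  )
  names(models) <- vapply(models, function(m) m$id, character(1))
  labels <- tibble(
    id = names(models),
    cluster = rep(c(1L, 2L), each = spec$n_per_cluster)
  )
  list(models = models, labels = labels)
}

#' Gaussian absorbance band
#'
#' @param wavelengths Wavelength grid, nm.
#' @param lambda_max Band centre, nm.
#' @param fwhm Full width at half maximum, nm.
#' @param peak Peak absorbance.
#' @return Numeric absorbance vector.
#' @export
gaussian_band <- function(wavelengths, lambda_max, fwhm, peak = 1) {
  peak * exp(-4 * log(2) * ((wavelengths - lambda_max) / fwhm)^2)
}

#' Specification of a simulated photocycle experiment
#'
#' Defaults emulate a five-intermediate (K, L, M, N, O) proton-pump
#' photocycle probed between 330 and 700 nm in 10 nm steps, with lifetimes
#' spanning microseconds to a hundred milliseconds, a green-absorbing ground
#' state, a strongly blue-shifted M state, and a red-shifted O state.
#'
#' @param lifetimes State lifetimes in chain order, s.
#' @param states Tibble with columns `state`, `lambda_max`, `fwhm`, `peak`
#'   (one row per intermediate, chain order).
#' @param ground Ground-state band: list with `lambda_max`, `fwhm`, `peak`.
#' @param f Cycling fraction in (0, 1] (0 allowed for degenerate tests).
#' @param noise_sd Additive Gaussian absorbance noise (0 = noiseless); see
#'   also `snr`.
#' @param snr If given, overrides `noise_sd` with
#'   `max(abs(clean)) / snr`.
#' @param wavelengths Wavelength grid, nm.
#' @param t_min,t_max Time span, s.
#' @param points_per_decade Log-uniform time sampling density.
#' @param seed Integer RNG seed.
#' @return A list of class `photocycle_spec`.
#' @export
photocycle_spec <- function(
    lifetimes = c(1.5e-6, 3e-5, 5e-4, 8e-3, 1e-1),
    states = tibble(
      state = c("K", "L", "M", "N", "O"),
      lambda_max = c(590, 510, 410, 530, 630),
      fwhm = c(90, 80, 70, 80, 90),
      peak = c(1.0, 0.9, 0.8, 0.9, 1.0)
    ),
    ground = list(lambda_max = 550, fwhm = 80, peak = 1.0),
    f = 0.3, noise_sd = 0, snr = NULL,
    wavelengths = seq(330, 700, by = 10),
    t_min = 1e-8, t_max = NULL, points_per_decade = 100,
    seed = 1) {
  stopifnot(length(lifetimes) == nrow(states), all(lifetimes > 0),
            f >= 0, f <= 1)
  structure(list(
    lifetimes = lifetimes, states = as_tibble(states), ground = ground,
    f = f, noise_sd = noise_sd, snr = snr, wavelengths = wavelengths,
    t_min = t_min, t_max = t_max %||% (10 * max(lifetimes)),
    points_per_decade = points_per_decade, seed = as.integer(seed)
  ), class = "photocycle_spec")
}

#' Simulate a transient-absorption surface from a sequential photocycle
#'
#' Builds `deltaA(lambda, t) = f * sum_j c_j(t) (S_j(lambda) -
#' S_ground(lambda))` with the state concentrations from the Bateman cascade
#' and Gaussian-band state spectra, samples it on a log-uniform time grid,
#' and adds Gaussian noise. At t much longer than the slowest lifetime the
#' surface relaxes to zero (complete recovery of the ground state). The
#' returned truth record carries everything needed to score parameter
#' recovery.
#'
#' @param spec A [photocycle_spec()].
#' @return A list with `dataset` (a [transient_absorption()]) and `truth`
#'   (list: lifetimes, state table, ground band, f, noise_sd actually used,
#'   state spectra matrix).
#' @export
simulate_photocycle_dataset <- function(spec) {
  stopifnot(inherits(spec, "photocycle_spec"))
  set.seed(spec$seed)
  wl <- spec$wavelengths
  times <- 10^seq(log10(spec$t_min), log10(spec$t_max),
                  by = 1 / spec$points_per_decade)
  ground <- gaussian_band(wl, spec$ground$lambda_max, spec$ground$fwhm,
                          spec$ground$peak)
  S <- t(vapply(seq_len(nrow(spec$states)), function(j) {
    gaussian_band(wl, spec$states$lambda_max[j], spec$states$fwhm[j],
                  spec$states$peak[j])
  }, numeric(length(wl))))                 # states x wl
  conc <- sequential_concentrations(1 / spec$lifetimes, times,
                                    state_names = spec$states$state)
  C <- as.matrix(conc[, spec$states$state])   # n_t x states
  dS <- sweep(S, 2, ground)                   # states x wl
  clean <- spec$f * t(C %*% dS)               # wl x n_t
  noise_sd <- spec$noise_sd
  if (!is.null(spec$snr)) noise_sd <- max(abs(clean)) / spec$snr
  noisy <- clean + matrix(rnorm(length(clean), sd = noise_sd),
                          nrow(clean), ncol(clean))
  truth <- list(
    lifetimes = spec$lifetimes, states = spec$states,
    ground = spec$ground, f = spec$f, noise_sd = noise_sd,
    state_spectra = S, ground_spectrum = ground, clean = clean
  )
  list(dataset = transient_absorption(wl, times, noisy), truth = truth)
}

#' Two antiparallel strands with an exact number of backbone hydrogen bonds
#'
#' A hand-placed beta-sheet-like fixture: chain A contributes `n_bonds`
#' backbone amide donors, chain B the matching carbonyl acceptors at exactly
#' 2.9 angstrom; every other N-O pair is farther than 4.5 angstrom, so the
#' default criteria detect exactly `n_bonds` bonds.
#'
#' @param n_bonds Number of planted hydrogen bonds (>= 1).
#' @return A two-chain [structure_model()].
#' @export
make_sheet_fixture <- function(n_bonds) {
  stopifnot(n_bonds >= 1)
  res_a <- lapply(seq_len(n_bonds), function(k) {
    x0 <- 7 * k
    tibble(
      chain = "A", resno = k, resid = "ALA",
      elety = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = x0 + c(0, 1.45, 2.9, 2.9),
      y = c(0, -0.8, 0, -1.23),
      z = 0
    )
  })
  res_b <- lapply(seq_len(n_bonds), function(k) {
    x0 <- 7 * k
    tibble(
      chain = "B", resno = k, resid = "ALA",
      elety = c("O", "C", "CA", "N"),
      element = c("O", "C", "C", "N"),
      x = x0 + c(0, 1.2, 2.5, 3.5),
      y = c(2.9, 3.6, 4.3, 5.3),
      z = 0
    )
  })
  atoms <- bind_rows(c(res_a, res_b)) |>
    mutate(ins = "", het = FALSE, o = 1, b = 0) |>
    select("chain", "resno", "ins", "resid", "het", "elety", "element",
           "x", "y", "z", "o", "b")
  structure_model(atoms, id = paste0("sheet", n_bonds))
}

#' Simulate a thermal-unfolding ratio curve
#'
#' Sum of logistic sigmoids (one per unfolding transition) on a linear
#' temperature ramp, plus a gentle linear baseline and Gaussian noise —
#' emulating the F350/F330 tryptophan-fluorescence ratio recorded by
#' label-free differential scanning fluorimetry between 15 and 98 degrees C.
#'
#' @param centers Transition midpoints, degrees C.
#' @param widths Logistic widths (scale parameter), degrees C; recycled.
#' @param amplitudes Step heights; recycled.
#' @param noise_sd Additive Gaussian noise (default 5e-4, the smoothness of
#'   a modern scanning-fluorimetry ratio trace).
#' @param baseline Intercept and slope of the linear baseline.
#' @param t_range Temperature span (default 15-98 degrees C).
#' @param step Grid step, degrees C (default 0.25).
#' @param seed Integer RNG seed.
#' @return A tibble with columns `temperature` and `ratio`.
#' @export
simulate_unfolding_curve <- function(centers, widths = 2.5, amplitudes = 0.1,
                                     noise_sd = 5e-4,
                                     baseline = c(0.8, 2e-4),
                                     t_range = c(15, 98), step = 0.25,
                                     seed = 1) {
  set.seed(as.integer(seed))
  tt <- seq(t_range[1], t_range[2], by = step)
  widths <- rep_len(widths, length(centers))
  amplitudes <- rep_len(amplitudes, length(centers))
  y <- baseline[1] + baseline[2] * (tt - t_range[1])
  for (i in seq_along(centers)) {
    y <- y + amplitudes[i] / (1 + exp(-(tt - centers[i]) / widths[i]))
  }
  tibble(temperature = tt, ratio = y + rnorm(length(tt), sd = noise_sd))
}
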