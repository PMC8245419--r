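# Global multiexponential analysis of flash-photolysis transient-absorption
# surfaces and reconstruction of absolute intermediate spectra under a
# sequential irreversible photocycle, plus quasi-logarithmic time compression
# and first-derivative melting-point detection for thermal-unfolding curves.

#' Transient-absorption dataset
#'
#' Container for a flash-photolysis surface: absorbance changes on a
#' wavelength x time grid, with optional per-point inverse-variance weights.
#'
#' @param wavelengths Numeric wavelength grid, nm.
#' @param times Strictly increasing positive times, s, typically spanning
#'   several decades.
#' @param delta_A Numeric matrix, `length(wavelengths)` rows x
#'   `length(times)` columns, of absorbance changes.
#' @param weights Optional matrix of the same shape (default: uniform).
#' @return An object of class `transient_absorption`.
#' @export
transient_absorption <- function(wavelengths, times, delta_A,
                                 weights = NULL) {
  delta_A <- as.matrix(delta_A)
  if (!all(dim(delta_A) == c(length(wavelengths), length(times)))) {
    abort("delta_A must be length(wavelengths) x length(times)")
  }
  if (any(times <= 0) || any(diff(times) <= 0)) {
    abort("times must be positive and strictly increasing")
  }
  if (!all(is.finite(delta_A))) abort("delta_A must be finite")
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == dim(delta_A)) || any(weights < 0)) {
      abort("weights must match delta_A in shape and be non-negative")
    }
  }
  structure(list(wavelengths = wavelengths, times = times,
                 delta_A = delta_A, weights = weights),
            class = "transient_absorption")
}

#' @export
print.transient_absorption <- function(x, ...) {
  cat(sprintf(
    "<transient_absorption> %d wavelengths (%g-%g nm) x %d times (%.3g-%.3g s)\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @rdname transient_absorption
#' @param x A `transient_absorption` object.
#' @param ... Unused.
#' @method tidy transient_absorption
#' @export
tidy.transient_absorption <- function(x, ...) {
  tidyr::expand_grid(wavelength = x$wavelengths, time = x$times) |>
    mutate(delta_A = as.vector(t(x$delta_A)))
}

#' Read / write a transient-absorption surface as delimited text
#'
#' File layout: first row the wavelength grid (nm) with an empty leading
#' cell, first column the time grid (s), body the absorbance changes (rows =
#' times, columns = wavelengths).
#'
#' @param path File path (TSV).
#' @param weights_path Optional matching weights file.
#' @return [read_transient_dataset()]: a [transient_absorption()];
#'   [write_transient_dataset()]: `path`, invisibly.
#' @export
read_transient_dataset <- function(path, weights_path = NULL) {
  m <- as.matrix(utils::read.delim(path, header = TRUE, row.names = 1,
                                   check.names = FALSE))
  wl <- as.numeric(colnames(m))
  times <- as.numeric(rownames(m))
  w <- NULL
  if (!is.null(weights_path)) {
    wm <- as.matrix(utils::read.delim(weights_path, header = TRUE,
                                      row.names = 1, check.names = FALSE))
    w <- t(wm)
  }
  transient_absorption(wl, times, t(m), weights = w)
}

#' @rdname read_transient_dataset
#' @param d A [transient_absorption()].
#' @export
write_transient_dataset <- function(d, path) {
  m <- t(d$delta_A)
  dimnames(m) <- list(format(d$times, digits = 10), d$wavelengths)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Quasi-logarithmic compression of a kinetic trace
#'
#' Bins a densely sampled trace into log-uniform time bins (a fixed number
#' of bins per time decade) and replaces each bin by its mean time and mean
#' signal — the standard reduction of ~32,000-point oscilloscope traces to
#' ~100 points per decade before global fitting. Empty bins are dropped, so
#' the output never has more points than the input.
#'
#' @param times Strictly increasing positive times, s.
#' @param values Numeric vector (same length as `times`) or matrix with
#'   `length(times)` columns (one row per wavelength).
#' @param points_per_decade Bins per factor-of-ten in time (default 100).
#' @return A list with `times` (bin mean times) and `values` (bin means,
#'   same shape convention as the input).
#' @export
quasi_log_compress <- function(times, values, points_per_decade = 100) {
  if (any(times <= 0)) abort("times must be positive for log compression")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  vec <- is.null(dim(values))
  vm <- if (vec) matrix(values, nrow = 1) else as.matrix(values)
  if (ncol(vm) != length(times)) abort("values do not match times")
  lt <- log10(times)
  edges <- seq(lt[1], lt[length(lt)] + 1 / points_per_decade,
               by = 1 / points_per_decade)
  bin <- findInterval(lt, edges, rightmost.closed = TRUE)
  new_t <- as.vector(tapply(times, bin, mean))
  new_v <- t(vapply(seq_len(nrow(vm)), function(r) {
    as.vector(tapply(vm[r, ], bin, mean))
  }, numeric(length(new_t))))
  if (vec) new_v <- as.vector(new_v)
  list(times = unname(new_t), values = unname(new_v))
}

# design matrix of the multiexponential model: one column per lifetime plus
# a constant column for the t -> Inf offset
exp_design <- function(times, tau) {
  cbind(exp(-outer(times, 1 / tau)), 1)
}

# weighted linear amplitude solve at fixed lifetimes; returns coefficients
# ((n+1) x n_wl) and the weighted residual SD
solve_amplitudes <- function(times, Y, W, tau) {
  E <- exp_design(times, tau)
  if (is.null(W)) {
    fit <- tryCatch(qr.solve(E, Y, tol = 1e-12),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    R <- Y - E %*% fit
    list(coef = fit, sd = sqrt(mean(R^2)))
  } else {
    n_wl <- ncol(Y)
    coef <- matrix(0, ncol(E), n_wl)
    ssr <- 0
    for (k in seq_len(n_wl)) {
      sw <- sqrt(W[, k])
      f <- tryCatch(qr.solve(E * sw, Y[, k] * sw, tol = 1e-12),
                    error = function(e) NULL)
      if (is.null(f)) return(NULL)
      coef[, k] <- f
      ssr <- ssr + sum(W[, k] * (Y[, k] - E %*% f)^2)
    }
    list(coef = coef, sd = sqrt(ssr / sum(W)))
  }
}

#' Global multiexponential fit of a transient-absorption surface
#'
#' Fits `delta_A(lambda, t) = sum_i A_i(lambda) exp(-t / tau_i) +
#' A_inf(lambda)` with the `n` lifetimes shared across all wavelengths, by
#' variable projection: at fixed lifetimes the amplitude spectra are a
#' weighted linear least-squares solve, and the lifetimes are optimized
#' nonlinearly (on a log scale) to minimize the weighted residual SD. When
#' no initial lifetimes are given the optimizer is multi-started from
#' log-spaced lifetime grids over the observed time span and the best start
#' wins.
#'
#' @param d A [transient_absorption()].
#' @param n Number of exponential components (>= 1).
#' @param init Optional numeric vector of `n` starting lifetimes, s.
#' @param n_starts Number of shifted log-grid starts when `init` is absent
#'   (default 4).
#' @return An object of class `photocycle_fit`: `tau` (s, ascending),
#'   `amplitudes` (wavelength x component matrix), `offset` (per-wavelength
#'   t -> Inf term), `sd_weighted`, `n`, plus the wavelength grid.
#' @export
fit_global_exponentials <- function(d, n, init = NULL, n_starts = 4) {
  stopifnot(inherits(d, "transient_absorption"), n >= 1)
  if (length(d$times) < n + 1) abort("fewer time points than components")
  times <- d$times
  Y <- t(d$delta_A)                     # n_t x n_wl
  W <- if (is.null(d$weights)) NULL else t(d$weights)
  lo <- log(min(times)) - log(10)
  hi <- log(max(times)) + log(10)
  starts <- if (!is.null(init)) {
    if (length(init) != n || any(init <= 0)) {
      abort("init must be n positive lifetimes")
    }
    list(log(sort(init)))
  } else {
    span <- seq(log(min(times) * 3), log(max(times) / 3), length.out = n + 2)
    base <- span[seq(2, n + 1)]
    step <- if (n > 1) diff(base)[1] else (hi - lo) / 4
    lapply(seq_len(n_starts), function(s) {
      base + (s - (n_starts + 1) / 2) * step / n_starts
    })
  }
  objective <- function(lt) {
    sol <- solve_amplitudes(times, Y, W, exp(lt))
    if (is.null(sol) || !is.finite(sol$sd)) return(1e10)
    sol$sd
  }
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      nlminb(st, objective, lower = lo, upper = hi,
             control = list(iter.max = 400, eval.max = 800)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective)) {
      best <- opt
    }
  }
  if (is.null(best) || best$objective >= 1e10) {
    abort("multiexponential fit failed to converge from all starts")
  }
  tau <- sort(exp(best$par))
  sol <- solve_amplitudes(times, Y, W, tau)
  if (is.null(sol)) abort("amplitude solve ill-conditioned at fitted lifetimes")
  amp <- t(sol$coef[seq_len(n), , drop = FALSE])   # n_wl x n
  colnames(amp) <- paste0("tau", seq_len(n))
  structure(list(
    tau = tau, amplitudes = amp, offset = sol$coef[n + 1, ],
    sd_weighted = sol$sd, n = n, wavelengths = d$wavelengths,
    times = times, convergence = best$convergence
  ), class = "photocycle_fit")
}

#' @export
print.photocycle_fit <- function(x, ...) {
  cat(sprintf("<photocycle_fit> %d components, weighted residual SD %.3g\n",
              x$n, x$sd_weighted))
  cat("  lifetimes (s):", format(x$tau, digits = 4), "\n")
  invisible(x)
}

#' @rdname fit_global_exponentials
#' @param x A `photocycle_fit`.
#' @param ... Unused.
#' @method tidy photocycle_fit
#' @export
tidy.photocycle_fit <- function(x, ...) {
  tibble(
    component = rep(seq_len(x$n), each = length(x$wavelengths)),
    lifetime = rep(x$tau, each = length(x$wavelengths)),
    wavelength = rep(x$wavelengths, x$n),
    amplitude = as.vector(x$amplitudes)
  )
}

#' @rdname fit_global_exponentials
#' @method glance photocycle_fit
#' @export
glance.photocycle_fit <- function(x, ...) {
  tibble(n = x$n, sd_weighted = x$sd_weighted,
         tau_min = min(x$tau), tau_max = max(x$tau))
}

#' @rdname fit_global_exponentials
#' @param object A `photocycle_fit`.
#' @method autoplot photocycle_fit
#' @export
autoplot.photocycle_fit <- function(object, ...) {
  td <- tidy(object) |>
    mutate(label = sprintf("tau[%d] == %.3g~s", .data$component,
                           .data$lifetime))
  ggplot(td, aes(x = .data$wavelength, y = .data$amplitude,
                 colour = .data$label)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 3) +
    scale_colour_discrete(name = NULL, labels = scales_parse) +
    labs(x = "wavelength (nm)", y = expression(Delta * A~amplitude),
         title = "Decay-associated amplitude spectra") +
    theme_minimal()
}

scales_parse <- function(x) parse(text = x)

#' Choose the number of exponential components
#'
#' Fits 1, 2, ... components and stops at the first count whose weighted
#' residual SD improves on the previous one by less than
#' `improvement_threshold` (relative); the previous count is chosen — the
#' operational form of incrementing the component count until the residual
#' SD stops improving. Each fit after the first is additionally warm-started
#' from the previous lifetimes with one extra component inserted in the
#' largest lifetime gap, which keeps the SD ladder monotone.
#'
#' @param d A [transient_absorption()].
#' @param n_max Largest component count to consider.
#' @param improvement_threshold Relative SD improvement below which adding a
#'   component is judged not to help (default 0.02).
#' @param n_starts Multi-start count passed to [fit_global_exponentials()].
#' @return A list with `n` (chosen count), `fit` (the chosen
#'   `photocycle_fit`), `sd_ladder` (tibble of n vs SD and relative
#'   improvement) and `fits` (all fits).
#' @export
select_component_count <- function(d, n_max = 6,
                                   improvement_threshold = 0.02,
                                   n_starts = 4) {
  stopifnot(n_max >= 1)
  fits <- vector("list", n_max)
  sds <- rep(NA_real_, n_max)
  chosen <- n_max
  for (n in seq_len(n_max)) {
    fit <- fit_global_exponentials(d, n, n_starts = n_starts)
    if (n > 1) {
      # warm start: previous lifetimes + one in the largest log-gap
      prev <- fits[[n - 1]]$tau
      gaps <- diff(log(c(min(d$times), prev, max(d$times))))
      g <- which.max(gaps)
      bounds <- c(min(d$times), prev, max(d$times))
      extra <- exp(mean(log(bounds[c(g, g + 1)])))
      warm <- fit_global_exponentials(d, n, init = sort(c(prev, extra)))
      if (warm$sd_weighted < fit$sd_weighted) fit <- warm
    }
    fits[[n]] <- fit
    sds[n] <- fit$sd_weighted
    if (n > 1) {
      rel <- (sds[n - 1] - sds[n]) / sds[n - 1]
      if (rel < improvement_threshold) {
        chosen <- n - 1
        break
      }
    }
  }
  done <- !is.na(sds)
  ladder <- tibble(
    n = which(done), sd_weighted = sds[done],
    rel_improvement = c(NA, -diff(sds[done]) / head(sds[done], -1))
  )
  list(n = chosen, fit = fits[[chosen]], sd_ladder = ladder,
       fits = fits[done])
}

#' Concentrations along a sequential irreversible photocycle
#'
#' Solves the unidirectional kinetic chain `state_1 -> state_2 -> ... ->
#' recovered` with `C_1(0) = 1` (the Bateman cascade). Rates must be
#' positive; near-degenerate rates (relative gap below `degeneracy_tol`)
#' switch the closed form to a matrix-exponential evaluation to avoid
#' catastrophic cancellation.
#'
#' @param rates Positive rate constants, 1/s, in chain order.
#' @param times Times at which to evaluate, s.
#' @param state_names Optional state labels (default S1..Sm).
#' @param degeneracy_tol Relative rate gap below which the matrix-exponential
#'   path is used (default 1e-6).
#' @return A tibble: `time`, one column per state, and `recovered`; each row
#'   sums to 1.
#' @export
sequential_concentrations <- function(rates, times, state_names = NULL,
                                      degeneracy_tol = 1e-6) {
  if (any(rates <= 0)) abort("rates must be positive")
  m <- length(rates)
  state_names <- state_names %||% paste0("S", seq_len(m))
  degenerate <- m > 1 && min(abs(diff(sort(rates))) / sort(rates)[-m]) <
    degeneracy_tol
  if (!degenerate) {
    M <- bateman_coefficients(rates)
    Ebas <- exp(-outer(times, rates))          # n_t x m
    C <- Ebas %*% t(M)                          # n_t x m
  } else {
    warn("near-degenerate rates: using matrix-exponential evaluation")
    Q <- matrix(0, m, m)
    diag(Q) <- -rates
    if (m > 1) Q[cbind(seq(2, m), seq(1, m - 1))] <- rates[-m]
    C <- t(vapply(times, function(t1) {
      (expm_small(Q * t1) %*% c(1, rep(0, m - 1)))[, 1]
    }, numeric(m)))
  }
  C <- pmin(pmax(C, 0), 1)
  out <- as_tibble(C, .name_repair = ~state_names)
  out <- mutate(out, time = times, recovered = pmax(1 - rowSums(C), 0))
  select(out, "time", dplyr::all_of(state_names), "recovered")
}

# coefficients of the Bateman cascade: c_j(t) = sum_i M[j, i] exp(-k_i t)
bateman_coefficients <- function(rates) {
  m <- length(rates)
  M <- matrix(0, m, m)
  for (j in seq_len(m)) {
    pref <- prod(rates[seq_len(j - 1)])
    for (i in seq_len(j)) {
      denom <- prod(rates[setdiff(seq_len(j), i)] - rates[i])
      M[j, i] <- pref / ifelse(j == 1, 1, denom)
    }
    if (j == 1) M[1, 1] <- 1
  }
  M
}

# scaling-and-squaring Taylor matrix exponential (small dense matrices)
expm_small <- function(A) {
  n <- nrow(A)
  s <- max(0, ceiling(log2(max(1, norm(A, "1")))))
  A <- A / 2^s
  F <- diag(n)
  term <- diag(n)
  for (k in seq_len(40)) {
    term <- term %*% A / k
    F <- F + term
    if (max(abs(term)) < 1e-17) break
  }
  for (k in seq_len(s)) F <- F %*% F
  F
}

#' Reconstruct absolute intermediate spectra and the cycling fraction
#'
#' Under the sequential irreversible interpretation, the fitted lifetimes
#' (sorted ascending) map one-to-one onto the chain steps, fastest first.
#' Each state concentration is a known linear combination of the fitted
#' exponentials (Bateman coefficients), so inverting that relation turns the
#' decay-associated amplitude spectra into the difference spectra of the
#' intermediates relative to the final (recovered ground) state, scaled by
#' the cycling fraction f. Absolute spectra follow as `S_j = S_ground +
#' deltaS_j / f`. The fraction is determined on a grid: candidates are
#' feasible when every absolute spectrum stays above `-epsilon`, and the
#' smallest feasible f is chosen — the value at which the ground-state band
#' is maximally subtracted (no residual initial-state contribution) without
#' producing negative absorbance.
#'
#' @param fit A `photocycle_fit`.
#' @param ground_spectrum Data frame with columns `wavelength` and
#'   `absorbance`: the (final = initial) ground-state spectrum; interpolated
#'   onto the fit's wavelength grid if needed.
#' @param f_grid Candidate cycling fractions (default 0.01..1 step 0.01).
#' @param epsilon Floor of the non-negativity tolerance in absorbance units
#'   (default 1e-3). On noisy data the effective tolerance at a candidate f
#'   is `epsilon + 3 * se / f`, where `se` is the standard error of the
#'   difference spectra propagated from the fit's weighted residual SD:
#'   a candidate is only rejected when a spectrum dips below what noise
#'   alone could explain.
#' @param state_names Optional state labels (default S1..Sn).
#' @return An object of class `intermediate_spectra`: `wavelengths`,
#'   `states`, `difference` and `absolute` spectra (state x wavelength
#'   matrices), chosen `f`, `feasible` flag and the worst negative excursion
#'   `violation` (0 when feasible).
#' @export
reconstruct_intermediate_spectra <- function(fit, ground_spectrum,
                                             f_grid = seq(0.01, 1, by = 0.01),
                                             epsilon = 1e-3,
                                             state_names = NULL) {
  stopifnot(inherits(fit, "photocycle_fit"))
  gs <- as_tibble(ground_spectrum)
  if (!all(c("wavelength", "absorbance") %in% names(gs))) {
    abort("ground_spectrum needs columns wavelength and absorbance")
  }
  ground <- if (isTRUE(all.equal(gs$wavelength, fit$wavelengths))) {
    gs$absorbance
  } else {
    approx(gs$wavelength, gs$absorbance, xout = fit$wavelengths,
           rule = 2)$y
  }
  n <- fit$n
  state_names <- state_names %||% paste0("S", seq_len(n))
  k <- 1 / fit$tau                       # fastest step first
  M <- bateman_coefficients(k)
  A <- t(fit$amplitudes)                 # n x n_wl, rows = components
  Minv <- tryCatch(solve(t(M)), error = function(e) {
    abort("singular exponential-to-state transform (degenerate rates)")
  })
  FD <- Minv %*% A                       # rows j = f * deltaS_j
  # amplitude noise propagated through the exponential-to-state transform:
  # sets how deep below zero a candidate's spectra may dip before the
  # non-negativity criterion rejects it
  se_fd <- tryCatch({
    E <- exp_design(fit$times, fit$tau)
    se_amp <- fit$sd_weighted * sqrt(diag(solve(crossprod(E))))[seq_len(n)]
    max(sqrt((Minv^2) %*% se_amp^2))
  }, error = function(e) 0)
  if (max(abs(FD)) < 1e-12) {
    # degenerate: nothing cycled, every state equals the ground state
    f <- 1
    feasible <- TRUE; violation <- 0
  } else {
    mins <- vapply(f_grid, function(f) {
      min(sweep(FD / f, 2, ground, `+`))
    }, numeric(1))
    tol <- epsilon + 3 * se_fd / f_grid
    ok <- mins >= -tol
    if (any(ok)) {
      f <- f_grid[which(ok)[1]]          # smallest feasible fraction
      feasible <- TRUE; violation <- 0
    } else {
      best <- which.max(mins + tol)
      f <- f_grid[best]
      feasible <- FALSE
      violation <- -(mins[best] + tol[best])
      warn(sprintf(
        "no cycling fraction satisfies non-negativity; best f = %.2f leaves a %.3g excursion",
        f, violation))
    }
  }
  difference <- FD / f
  absolute <- sweep(difference, 2, ground, `+`)
  rownames(difference) <- rownames(absolute) <- state_names
  colnames(difference) <- colnames(absolute) <- fit$wavelengths
  structure(list(
    wavelengths = fit$wavelengths, states = state_names,
    difference = difference, absolute = absolute, f = f,
    ground = ground, feasible = feasible, violation = violation,
    tau = fit$tau
  ), class = "intermediate_spectra")
}

#' @export
print.intermediate_spectra <- function(x, ...) {
  cat(sprintf(
    "<intermediate_spectra> %d states, cycling fraction f = %.2f%s\n",
    length(x$states), x$f,
    if (x$feasible) "" else sprintf(" (infeasible, excursion %.3g)",
                                    x$violation)))
  invisible(x)
}

#' @rdname reconstruct_intermediate_spectra
#' @param x An `intermediate_spectra` object.
#' @param ... Unused.
#' @method tidy intermediate_spectra
#' @export
tidy.intermediate_spectra <- function(x, ...) {
  tibble(
    state = rep(x$states, each = length(x$wavelengths)),
    wavelength = rep(x$wavelengths, length(x$states)),
    difference = as.vector(t(x$difference)),
    absolute = as.vector(t(x$absolute))
  )
}

#' @rdname reconstruct_intermediate_spectra
#' @method glance intermediate_spectra
#' @export
glance.intermediate_spectra <- function(x, ...) {
  tibble(n_states = length(x$states), f = x$f, feasible = x$feasible,
         violation = x$violation)
}

#' @rdname reconstruct_intermediate_spectra
#' @param object An `intermediate_spectra` object.
#' @method autoplot intermediate_spectra
#' @export
autoplot.intermediate_spectra <- function(object, ...) {
  td <- tidy(object)
  gr <- tibble(wavelength = object$wavelengths, absolute = object$ground,
               state = "ground")
  ggplot(td, aes(x = .data$wavelength, y = .data$absolute,
                 colour = .data$state)) +
    geom_line() +
    geom_line(data = gr, linetype = 2, colour = "grey30") +
    labs(x = "wavelength (nm)", y = "absorbance",
         title = sprintf("Absolute intermediate spectra (f = %.2f)",
                         object$f)) +
    theme_minimal()
}

#' Detect unfolding transitions in a thermal melting curve
#'
#' Melting temperatures are the peaks of the first derivative of the signal
#' (e.g. the tryptophan fluorescence ratio F350/F330) with respect to
#' temperature: the curve is smoothed with a centred moving average,
#' differentiated centrally, and local derivative maxima exceeding a
#' prominence threshold are reported.
#'
#' @param curve Data frame with columns `temperature` (degrees C, strictly
#'   increasing) and `ratio`.
#' @param smoothing_window Odd moving-average window in points (default 11).
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   derivative's full spread (default 0.25). Prominence — the height of a
#'   derivative peak above the highest saddle separating it from a larger
#'   peak — rejects noise wiggles that mere peak height would count.
#' @param refine_halfwidth Half-width, degrees C, of the quadratic fitted
#'   around each derivative peak to localize the transition below the grid
#'   step (default 4; 0 disables refinement).
#' @return Numeric vector of transition temperatures, sorted ascending
#'   (empty for flat or monotone-linear curves, whose derivative has no
#'   prominent peak).
#' @export
detect_unfolding_transitions <- function(curve, smoothing_window = 11,
                                         min_prominence = 0.25,
                                         refine_halfwidth = 4) {
  curve <- as_tibble(curve)
  stopifnot(all(c("temperature", "ratio") %in% names(curve)))
  tt <- curve$temperature
  if (length(tt) < 5) abort("need at least 5 points")
  if (any(diff(tt) <= 0)) abort("temperatures must be strictly increasing")
  if (smoothing_window %% 2 == 0) abort("smoothing window must be odd")
  y <- curve$ratio
  if (smoothing_window > 1 && length(y) > smoothing_window) {
    sm <- stats::filter(y, rep(1 / smoothing_window, smoothing_window),
                        sides = 2)
    y <- ifelse(is.na(sm), y, as.numeric(sm))
  }
  dy <- pracma::gradient(y, tt)
  spread <- max(dy) - min(dy)
  # flat curve, or constant slope (linear ramp): no transition
  if (spread <= 1e-12 || spread <= 1e-6 * max(abs(dy))) {
    return(numeric(0))
  }
  # the first/last half-window is unsmoothed: peaks there are edge artifacts
  margin <- smoothing_window
  peaks <- which(diff(sign(diff(dy))) < 0) + 1
  peaks <- peaks[peaks > margin & peaks <= length(dy) - margin]
  if (length(peaks) == 0) return(numeric(0))
  prom <- vapply(peaks, function(i) peak_prominence(dy, i), numeric(1))
  peaks <- peaks[prom >= min_prominence * spread]
  if (refine_halfwidth <= 0) return(sort(tt[peaks]))
  sort(vapply(peaks, function(i) quad_peak_refine(tt, dy, i,
                                                  refine_halfwidth),
              numeric(1)))
}

# sub-grid peak position: vertex of a least-squares parabola fitted to the
# derivative around the grid argmax, clamped to the fitting window
quad_peak_refine <- function(tt, dy, i, halfwidth) {
  keep <- which(abs(tt - tt[i]) <= halfwidth)
  if (length(keep) < 5) return(tt[i])
  x <- tt[keep] - tt[i]
  co <- tryCatch(stats::coef(stats::lm.fit(cbind(1, x, x^2), dy[keep])),
                 error = function(e) NULL)
  if (is.null(co) || !is.finite(co[3]) || co[3] >= 0) return(tt[i])
  v <- -co[2] / (2 * co[3])
  tt[i] + max(min(v, max(x)), min(x))
}

# topographic prominence of a local maximum: height above the higher of the
# two key saddles (walk each way until a taller point or the series end)
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]
  for (j in rev(seq_len(i - 1))) {
    if (y[j] > y[i]) break
    left_min <- min(left_min, y[j])
  }
  right_min <- y[i]
  j <- i + 1
  while (j <= n && y[j] <= y[i]) {
    right_min <- min(right_min, y[j])
    j <- j + 1
  }
  y[i] - max(left_min, right_min)
}
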