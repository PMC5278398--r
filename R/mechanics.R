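#' Lever geometry of the glasses temple--hinge system
#'
#' The temple acts as a lever pivoting about the hinge joint: the
#' temporalis muscle presses on the temple at distance `L_temple` from the
#' joint while the hinge load cell sits at distance `L_hinge`. Under moment
#' equilibrium the hinge force is the temple force multiplied by
#' `L_temple / L_hinge`, so the weak muscle force is mechanically
#' amplified at the hinge.
#'
#' @param L_temple hinge joint to temple (skin) contact point, mm.
#' @param L_hinge hinge joint to hinge load-cell contact, mm.
#' @return An object of class `lever_geometry`.
#' @export
lever_geometry <- function(L_temple = 69, L_hinge = 9) {
  if (!(L_temple > 0 && L_hinge > 0)) stop("lever arm lengths must be positive")
  if (L_temple < L_hinge) stop("L_temple must be at least L_hinge")
  structure(list(L_temple = L_temple, L_hinge = L_hinge),
            class = "lever_geometry")
}

#' Theoretical force amplification factor
#'
#' Moment equilibrium about the hinge joint gives
#' `F_hinge = (L_temple / L_hinge) * F_temple`; the dimensionless ratio of
#' lever arms is the amplification factor. The default 69 mm / 9 mm
#' geometry gives 7.67.
#'
#' @param geom a [lever_geometry()].
#' @return Dimensionless amplification factor.
#' @export
amplification_factor <- function(geom) {
  stopifnot(inherits(geom, "lever_geometry"))
  geom$L_temple / geom$L_hinge
}

#' Force transmitted from temple to hinge
#'
#' @param F_temple nonnegative temple force, N (vectorized).
#' @param geom a [lever_geometry()].
#' @return Hinge force, N.
#' @export
transmit_force <- function(F_temple, geom) {
  if (any(F_temple < 0)) stop("temple force must be nonnegative")
  amplification_factor(geom) * F_temple
}

#' Ordinary least-squares line fit
#'
#' Fits `y = slope * x + intercept` by least squares and reports the
#' coefficient of determination and the two-sided p-value of the test of
#' zero slope.
#'
#' @param x,y numeric vectors of equal length (>= 3), `x` not constant.
#' @return An object of class `regression_fit` with fields `slope`,
#'   `intercept`, `r_squared`, `p_value`.
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant")
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - (intercept + slope * x)
  ss_tot <- sum((y - mean(y))^2)
  r_squared <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 0
  # two-sided t-test of zero slope; a numerically perfect fit bottoms out
  # at the smallest positive double so p stays in (0, 1]
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  p_value <- if (se > 0) {
    2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  } else .Machine$double.xmin
  p_value <- max(p_value, .Machine$double.xmin)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, p_value = p_value),
            class = "regression_fit")
}

#' Bench-sweep container
#'
#' Paired temple/hinge force measurements taken while a linear sub-stage
#' displaces the temple in fixed increments.
#'
#' @param displacement strictly increasing displacements, mm.
#' @param F_temple,F_hinge forces, N, same length as `displacement`.
#' @return An object of class `bench_sweep`.
#' @export
bench_sweep <- function(displacement, F_temple, F_hinge) {
  stopifnot(length(displacement) == length(F_temple),
            length(displacement) == length(F_hinge))
  if (any(diff(displacement) <= 0)) stop("displacement must be strictly increasing")
  structure(list(displacement = displacement,
                 F_temple = F_temple, F_hinge = F_hinge),
            class = "bench_sweep")
}

#' Experimental amplification factor from a bench sweep
#'
#' Regresses hinge force on temple force; the slope is the experimental
#' amplification factor, directly comparable with the geometric
#' [amplification_factor()].
#'
#' @param sweep a [bench_sweep()].
#' @return A `regression_fit`; `slope` is the experimental factor.
#' @export
estimate_amplification <- function(sweep) {
  stopifnot(inherits(sweep, "bench_sweep"))
  fit_line(sweep$F_temple, sweep$F_hinge)
}

#' Simulate a bench validation sweep
#'
#' Linear-elastic contact model of the validation rig: the sub-stage moves
#' in `step` mm increments; after contact onset `d0` the temple force grows
#' as `stiffness_temple * (d - d0)` and the hinge force is the lever-
#' transmitted temple force. Independent Gaussian measurement noise is
#' added to both load-cell readings.
#'
#' @param geom a [lever_geometry()].
#' @param stiffness_temple N/mm.
#' @param n_steps number of displacement steps (>= 3).
#' @param step displacement increment, mm (the rig resolution, default
#'   0.05 mm).
#' @param noise_sd measurement noise, N.
#' @param seed integer seed.
#' @param d0 contact-onset displacement, mm.
#' @return A `bench_sweep`.
#' @export
simulate_bench <- function(geom, stiffness_temple = 0.44, n_steps = 100,
                           step = 0.05, noise_sd = 0, seed = 1, d0 = 0) {
  stopifnot(inherits(geom, "lever_geometry"), step > 0)
  if (n_steps < 3) stop("n_steps must be >= 3")
  with_seed(seed, {
    d <- seq_len(n_steps) * step
    f_t <- pmax(0, stiffness_temple * (d - d0))
    f_h <- transmit_force(f_t, geom)
    if (noise_sd > 0) {
      f_t <- f_t + stats::rnorm(n_steps, 0, noise_sd)
      f_h <- f_h + stats::rnorm(n_steps, 0, noise_sd)
    }
    bench_sweep(d, f_t, f_h)
  })
}

#' Write a bench sweep as CSV
#'
#' Columns `displacement_mm,F_temple_N,F_hinge_N`.
#'
#' @param sweep a `bench_sweep`.
#' @param path output file.
#' @export
write_sweep_csv <- function(sweep, path) {
  df <- data.frame(displacement_mm = sweep$displacement,
                   F_temple_N = sweep$F_temple,
                   F_hinge_N = sweep$F_hinge)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
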