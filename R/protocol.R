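#' Drop-tower impaction specification
#'
#' Encodes the geometry of a standardized drop-tower impaction: a cylindrical
#' weight of mass `mass` dropped from `drop_height` onto the cartilage surface.
#' The tip diameter is carried as metadata only; contact mechanics are out of
#' scope.
#'
#' @param mass Drop weight in kilograms (>= 0).
#' @param drop_height Drop height in meters (>= 0).
#' @param gravity Gravitational acceleration in m/s^2 (> 0, default 9.81).
#' @param tip_diameter_mm Impactor tip diameter in millimeters (informational).
#' @return An object of class `impaction_spec`.
#' @examples
#' low  <- impaction_spec(mass = 0.5, drop_height = 0.100)
#' impact_energy(low)    # 0.49 J
#' impact_velocity(low)  # 1.4 m/s
#' @export
impaction_spec <- function(mass, drop_height, gravity = 9.81,
                           tip_diameter_mm = 5) {
  stopifnot(is.numeric(mass), length(mass) == 1L,
            is.numeric(drop_height), length(drop_height) == 1L,
            is.numeric(gravity), length(gravity) == 1L)
  if (is.na(mass) || mass < 0)
    stop("'mass' must be a non-negative number of kilograms", call. = FALSE)
  if (is.na(drop_height) || drop_height < 0)
    stop("'drop_height' must be a non-negative number of meters", call. = FALSE)
  if (is.na(gravity) || gravity <= 0)
    stop("'gravity' must be positive", call. = FALSE)
  structure(
    list(mass = mass, drop_height = drop_height, gravity = gravity,
         tip_diameter_mm = tip_diameter_mm),
    class = "impaction_spec"
  )
}

#' Impact velocity at the moment of contact
#'
#' Free-fall velocity `v = sqrt(2 g h)` of the drop weight; independent of the
#' mass.
#'
#' @param spec An [impaction_spec()].
#' @return Velocity in m/s.
#' @export
impact_velocity <- function(spec) {
  stopifnot(inherits(spec, "impaction_spec"))
  sqrt(2 * spec$gravity * spec$drop_height)
}

#' Delivered impaction energy
#'
#' Potential energy `E = m g h` released by the drop; linear in both mass and
#' height, so doubling the mass at fixed height exactly doubles the energy.
#'
#' @param spec An [impaction_spec()].
#' @return Energy in joules.
#' @export
impact_energy <- function(spec) {
  stopifnot(inherits(spec, "impaction_spec"))
  spec$mass * spec$gravity * spec$drop_height
}

#' Multi-echo spin-echo timing schedule
#'
#' The acquisition samples the transverse decay at equidistant echo times
#' `TE_n = n * echo_spacing` for `n = 1..n_echoes`. A contiguous subset of
#' echoes (1-based indices, default 2--7) is used for T2 fitting: the first
#' echo is discarded to avoid stimulated-echo artefacts and late echoes
#' (TE >= 60 ms) are discarded for their low signal-to-noise ratio.
#'
#' @param echo_spacing Echo spacing in milliseconds (default 8.38).
#' @param n_echoes Number of echoes (default 12).
#' @param fit_echo_indices Ordered 1-based echo indices used for fitting
#'   (default `2:7`).
#' @return An object of class `echo_schedule`.
#' @examples
#' sched <- echo_schedule()
#' echo_times(sched)[5]              # 41.9 ms
#' echo_times(sched, fit_only = TRUE)
#' @export
echo_schedule <- function(echo_spacing = 8.38, n_echoes = 12,
                          fit_echo_indices = 2:7) {
  stopifnot(is.numeric(echo_spacing), length(echo_spacing) == 1L,
            is.numeric(n_echoes), length(n_echoes) == 1L)
  if (echo_spacing <= 0)
    stop("'echo_spacing' must be positive (milliseconds)", call. = FALSE)
  n_echoes <- as.integer(n_echoes)
  if (n_echoes < 1L) stop("'n_echoes' must be >= 1", call. = FALSE)
  fit_echo_indices <- as.integer(fit_echo_indices)
  if (anyNA(fit_echo_indices) ||
      any(fit_echo_indices < 1L) || any(fit_echo_indices > n_echoes))
    stop("'fit_echo_indices' must be 1-based indices within 1..n_echoes",
         call. = FALSE)
  if (is.unsorted(fit_echo_indices, strictly = TRUE))
    stop("'fit_echo_indices' must be strictly ascending", call. = FALSE)
  structure(
    list(echo_spacing = echo_spacing, n_echoes = n_echoes,
         fit_echo_indices = fit_echo_indices),
    class = "echo_schedule"
  )
}

#' Echo times of a schedule
#'
#' @param schedule An [echo_schedule()].
#' @param fit_only If `TRUE`, return only the echo times selected for fitting.
#' @return Echo times in milliseconds.
#' @export
echo_times <- function(schedule, fit_only = FALSE) {
  stopifnot(inherits(schedule, "echo_schedule"))
  te <- seq_len(schedule$n_echoes) * schedule$echo_spacing
  if (fit_only) te[schedule$fit_echo_indices] else te
}

#' Derived protocol table
#'
#' Tabulates the impaction arms (velocity and energy) of the study design:
#' unimpacted controls, low impact (500 g) and high impact (1000 g), both
#' dropped from 100 mm.
#'
#' @param specs Named list of [impaction_spec()] objects; defaults to the
#'   CONT/LIMP/HIMP arms of the study design.
#' @return A data.frame with mass (g), height (mm), velocity (m/s), energy (J).
#' @export
protocol_table <- function(specs = list(
                             CONT = impaction_spec(0, 0),
                             LIMP = impaction_spec(0.5, 0.100),
                             HIMP = impaction_spec(1.0, 0.100))) {
  data.frame(
    group = names(specs),
    mass_g = vapply(specs, function(s) s$mass * 1000, numeric(1)),
    height_mm = vapply(specs, function(s) s$drop_height * 1000, numeric(1)),
    velocity_m_s = vapply(specs, impact_velocity, numeric(1)),
    energy_J = vapply(specs, impact_energy, numeric(1)),
    row.names = NULL
  )
}
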