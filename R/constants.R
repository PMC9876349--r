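#' Physical constants for oxygen diffusion and consumption
#'
#' Bundles the dimensional constants needed to move between the lumped
#' parameterisation used throughout the package (pressures in percent of
#' atmosphere, radii in micrometres) and SI-unit oxygen kinetics. Radial
#' profiles and growth dynamics never depend on these individually, only on
#' lumped combinations, so they enter exclusively through the explicit
#' conversion helpers [critical_radius_from_constants()] and
#' [alpha_from_critical_radius()] and through snapshot estimation of the
#' consumption rate.
#'
#' @param k oxygen diffusivity in tissue \[m^2 s^-1\].
#' @param Omega conversion constant from oxygen volume per unit tumour mass
#'   to partial pressure \[mmHg kg m^-3\].
#' @param percent_to_mmHg pressure conversion factor \[mmHg per percent of
#'   atmosphere\]; the default corresponds to 760 mmHg per 100%.
#' @param p_hyp pimonidazole-binding threshold partial pressure \[%\] used to
#'   predict the hypoxic radius.
#'
#' @return An object of class `oxygen_constants` (a named list).
#' @export
oxygen_constants <- function(k = 2e-9, Omega = 3.0318e7,
                             percent_to_mmHg = 7.6, p_hyp = 0.5) {
  stopifnot(k > 0, Omega > 0, percent_to_mmHg > 0, p_hyp >= 0)
  structure(list(k = k, Omega = Omega, percent_to_mmHg = percent_to_mmHg,
                 p_hyp = p_hyp),
            class = "oxygen_constants")
}

#' Read and write the physical-constant configuration
#'
#' Plain key-value text (`key = value`, one per line, `#` comments) holding
#' the four configurable constants of [oxygen_constants()]. The round trip
#' is lossless (17 significant digits).
#'
#' @param path file path.
#' @return `read_constants()` returns an `oxygen_constants` object;
#'   `write_constants()` returns `path` invisibly.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`,
                                                    character(1), 2))))
  if (any(is.na(vals)))
    stop("malformed value for key(s): ",
         paste(keys[is.na(vals)], collapse = ", "))
  allowed <- c("k", "Omega", "percent_to_mmHg", "p_hyp")
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  args <- stats::setNames(as.list(vals), keys)
  do.call(oxygen_constants, args)
}

#' @param constants an [oxygen_constants()] object.
#' @rdname read_constants
#' @export
write_constants <- function(constants, path) {
  stopifnot(inherits(constants, "oxygen_constants"))
  keys <- c("k", "Omega", "percent_to_mmHg", "p_hyp")
  writeLines(paste(keys, "=",
                   vapply(constants[keys], formatC, character(1),
                          digits = 17, format = "g")),
             path)
  invisible(path)
}

#' Critical outer radius from dimensional constants
#'
#' The outer radius at which the central oxygen partial pressure first
#' reaches zero and a necrotic core forms:
#' \eqn{R_c = \sqrt{6 k p_\infty / (\alpha \Omega)}}.
#'
#' @param k oxygen diffusivity \[m^2 s^-1\].
#' @param alpha oxygen consumption rate \[m^3 kg^-1 s^-1\].
#' @param Omega conversion constant \[mmHg kg m^-3\].
#' @param p_mmHg external oxygen partial pressure \[mmHg\].
#'
#' @return Critical radius \[um\].
#' @seealso [alpha_from_critical_radius()] for the exact inverse.
#' @export
critical_radius_from_constants <- function(k, alpha, Omega, p_mmHg) {
  stopifnot(k > 0, alpha > 0, Omega > 0, p_mmHg > 0)
  sqrt(6 * k * p_mmHg / (alpha * Omega)) * 1e6
}

#' Oxygen consumption rate from the critical radius
#'
#' Exact inverse of [critical_radius_from_constants()]:
#' \eqn{\alpha = 6 k p_\infty / (R_c^2 \Omega)}.
#'
#' @param R_c critical outer radius \[um\].
#' @param k oxygen diffusivity \[m^2 s^-1\].
#' @param Omega conversion constant \[mmHg kg m^-3\].
#' @param p_mmHg external oxygen partial pressure \[mmHg\].
#'
#' @return Consumption rate \[m^3 kg^-1 s^-1\].
#' @export
alpha_from_critical_radius <- function(R_c, k, Omega, p_mmHg) {
  stopifnot(R_c > 0, k > 0, Omega > 0, p_mmHg > 0)
  6 * k * p_mmHg / ((R_c * 1e-6)^2 * Omega)
}

#' Convert partial pressure from percent of atmosphere to mmHg
#'
#' @param p_percent pressure \[%\].
#' @param constants an [oxygen_constants()] object supplying the factor.
#' @return Pressure \[mmHg\].
#' @export
percent_to_mmHg <- function(p_percent, constants = oxygen_constants()) {
  p_percent * constants$percent_to_mmHg
}
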