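#' Define an intraocular lens model
#'
#' An IOL model bundles the facts about a lens product that the power
#' calculation and tolerance analysis need: the diopter grid step at which it
#' is manufactured, the standard deviation of its dioptric labelling error,
#' its SRK/T A-constant, its Haigis constants, and the labelled power range.
#'
#' @param name Product name (character scalar).
#' @param interval Diopter grid step, e.g. 0.50 or 0.25 D. Must be positive.
#' @param tolerance_sd Standard deviation of the manufacturing power error, in
#'   diopters (>= 0). The 0.50 D-interval class is conventionally assigned
#'   0.40 D and the 0.25 D-interval class 0.11 D.
#' @param a_constant SRK/T A-constant (dimensionless, typically 112-122).
#' @param haigis_a0,haigis_a1,haigis_a2 Haigis effective-lens-position
#'   constants: `a0` in mm, `a1` per mm of anterior chamber depth, `a2` per mm
#'   of axial length.
#' @param power_min,power_max Labelled power range in diopters
#'   (`power_min < power_max`).
#'
#' @return An object of class `iol_lens` (a named list of the fields above).
#' @seealso [default_lens_registry()] for the two study lenses,
#'   [round_to_grid()] for snapping a continuous power onto the lens grid.
#' @examples
#' iol_lens("Akreos AO", interval = 0.50, tolerance_sd = 0.40,
#'          a_constant = 118.24, haigis_a0 = 1.706, haigis_a1 = 0.279,
#'          haigis_a2 = 0.087)
#' @export
iol_lens <- function(name, interval, tolerance_sd, a_constant,
                     haigis_a0, haigis_a1, haigis_a2,
                     power_min = 15.5, power_max = 25.0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0)
    stop("'interval' must be a single positive diopter step", call. = FALSE)
  if (!is.numeric(tolerance_sd) || length(tolerance_sd) != 1L || tolerance_sd < 0)
    stop("'tolerance_sd' must be a single non-negative diopter SD", call. = FALSE)
  if (!(power_min < power_max))
    stop("'power_min' must be strictly less than 'power_max'", call. = FALSE)
  structure(
    list(name = name, interval = interval, tolerance_sd = tolerance_sd,
         a_constant = a_constant, haigis_a0 = haigis_a0,
         haigis_a1 = haigis_a1, haigis_a2 = haigis_a2,
         power_min = power_min, power_max = power_max),
    class = "iol_lens")
}

#' @export
print.iol_lens <- function(x, ...) {
  cat(sprintf("IOL model: %s\n", x$name))
  cat(sprintf("  grid interval: %.2f D   tolerance SD: %.2f D\n",
              x$interval, x$tolerance_sd))
  cat(sprintf("  SRK/T A-constant: %.2f\n", x$a_constant))
  cat(sprintf("  Haigis a0/a1/a2: %.3f / %.3f / %.3f\n",
              x$haigis_a0, x$haigis_a1, x$haigis_a2))
  cat(sprintf("  labelled power range: %.2f - %.2f D\n",
              x$power_min, x$power_max))
  invisible(x)
}

#' Built-in lens registry
#'
#' Returns the two lens models of the bilateral paired-eye study design: the
#' Akreos AO (0.50 D grid, 0.40 D tolerance SD) and the Softec HD (0.25 D
#' grid, 0.11 D tolerance SD), with their data-adjusted SRK/T A-constants and
#' Haigis constants.
#'
#' @return A named list of [iol_lens()] objects
#'   (`$akreos_ao`, `$softec_hd`).
#' @examples
#' default_lens_registry()$softec_hd
#' @export
default_lens_registry <- function() {
  list(
    akreos_ao = iol_lens("Akreos AO", interval = 0.50, tolerance_sd = 0.40,
                         a_constant = 118.24, haigis_a0 = 1.706,
                         haigis_a1 = 0.279, haigis_a2 = 0.087),
    softec_hd = iol_lens("Softec HD", interval = 0.25, tolerance_sd = 0.11,
                         a_constant = 118.17, haigis_a0 = 0.565,
                         haigis_a1 = 0.240, haigis_a2 = 0.138))
}

#' Read or write a lens registry as JSON
#'
#' The registry file is a JSON object mapping registry keys to lens fields,
#' the same fields [iol_lens()] takes. A copy of the built-in registry ships
#' with the package (`system.file("extdata", "lens_registry.json",
#' package = "iolmc")`).
#'
#' @param path File path of the JSON registry.
#' @return `read_lens_registry()` returns a named list of `iol_lens` objects;
#'   `write_lens_registry()` returns `path` invisibly.
#' @export
read_lens_registry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(x) do.call(iol_lens, as.list(x)))
  names(out) <- names(raw)
  out
}

#' @rdname read_lens_registry
#' @param registry Named list of [iol_lens()] objects.
#' @export
write_lens_registry <- function(registry, path) {
  stopifnot(is.list(registry), length(registry) >= 1L)
  jsonlite::write_json(lapply(registry, unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
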