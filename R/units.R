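#' Unit conversion helpers
#'
#' All internal computation in clotbg is carried out in SI units (m, kg, s,
#' N, Pa). Configuration files may state quantities in the mixed units common
#' in the clinical and device literature (mm, cm, g, mmHg, kPa); these helpers
#' convert them on input.
#'
#' @name units
NULL

# conversion factors to the SI base of each dimension
.unit_table <- list(
  length   = c("m" = 1, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6),
  mass     = c("kg" = 1, "g" = 1e-3, "mg" = 1e-6),
  time     = c("s" = 1, "ms" = 1e-3),
  pressure = c("Pa" = 1, "kPa" = 1e3, "mmHg" = 133.322, "atm" = 101325),
  force    = c("N" = 1, "mN" = 1e-3, "uN" = 1e-6, "nN" = 1e-9),
  area     = c("m^2" = 1, "cm^2" = 1e-4, "mm^2" = 1e-6, "um^2" = 1e-12),
  stiffness = c("N/m" = 1),
  damping  = c("N.s/m" = 1, "N*s/m" = 1, "N s/m" = 1, "kg/s" = 1),
  density  = c("kg/m^3" = 1, "g/cm^3" = 1e3, "g/ml" = 1e3),
  dimensionless = stats::setNames(c(1, 1, 1, 1e-2, 1e-2),
                                  c("", "1", "fraction", "percent", "%"))
)

#' Convert a tagged quantity to SI
#'
#' Accepts either a bare number (assumed to already be in SI units of the
#' stated dimension) or a list `list(value =, unit =)` as read from a YAML
#' scenario file.
#'
#' @param x numeric scalar or `list(value, unit)`.
#' @param dimension one of `"length"`, `"mass"`, `"time"`, `"pressure"`,
#'   `"force"`, `"area"`, `"stiffness"`, `"damping"`, `"density"`,
#'   `"dimensionless"`.
#' @param field field name used in error messages.
#' @return numeric scalar in SI units.
#' @export
as_si <- function(x, dimension, field = deparse(substitute(x))) {
  tab <- .unit_table[[dimension]]
  if (is.null(tab)) {
    stop("unknown dimension '", dimension, "' for field ", field, call. = FALSE)
  }
  if (is.list(x)) {
    if (is.null(x$value)) {
      stop("field ", field, " must have a 'value' entry", call. = FALSE)
    }
    unit <- if (is.null(x$unit)) names(tab)[1] else as.character(x$unit)
    fac <- tab[unit]
    if (is.na(fac)) {
      stop("unknown unit '", unit, "' for field ", field,
           " (expected one of: ", paste(names(tab), collapse = ", "), ")",
           call. = FALSE)
    }
    as.numeric(x$value) * unname(fac)
  } else if (is.numeric(x) && length(x) == 1L) {
    as.numeric(x)
  } else {
    stop("field ", field, " must be a number or {value, unit} pair",
         call. = FALSE)
  }
}

#' Convert between mmHg and kPa
#'
#' Uses the exact definition 1 mmHg = 0.133322 kPa, so a 120/80 mmHg blood
#' pressure corresponds to roughly 16/11 kPa.
#'
#' @param p pressure in mmHg (for `mmhg_to_kpa`) or kPa (for `kpa_to_mmhg`).
#' @return pressure in the other unit.
#' @examples
#' mmhg_to_kpa(120) # ~16 kPa
#' kpa_to_mmhg(mmhg_to_kpa(80))
#' @export
mmhg_to_kpa <- function(p) p * 0.133322

#' @rdname mmhg_to_kpa
#' @export
kpa_to_mmhg <- function(p) p / 0.133322
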