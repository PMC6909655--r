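#' Oxygen-transport constants
#'
#' Physical constants used throughout the oxygen-transport calculators.
#' `hb_o2_capacity` is the Huefner number: millilitres of oxygen bound per
#' gram of fully saturated haemoglobin. `dissolved_o2_coeff` converts arterial
#' oxygen tension (mmHg) to dissolved oxygen (mL O2 per dL of plasma).
#' `dl_per_l` converts content per decilitre to content per litre, required
#' because haemoglobin is conventionally reported in g/dL while pump flow is
#' in L/min.
#'
#' @param hb_o2_capacity mL O2 bound per g haemoglobin at full saturation.
#' @param dissolved_o2_coeff mL O2 dissolved per dL blood per mmHg PaO2.
#' @param dl_per_l decilitres per litre (unit factor).
#'
#' @return A named list of class `phys_constants`.
#' @examples
#' phys_constants()
#' @export
phys_constants <- function(hb_o2_capacity = 1.36,
                           dissolved_o2_coeff = 0.003,
                           dl_per_l = 10) {
  check_range(hb_o2_capacity, "hb_o2_capacity", 0, strict_lower = TRUE)
  check_range(dissolved_o2_coeff, "dissolved_o2_coeff", 0, strict_lower = TRUE)
  check_range(dl_per_l, "dl_per_l", 0, strict_lower = TRUE)
  structure(
    list(
      hb_o2_capacity = hb_o2_capacity,
      dissolved_o2_coeff = dissolved_o2_coeff,
      dl_per_l = dl_per_l
    ),
    class = "phys_constants"
  )
}

validate_oxygen_state <- function(hb = NULL, sao2 = NULL, svo2 = NULL,
                                  pao2 = NULL, flow = NULL, bsa = NULL) {
  if (!is.null(hb)) check_range(hb, "hb", 0, 25, strict_lower = TRUE)
  if (!is.null(sao2)) check_range(sao2, "sao2", 0, 1)
  if (!is.null(svo2)) check_range(svo2, "svo2", 0, 1)
  if (!is.null(sao2) && !is.null(svo2) &&
      any(svo2 > sao2, na.rm = TRUE)) {
    abort("`svo2` out of range: venous saturation cannot exceed arterial `sao2`.")
  }
  if (!is.null(pao2)) check_range(pao2, "pao2", 0)
  if (!is.null(flow)) check_range(flow, "flow", 0)
  if (!is.null(bsa)) check_range(bsa, "bsa", 0.5, 3.5, strict_lower = TRUE, strict_upper = TRUE)
  invisible(NULL)
}

#' Arterial oxygen content
#'
#' Oxygen carried per decilitre of blood: haemoglobin-bound oxygen
#' (`hb_o2_capacity * hb * sao2`) plus dissolved oxygen
#' (`dissolved_o2_coeff * pao2`).
#'
#' @param hb haemoglobin concentration, g/dL. Must lie in (0, 25].
#' @param sao2 arterial oxygen saturation as a fraction in \[0, 1\].
#' @param pao2 arterial oxygen tension, mmHg (non-negative). Default 0, i.e.
#'   dissolved oxygen neglected.
#' @param constants a [phys_constants()] object.
#'
#' @return Oxygen content in mL O2 per dL of blood. Vectorised.
#' @examples
#' o2_content(hb = 10, sao2 = 1)            # 13.6 mL/dL
#' o2_content(hb = 8, sao2 = 1, pao2 = 100) # 11.18 mL/dL
#' @export
o2_content <- function(hb, sao2, pao2 = 0, constants = phys_constants()) {
  validate_oxygen_state(hb = hb, sao2 = sao2, pao2 = pao2)
  constants$hb_o2_capacity * hb * sao2 + constants$dissolved_o2_coeff * pao2
}

#' Indexed oxygen delivery (DO2i)
#'
#' Oxygen delivered to the tissues per minute per square metre of body surface
#' area: cardiac index times arterial oxygen content, with the dL-to-L unit
#' factor. On bypass the pump flow stands in for cardiac output, so
#' `flow / bsa` is the cardiac index (CI). Call with `bsa = 1` to pass CI
#' directly as `flow`.
#'
#' @param flow pump flow, L/min (or cardiac index if `bsa = 1`).
#' @param hb haemoglobin, g/dL.
#' @param sao2 arterial saturation, fraction in \[0, 1\]. Default 1.
#' @param pao2 arterial oxygen tension, mmHg. Default 0.
#' @param bsa body surface area, m^2. Default 1 (i.e. `flow` is already indexed).
#' @param constants a [phys_constants()] object.
#'
#' @return DO2i in mL O2/min/m^2. Vectorised.
#' @examples
#' do2i(flow = 2.2, hb = 10)                 # 299.2 at CI 2.2, Hb 10
#' do2i(flow = 4.29, hb = 10, bsa = 1.95)    # same CI via flow and BSA
#' @export
do2i <- function(flow, hb, sao2 = 1, pao2 = 0, bsa = 1,
                 constants = phys_constants()) {
  check_range(flow, "flow", 0)
  check_range(bsa, "bsa", 0, strict_lower = TRUE)
  (flow / bsa) * constants$dl_per_l * o2_content(hb, sao2, pao2, constants)
}

#' Cardiac index required to reach a DO2i target
#'
#' Inverts the DO2i relation: the minimum cardiac index at which the given
#' blood composition delivers `do2i_target`. This is the core of the
#' goal-directed pump-flow recommendation: at Hb 8 g/dL and full saturation
#' (dissolved oxygen neglected) a DO2i of 280 mL/min/m^2 needs a CI of about
#' 2.6 L/min/m^2.
#'
#' @param do2i_target target oxygen delivery index, mL O2/min/m^2 (>= 0).
#' @param hb haemoglobin, g/dL.
#' @param sao2 arterial saturation, fraction. Default 1.
#' @param pao2 arterial oxygen tension, mmHg. Default 0.
#' @param constants a [phys_constants()] object.
#'
#' @return Required cardiac index, L/min/m^2. Vectorised.
#' @examples
#' required_ci(280, hb = 8)   # 2.574, rounds to 2.6
#' required_ci(280, hb = 10)  # 2.059
#' @export
required_ci <- function(do2i_target, hb, sao2 = 1, pao2 = 0,
                        constants = phys_constants()) {
  check_range(do2i_target, "do2i_target", 0)
  content <- o2_content(hb, sao2, pao2, constants)
  if (any(content <= 0 & do2i_target > 0, na.rm = TRUE)) {
    abort("`do2i_target` unreachable: arterial oxygen content is zero.")
  }
  out <- do2i_target / (constants$dl_per_l * content)
  zero <- !is.na(do2i_target) & do2i_target == 0
  out[zero] <- 0
  out
}

#' Oxygen extraction ratio (O2ER)
#'
#' Fraction of delivered oxygen consumed by the tissues, approximated from
#' arterial and mixed venous saturations as `(sao2 - svo2) / sao2`.
#'
#' @param sao2 arterial saturation, fraction in (0, 1\].
#' @param svo2 mixed venous saturation, fraction in \[0, sao2\].
#'
#' @return Extraction ratio in \[0, 1\]. Vectorised.
#' @examples
#' o2_extraction_ratio(1.0, 0.68)  # 0.32 at the venous saturation threshold
#' @export
o2_extraction_ratio <- function(sao2, svo2) {
  check_range(sao2, "sao2", 0, 1, strict_lower = TRUE)
  validate_oxygen_state(sao2 = sao2, svo2 = svo2)
  (sao2 - svo2) / sao2
}

#' Indexed oxygen consumption (VO2i) by the Fick principle
#'
#' Oxygen consumed per minute per square metre: cardiac index times the
#' arteriovenous oxygen content difference.
#'
#' @param flow pump flow, L/min (or CI if `bsa = 1`).
#' @param hb haemoglobin, g/dL.
#' @param sao2,svo2 arterial and mixed venous saturations, fractions.
#' @param pao2,pvo2 arterial and venous oxygen tensions, mmHg. Default 0.
#' @param bsa body surface area, m^2. Default 1.
#' @param constants a [phys_constants()] object.
#'
#' @return VO2i in mL O2/min/m^2. Vectorised.
#' @examples
#' vo2i_fick(flow = 2.4, hb = 10, sao2 = 1, svo2 = 0.68)  # 104.448
#' @export
vo2i_fick <- function(flow, hb, sao2, svo2, pao2 = 0, pvo2 = 0, bsa = 1,
                      constants = phys_constants()) {
  check_range(flow, "flow", 0)
  check_range(bsa, "bsa", 0, strict_lower = TRUE)
  check_range(pvo2, "pvo2", 0)
  validate_oxygen_state(hb = hb, sao2 = sao2, svo2 = svo2, pao2 = pao2)
  art <- o2_content(hb, sao2, pao2, constants)
  ven <- constants$hb_o2_capacity * hb * svo2 + constants$dissolved_o2_coeff * pvo2
  (flow / bsa) * constants$dl_per_l * (art - ven)
}
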