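#' Reference calibration peak areas for the two drugs
#'
#' Bundled worked-example data: mean baseline-corrected peak areas of the
#' analytical band (triplicate measurements) for doxorubicin hydrochloride
#' (0.6-1.4 %w/w in KBr, C=O band window 1770-1680 cm^-1) and arterolane
#' maleate (0.2-1.0 %w/w, amide C=O window 1690-1630 cm^-1), each measured
#' in KBr-pellet transmittance and DRIFTS reflectance (Kubelka-Munk) modes.
#' Areas are in the acquisition software's display units; all statistics
#' computed from them are invariant to that fixed scale.
#'
#' @param drug `"DOX"` or `"ALM"`.
#' @param mode `"transmittance"` or `"reflectance"`.
#' @return A tibble with columns `concentration` (%w/w) and `area`.
#' @examples
#' fit_calibration(reference_calibration("DOX", "transmittance"))
#' @export
reference_calibration <- function(drug = c("DOX", "ALM"),
                                  mode = c("transmittance", "reflectance")) {
  drug <- match.arg(drug)
  mode <- match.arg(mode)
  areas <- switch(drug,
    DOX = list(concentration = c(0.6, 0.8, 1.0, 1.2, 1.4),
               transmittance = c(2.131, 2.850, 3.521, 3.913, 4.601),
               reflectance = c(0.614, 0.843, 1.030, 1.201, 1.382)),
    ALM = list(concentration = c(0.2, 0.4, 0.6, 0.8, 1.0),
               transmittance = c(0.644, 0.811, 1.091, 1.400, 1.581),
               reflectance = c(0.180, 0.486, 0.811, 1.060, 1.272))
  )
  tibble::tibble(concentration = areas$concentration, area = areas[[mode]])
}

#' Reference standard-addition recovery records
#'
#' Bundled worked-example data from the recovery studies of both drugs in
#' both modes: drug already present (`cu`), drug added (`ca`) and total drug
#' measured (`cv`), all in mg per 100 mg of drug-KBr mix. Doxorubicin rows
#' use 1:10 w/w drug:KBr stocks (5 mg sample aliquot), arterolane rows
#' 1:20 w/w stocks (3 mg sample aliquot).
#'
#' @inheritParams reference_calibration
#' @return A tibble with columns `cu`, `ca`, `cv` (mg per 100 mg mix).
#' @examples
#' r <- reference_recovery("ALM", "transmittance")
#' recovery_overall(r$cu, r$ca, r$cv)
#' @export
reference_recovery <- function(drug = c("DOX", "ALM"),
                               mode = c("transmittance", "reflectance")) {
  drug <- match.arg(drug)
  mode <- match.arg(mode)
  if (drug == "DOX") {
    cu <- 0.5; ca <- c(0.1, 0.5, 0.9)
    cv <- if (mode == "transmittance") c(0.566, 0.967, 1.375) else c(0.555, 0.969, 1.390)
  } else {
    cu <- 0.15; ca <- c(0.05, 0.45, 0.85)
    cv <- if (mode == "transmittance") c(0.186, 0.550, 0.921) else c(0.182, 0.550, 0.919)
  }
  tibble::tibble(cu = cu, ca = ca, cv = cv)
}

#' Reference formulation assay results
#'
#' Bundled worked-example data: mean drug amount found (five estimations) in
#' a marketed lyophilised doxorubicin injection (label claim 10 mg) and an
#' arterolane maleate tablet (label claim 150 mg), by mode.
#'
#' @inheritParams reference_calibration
#' @return A list with `amount_found_mg` and `label_claim_mg`.
#' @examples
#' a <- reference_assay("ALM", "transmittance")
#' 100 * a$amount_found_mg / a$label_claim_mg  # % purity
#' @export
reference_assay <- function(drug = c("DOX", "ALM"),
                            mode = c("transmittance", "reflectance")) {
  drug <- match.arg(drug)
  mode <- match.arg(mode)
  found <- switch(drug,
    DOX = c(transmittance = 9.283, reflectance = 9.461),
    ALM = c(transmittance = 144.11, reflectance = 148.02)
  )
  list(amount_found_mg = unname(found[[mode]]),
       label_claim_mg = if (drug == "DOX") 10 else 150)
}
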