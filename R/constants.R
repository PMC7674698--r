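#' Physical constants and unit conversions used throughout the package
#'
#' Single registry for the unit chain that converts Monte Carlo tallies
#' (MeV/g per decay) into absorbed dose per unit administered activity
#' (mGy/mCi):
#' 1 mCi = 3.7e7 decays/s, i.e. 2.22e9 decays per mCi-minute, and
#' 1 MeV/g = 1.602e-7 mGy.
#'
#' @return Named list of constants:
#' \describe{
#'   \item{decays_per_mci_s}{3.7e7 (Bq per mCi)}
#'   \item{decays_per_mci_min}{2.22e9}
#'   \item{mgy_per_mev_g}{1.602e-7}
#'   \item{electron_rest_mev}{electron rest energy, MeV}
#' }
#' @export
#' @examples
#' dose_constants()$decays_per_mci_min
dose_constants <- function() {
  list(
    decays_per_mci_s   = 3.7e7,
    decays_per_mci_min = 3.7e7 * 60,
    mgy_per_mev_g      = 1.602e-7,
    electron_rest_mev  = 0.51099895
  )
}

#' ICRP reference organ dose coefficients for Tc-99m DTPA in a 5-year-old
#'
#' Reference absorbed doses per unit administered activity (mGy/mCi) for the
#' kidneys and gonads of a five-year-old under normal and abnormal (impaired)
#' kidney function, used as the comparison baseline for simulated doses.
#'
#' @return data.frame with columns `organ`, `normal`, `abnormal` (mGy/mCi).
#' @export
#' @examples
#' icrp_reference()
icrp_reference <- function() {
  ref <- data.frame(
    organ    = c("kidney", "ovary", "testis"),
    normal   = c(0.407, 0.407, 0.37),
    abnormal = c(0.739, 0.518, 0.407)
  )
  stopifnot(all(ref$normal > 0), all(ref$abnormal >= ref$normal))
  ref
}
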