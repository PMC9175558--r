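#' Final compound concentration after stock deposition
#'
#' Concentration reached when a small volume of DMSO stock is deposited in a
#' well and culture is added on top, e.g. 200 nL of a 10 mM stock under
#' 200 uL of culture gives ~10 uM in the assay.
#'
#' @param stock_mM stock concentration in millimolar (> 0).
#' @param stock_nL deposited stock volume in nanolitres (> 0).
#' @param culture_uL culture volume added, in microlitres (> 0).
#' @return final concentration in micromolar, using the complete final
#'   volume (culture + stock).
#' @examples
#' final_concentration_uM(10, 200, 200) # ~10 uM, the screen condition
#' @export
final_concentration_uM <- function(stock_mM, stock_nL, culture_uL) {
  ss_check_number(stock_mM, "stock_mM", lower = 1e-12)
  ss_check_number(stock_nL, "stock_nL", lower = 1e-12)
  ss_check_number(culture_uL, "culture_uL", lower = 1e-12)
  stock_uL <- stock_nL / 1000
  # nmol in stock / total uL -> mM; x1000 -> uM
  1000 * stock_mM * stock_uL / (culture_uL + stock_uL)
}

#' Optical density after mixing two liquid volumes
#'
#' Volume-weighted mean OD600, e.g. the 1:1 dilution of an OD 0.1 culture
#' with drug solution that starts validation assays at OD 0.05.
#'
#' @param od_a,vol_a OD600 and volume of the first liquid.
#' @param od_b,vol_b OD600 and volume of the second liquid (default a
#'   cell-free solution, `od_b = 0`).
#' @return OD600 of the mixture.
#' @examples
#' mixed_od(0.1, 100, 0, 100) # 0.05 starting OD
#' @export
mixed_od <- function(od_a, vol_a, od_b = 0, vol_b) {
  ss_check_number(od_a, "od_a", lower = 0)
  ss_check_number(vol_a, "vol_a", lower = 1e-12)
  ss_check_number(od_b, "od_b", lower = 0)
  ss_check_number(vol_b, "vol_b", lower = 0)
  (od_a * vol_a + od_b * vol_b) / (vol_a + vol_b)
}
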