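#' Measured per-insert HU statistics of the physical phantoms
#'
#' Mean HU and standard deviation per insert material for the calibration and
#' validation mini-phantoms at 50 and 90 kVp, as measured on the real scanner.
#' These noise levels drive the synthetic noise model, and the mean values
#' serve as external reference points for the HU simulation.
#'
#' @param which `"calibration"` or `"validation"`.
#' @return Data frame with columns `material`, `mean_50`, `sd_50`, `mean_90`,
#'   `sd_90`.
#' @export
measured_hu_table <- function(which = c("calibration", "validation")) {
  which <- match.arg(which)
  if (which == "calibration") {
    data.frame(
      material = c("Air", "AP6", "BR12", "SR2", "Solid Water", "Water", "LV1",
                   "IB3", "B200", "CB2-30%", "CB2-50%", "SB3"),
      mean_50 = c(-1000, -248, -171, -147, -2, 0, 69, 729, 768, 1297, 2483, 3723),
      sd_50   = c(19, 17, 19, 18, 22, 22, 23, 54, 38, 22, 28, 25),
      mean_90 = c(-1000, -173, -115, -64, -7, 0, 68, 456, 482, 857, 1632, 2448),
      sd_90   = c(13, 16, 16, 15, 20, 17, 20, 38, 31, 16, 16, 17))
  } else {
    data.frame(
      material = c("Air", "Paraffin", "Adipose", "BR12", "PMMA", "Water",
                   "Lucite", "Muscle", "Bone"),
      mean_50 = c(-1000, -281, -226, -146, -73, -36, -31, 2, 2230),
      sd_50   = c(17, 13, 16, 16, 12, 15, 13, 14, 29),
      mean_90 = c(-1000, -178, -147, -106, 10, -15, 46, 25, 1508),
      sd_90   = c(13, 11, 13, 13, 11, 12, 12, 12, 22))
  }
}

#' Per-material noise levels for the synthetic scans
#'
#' Named vector of HU noise standard deviations at the measured per-insert
#' levels, for use as `noise_sigma` in [simulate_ct()]. Materials not listed
#' in the measured table (the Solid Water bulk, and Teflon, which was not
#' used in the study) are filled in with the Solid Water and Bone sigmas
#' respectively.
#'
#' @param which Phantom: `"calibration"` or `"validation"`.
#' @param kvp 50 or 90.
#' @return Named numeric vector of sigmas (HU).
#' @export
phantom_noise_levels <- function(which = c("calibration", "validation"),
                                 kvp = 50) {
  which <- match.arg(which)
  t <- measured_hu_table(which)
  col <- if (kvp <= 70) "sd_50" else "sd_90"
  sig <- stats::setNames(t[[col]], t$material)
  if (which == "validation") {
    sw <- measured_hu_table("calibration")
    sig["Solid Water"] <- sw[[col]][sw$material == "Solid Water"]
    sig["Teflon"] <- sig[["Bone"]]
  }
  sig
}

#' Segmentation scheme presets
#'
#' The segmentation schemes investigated in the study: SECT with 3, 4 or 7
#' media and DECT with 7, 8 or 9 media for the validation phantom, plus the
#' mouse schemes (SECT 3 media, DECT 6 media) and the validation-phantom
#' reference media list.
#'
#' @param name One of `"SECT3"`, `"SECT4"`, `"SECT7"`, `"DECT7"`, `"DECT8"`,
#'   `"DECT9"`, `"MOUSE_SECT3"`, `"MOUSE_DECT6"`, `"REFERENCE9"`.
#' @return Character vector of media names, ordered by increasing density.
#' @export
scheme_preset <- function(name) {
  presets <- list(
    SECT3 = c("Air", "Solid Water", "Bone"),
    SECT4 = c("Air", "Adipose", "Muscle", "Bone"),
    SECT7 = c("Air", "Paraffin", "Adipose", "BR12", "Solid Water", "Lucite",
              "Bone"),
    DECT7 = c("Air", "Paraffin", "Adipose", "BR12", "Solid Water", "Lucite",
              "Bone"),
    DECT8 = c("Air", "Paraffin", "Adipose", "BR12", "Solid Water", "Muscle",
              "Lucite", "Bone"),
    DECT9 = c("Air", "Paraffin", "Adipose", "BR12", "Water", "Solid Water",
              "Muscle", "Lucite", "Bone"),
    MOUSE_SECT3 = c("Air", "Brain", "Cortical Bone"),
    MOUSE_DECT6 = c("Air", "ICRU Adipose", "Brain", "Spongiosa", "Cranium",
                    "Cortical Bone"),
    REFERENCE9 = c("Air", "Paraffin", "Adipose", "BR12", "Water",
                   "Solid Water", "Muscle", "Lucite", "Bone"))
  if (!name %in% names(presets)) stop("unknown scheme preset '", name, "'")
  presets[[name]]
}
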