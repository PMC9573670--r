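# Mode-specific image-noise presets.
#
# White-Gaussian HU noise standard deviations measured in a 20 mm x 20 mm
# cylindrical VOI of gel scanned in its container, per accelerator,
# reconstruction algorithm (CBCT vs iterative CBCT) and acquisition mode.
# The simulator characterises a mode solely by this Std.

.noise_preset_table <- function() {
  tibble::tribble(
    ~accelerator, ~algorithm, ~mode,                ~std_hu,
    "Halcyon",   "CBCT",  "Image Gently",        25.841,
    "Halcyon",   "CBCT",  "Image Gently Large",  16.506,
    "Halcyon",   "CBCT",  "Head",                18.917,
    "Halcyon",   "CBCT",  "Head Low Dose",       24.452,
    "Halcyon",   "CBCT",  "Pelvis",               2.984,
    "Halcyon",   "CBCT",  "Pelvis Fast",          7.403,
    "Halcyon",   "CBCT",  "Pelvis Large",         2.772,
    "Halcyon",   "CBCT",  "Pelvis Large Fast",    4.570,
    "Halcyon",   "iCBCT", "Image Gently",         9.581,
    "Halcyon",   "iCBCT", "Image Gently Large",   4.475,
    "Halcyon",   "iCBCT", "Head",                 3.679,
    "Halcyon",   "iCBCT", "Head Low Dose",        8.465,
    "Halcyon",   "iCBCT", "Pelvis",               2.129,
    "Halcyon",   "iCBCT", "Pelvis Fast",          2.703,
    "Halcyon",   "iCBCT", "Pelvis Large",         1.585,
    "Halcyon",   "iCBCT", "Pelvis Large Fast",    1.511,
    "TrueBeam",  "CBCT",  "Head",                11.867,
    "TrueBeam",  "CBCT",  "Image Gently",        17.916,
    "TrueBeam",  "CBCT",  "Pelvis Large",         4.986,
    "TrueBeam",  "CBCT",  "Pelvis",               2.743,
    "TrueBeam",  "CBCT",  "Short Thorax",         7.269,
    "TrueBeam",  "CBCT",  "Spotlight",            4.785,
    "TrueBeam",  "CBCT",  "Thorax",               3.746,
    "TrueBeam",  "iCBCT", "Head",                 4.115,
    "TrueBeam",  "iCBCT", "Image Gently",         6.875,
    "TrueBeam",  "iCBCT", "Pelvis Large",         3.233,
    "TrueBeam",  "iCBCT", "Pelvis",               1.555)
}

#' Table of CBCT/iCBCT noise presets
#'
#' @return tibble with columns `accelerator`, `algorithm`, `mode`, `std_hu`
#'   (the VOI HU standard deviation used as the white-noise level when
#'   simulating that mode).
#' @export
noise_presets <- function() .noise_preset_table()

#' Look up a noise preset
#'
#' @param accelerator `"TrueBeam"` or `"Halcyon"`.
#' @param algorithm `"CBCT"` or `"iCBCT"`.
#' @param mode acquisition mode name, e.g. `"Pelvis"`.
#' @return the HU standard deviation for that mode.
#' @export
#' @examples
#' noise_preset("TrueBeam", "iCBCT", "Pelvis")  # 1.555
noise_preset <- function(accelerator, algorithm, mode) {
  tab <- .noise_preset_table()
  hit <- tab$accelerator == accelerator & tab$algorithm == algorithm &
    tab$mode == mode
  if (!any(hit))
    err_usage(sprintf("no noise preset for %s/%s/%s",
                      accelerator, algorithm, mode))
  tab$std_hu[hit][1]
}
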