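#' Per-lesion scalar measurements
#'
#' Bundle of the scalars the VMSBR threshold model consumes for one lesion:
#' tumor volume `x` (cm^3, measured at end-expiration on 4D CT), motion
#' extent `y` (mm, end-inspiration to end-expiration centroid distance),
#' and the mean activity concentrations of tumor and background (Bq/mL)
#' from which the degraded source-to-background ratio is formed.
#'
#' @param lesion_id identifier (integer or character).
#' @param location anatomical label, e.g. lung lobe ("RUL", "LLL", ...).
#' @param volume_cm3 tumor volume x, cm^3; must be > 0.
#' @param motion_mm peak-to-peak motion extent y, mm; must be >= 0.
#' @param tumor_ac tumor mean activity concentration, Bq/mL.
#' @param background_ac background (lung) mean activity concentration, Bq/mL;
#'   must satisfy `tumor_ac > background_ac > 0`.
#' @return object of class `lesion_measurements`.
#' @export
lesion_measurements <- function(lesion_id, location = NA_character_,
                                volume_cm3, motion_mm, tumor_ac, background_ac) {
  if (!is.finite(volume_cm3) || volume_cm3 <= 0)
    stop("tumor volume must be > 0 cm^3", call. = FALSE)
  if (!is.finite(motion_mm) || motion_mm < 0)
    stop("motion extent must be >= 0 mm", call. = FALSE)
  if (!is.finite(tumor_ac) || !is.finite(background_ac) ||
      background_ac <= 0 || tumor_ac <= background_ac)
    stop("activity concentrations must satisfy tumor_ac > background_ac > 0",
         call. = FALSE)
  structure(
    list(lesion_id = lesion_id, location = location,
         volume_cm3 = volume_cm3, motion_mm = motion_mm,
         tumor_ac = tumor_ac, background_ac = background_ac),
    class = "lesion_measurements"
  )
}

#' Degraded source-to-background ratio of a lesion
#' @param lesion a [lesion_measurements()].
#' @return `tumor_ac / background_ac` (> 1 by construction).
#' @export
degraded_sbr <- function(lesion) lesion$tumor_ac / lesion$background_ac

#' Reference cohort of 24 lung tumors
#'
#' The packaged evaluation cohort: 24 solid lung lesions with relatively
#' homogeneous FDG uptake, imaged with PET and 4D CT in the same session.
#' Columns are the lesion id, lung lobe, tumor volume (cm^3) at
#' end-expiration, peak-to-peak motion extent (mm), tumor mean activity
#' concentration and lung background mean activity concentration (Bq/mL).
#' Volumes span 0.1-28 cm^3 and motion 0.6-15 mm.
#'
#' @param as_list if `TRUE`, return a list of [lesion_measurements()]
#'   objects instead of a data.frame.
#' @return a 24-row data.frame (default) or list of `lesion_measurements`.
#' @export
lung_cohort <- function(as_list = FALSE) {
  df <- data.frame(
    lesion_id = 1:24,
    location = c("RLL", "RUL", "RLL", "RLL", "LUL", "RUL", "RLL", "LUL",
                 "RUL", "RML", "RUL", "LUL", "LUL", "LLL", "RUL", "LLL",
                 "LUL", "RUL", "RLL", "RUL", "LUL", "LUL", "LUL", "LUL"),
    volume_cm3 = c(21.1, 15.3, 1.1, 0.8, 1.0, 28.0, 2.5, 1.5, 0.7, 0.6,
                   13.6, 1.1, 10.3, 0.4, 3.6, 2.2, 4.8, 2.7, 0.7, 1.6,
                   1.5, 5.2, 0.1, 0.5),
    motion_mm = c(10.8, 7.8, 10.3, 6.2, 6.6, 1.5, 13.6, 2.4, 4.6, 2.2,
                  1.0, 8.0, 8.6, 8.8, 4.0, 15.0, 3.1, 2.7, 1.5, 6.3,
                  2.7, 0.6, 1.0, 5.1),
    tumor_ac = c(99801.6, 63799.8, 11910.4, 60414.2, 67181.7, 38936.3,
                 33286.9, 79330.4, 36930.2, 27270.3, 121006, 10314.4,
                 46834.6, 12710.3, 20158.7, 18006.2, 21106.1, 42787.6,
                 38805.8, 65668.8, 41978.3, 65254.3, 8586.72, 42631.4),
    background_ac = c(3576.5, 2515.8, 3127.5, 2267.4, 5692.0, 2890.4,
                      2781.2, 3702.4, 3118.9, 3110.9, 3043.0, 3202.8,
                      1953.3, 3078.1, 2750.5, 3510.5, 2330.7, 1809.4,
                      2488.2, 3080.7, 3384.9, 3680.7, 2409.0, 3683.0),
    stringsAsFactors = FALSE
  )
  if (!as_list) return(df)
  lapply(seq_len(nrow(df)), function(i)
    lesion_measurements(df$lesion_id[i], df$location[i], df$volume_cm3[i],
                        df$motion_mm[i], df$tumor_ac[i], df$background_ac[i]))
}
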