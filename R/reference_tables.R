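# Reference cohort tables from a published retrospective series of 31 eyes of
# 29 consecutive patients with active myopic CNV treated by intravitreal
# anti-VEGF injection. They serve as worked inputs for the cohort-statistics
# layer: the qualitative feature table feeds summarize_features(), the
# biomarker summary feeds relative_ratio()/decrease computations, and the
# correlation table carries the published Spearman coefficients for the
# strength-label mapping. Per-eye raw biomarker values were not published;
# only these printed summaries are available.

#' Reference cohort: qualitative OCTA features (31 eyes, 29 patients)
#'
#' One row per eye: patient number, age (years), sex, eye, spherical
#' equivalent (diopters; `NA` where not reported), and the five qualitative
#' features — overall pattern (`OP`: `OI` organized interlacing / `DVL`
#' disorganized vascular loops), exuberant capillaries (`EC`), anastomoses
#' and loops (`AL`), perilesional hypointense halo (`HH`), feeder vessel
#' (`FV`), each `Y`/`N`.
#'
#' @return A 31-row data.frame with columns
#'   `Pt, Age, Sex, Eye, SE, OP, EC, AL, HH, FV`.
#' @export
mcnv_cohort_features <- function() {
  tab <- c(
    "1,58,F,L,-13.00,OI,Y,Y,N,Y",
    "2,47,M,R,-15.50,OI,Y,Y,Y,N",
    "3,67,F,R,-7.13,OI,Y,Y,Y,Y",
    "4,52,F,R,-13.50,OI,Y,Y,Y,N",
    "5,50,F,L,-12.63,OI,Y,Y,N,N",
    "6,50,M,R,-10.88,OI,Y,Y,Y,Y",
    "7,30,F,L,-13.50,OI,Y,Y,Y,Y",
    "8,51,M,R,NA,OI,Y,Y,N,N",
    "8,51,M,L,NA,DVL,N,Y,N,N",
    "9,49,F,L,-13.25,OI,Y,Y,Y,N",
    "10,31,F,L,-6.50,OI,Y,Y,Y,N",
    "11,43,M,R,-7.75,OI,Y,Y,Y,Y",
    "11,43,M,L,-9.13,OI,Y,Y,Y,N",
    "12,25,F,L,-8.50,OI,Y,Y,Y,N",
    "13,53,F,L,-8.50,OI,Y,Y,Y,N",
    "14,57,F,R,-17.00,OI,Y,Y,Y,N",
    "15,49,M,R,-14.75,OI,Y,Y,Y,N",
    "16,37,M,L,-8.00,OI,Y,Y,Y,Y",
    "17,35,M,L,-13.50,DVL,N,Y,Y,N",
    "18,60,F,R,-15.50,OI,Y,Y,Y,N",
    "19,30,F,L,-11.75,OI,Y,Y,Y,N",
    "20,62,M,R,-11.25,OI,Y,Y,Y,N",
    "21,28,F,L,-11.13,OI,Y,Y,Y,N",
    "22,31,M,L,-7.00,OI,Y,Y,Y,N",
    "23,34,F,L,-7.63,DVL,N,Y,N,N",
    "24,58,F,L,-12.25,OI,Y,Y,Y,N",
    "25,29,M,R,-9.88,DVL,N,N,N,N",
    "26,35,M,R,-13.75,DVL,N,Y,Y,N",
    "27,46,M,R,-18.00,OI,Y,Y,Y,N",
    "28,27,F,R,-17.00,OI,Y,Y,Y,N",
    "29,66,F,L,-10.75,OI,Y,Y,Y,N")
  read.csv(text = paste(c("Pt,Age,Sex,Eye,SE,OP,EC,AL,HH,FV", tab),
                        collapse = "\n"),
           colClasses = c("integer", "integer", "character", "character",
                          "numeric", "character", "character", "character",
                          "character", "character"))
}

#' Reference cohort: biomarker group summaries before and after injection
#'
#' Group means and standard deviations of the ten quantitative biomarkers at
#' baseline and one month after the first anti-VEGF injection (29 eyes with
#' both timepoints), together with the published two-sided p display and the
#' published relative ratio. The `rr_consistent` flag marks the rows whose
#' published RR is reproducible from the printed means at 2 decimals; the
#' `VLD` and `VT` rows are not (the source evidently used unrounded means
#' there).
#'
#' Units: `mCNV_area` and `VA` mm^2; `VL` mm; `VD` um; `JD` n/mm; `CRT` um;
#' `VLD`, `FD`, `VT` dimensionless; `VJ` a count.
#'
#' @return Data.frame `biomarker, baseline_mean, baseline_sd, post_mean,
#'   post_sd, p_display, rr_published, rr_consistent`.
#' @export
mcnv_biomarker_summary <- function() {
  data.frame(
    biomarker     = c("mCNV_area", "VA", "VLD", "FD", "VD",
                      "VL", "VT", "VJ", "JD", "CRT"),
    baseline_mean = c(0.40, 0.20, 0.55, 1.08, 31.11,
                      6.96, 1.26, 49.36, 7.52, 316.75),
    baseline_sd   = c(0.52, 0.20, 0.09, 0.15, 3.78,
                      7.92, 0.07, 47.43, 1.65, 72.72),
    post_mean     = c(0.28, 0.13, 0.56, 0.95, 37.47,
                      4.38, 1.36, 24.50, 5.09, 257.39),
    post_sd       = c(0.41, 0.14, 0.14, 0.23, 13.94,
                      5.81, 0.33, 28.25, 2.26, 30.66),
    p_display     = c("<0.001", "<0.001", "0.829", "<0.001", "0.027",
                      "<0.001", "0.276", "<0.001", "<0.001", "<0.001"),
    rr_published  = c(70.00, 65.00, 102.82, 87.96, 120.44,
                      62.93, 107.93, 49.64, 67.69, 81.26),
    rr_consistent = c(TRUE, TRUE, FALSE, TRUE, TRUE,
                      TRUE, FALSE, TRUE, TRUE, TRUE)
  )
}

#' Reference cohort: correlations of biomarker percent change with CRT change
#'
#' Published Spearman coefficients and p-values between the per-eye percent
#' change of each OCTA biomarker and the percent change of central retinal
#' thickness.
#'
#' @return Data.frame `biomarker, r, p` (9 rows).
#' @export
mcnv_crt_correlations <- function() {
  data.frame(
    biomarker = c("mCNV_area", "VA", "VLD", "FD", "VD", "VL", "VT", "VJ", "JD"),
    r = c(0.552, 0.518, -0.251, 0.446, -0.190, 0.440, -0.152, 0.357, -0.090),
    p = c(0.002, 0.005, 0.197, 0.017, 0.333, 0.019, 0.467, 0.062, 0.649)
  )
}
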