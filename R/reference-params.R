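#' Reference piecewise-model parameter sets
#'
#' Published parameter estimates of the coverage growth-decline model for 17
#' rice treatment combinations from two growing seasons of field and
#' soil-bin nitrogen-by-cultivar trials (treatment codes: F field, S
#' soil-bin; 0N/9N/18N nitrogen rate; LT late transplanting; DJ/NP/SD/SI
#' cultivars; leading number = year). These rows define the realistic
#' parameter envelope used by the synthetic-data generator and serve as
#' ground truth in parameter-recovery experiments.
#'
#' @return A tibble with columns `year`, `treatment`, `K` (maximum coverage,
#'   fraction), `g` (growth rate, 1/day), `d0` (day of maximum growth rate),
#'   `a` (decline curvature, 1/day^2), `d1` (growth-to-decline transition
#'   day) and `r_squared` (goodness of fit of the published estimate).
#' @examples
#' reference_params()
#' @export
reference_params <- function() {
  tibble::tribble(
    ~year, ~treatment,    ~K,     ~g,      ~d0,     ~a,      ~d1,     ~r_squared,
    2023, "23-F-0N",     0.2512, 0.2738,  9.9412, 0.0003, 28.0717, 0.9858,
    2023, "23-F-0N-LT",  0.2081, 0.2889,  8.3847, 0.0002, 26.1100, 0.9825,
    2023, "23-F-9N",     0.3060, 0.2681,  8.6695, 0.0003, 27.0125, 0.9876,
    2023, "23-F-9N-LT",  0.3078, 0.3712,  7.7353, 0.0001, 25.7043, 0.9958,
    2023, "23-S-0N",     0.3272, 0.2658,  9.5009, 0.0003, 28.9899, 0.9926,
    2023, "23-S-18N",    0.3505, 0.2649,  8.2946, 0.0003, 27.4182, 0.9932,
    2023, "23-S-9N",     0.3455, 0.2781,  8.3295, 0.0003, 27.0919, 0.9936,
    2024, "24-F-0N-DJ",  0.2067, 0.3683,  8.5425, 0.0002, 26.3238, 0.9932,
    2024, "24-F-0N-NP",  0.2220, 0.3098, 10.3110, 0.0001, 29.3876, 0.9967,
    2024, "24-F-0N-SD",  0.1574, 0.2746, 11.0649, 0.0000, 31.9771, 0.9918,
    2024, "24-F-0N-SI",  0.2110, 0.2103, 13.0975, 0.0000, 34.0270, 0.9918,
    2024, "24-F-9N-DJ",  0.2500, 0.4606,  4.9593, 0.0002, 17.0930, 0.9672,
    2024, "24-F-9N-NP",  0.2663, 0.3667,  7.5438, 0.0002, 23.7445, 0.9860,
    2024, "24-F-9N-SD",  0.2102, 0.3355,  7.8603, 0.0001, 25.8459, 0.9902,
    2024, "24-F-9N-SI",  0.2782, 0.2695,  8.9365, 0.0002, 28.3735, 0.9905,
    2024, "24-S-0N",     0.1930, 0.1980, 17.6353, 0.0002, 40.1652, 0.9932,
    2024, "24-S-9N",     0.2293, 0.2053, 14.5728, 0.0002, 37.9843, 0.9908,
    2024, "24-S-18N",    0.2171, 0.2060, 16.2943, 0.0003, 38.9029, 0.9923
  )
}

#' Per-parameter envelope of the reference parameter sets
#'
#' @param params A parameter table with columns `K`, `g`, `d0`, `a`, `d1`;
#'   defaults to [reference_params()].
#' @return Tibble with columns `parameter`, `min`, `max`.
#' @export
param_envelope <- function(params = reference_params()) {
  nm <- c("K", "g", "d0", "a", "d1")
  tibble(
    parameter = nm,
    min = vapply(nm, function(p) min(params[[p]]), numeric(1)),
    max = vapply(nm, function(p) max(params[[p]]), numeric(1))
  )
}
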