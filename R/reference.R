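#' Published path-coefficient estimates from the motivating study
#'
#' The pooled regression results reported by the two-wave study of Latinx
#' early adolescents' perceived impact of Arizona's SB 1070 immigration law,
#' ethnic identity content, and self-esteem: all five equations with
#' coefficient, standard error, t, fractional (Barnard-Rubin) df, and p.
#' Useful as a worked example — the products of these printed paths
#' reproduce the published indirect-effect point estimates — and as the
#' default magnitudes of the synthetic generator's structural paths.
#'
#' @return A tibble with columns `equation`, `term`, `estimate`,
#'   `std.error`, `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' est <- reference_path_estimates()
#' indirect_effects(est)
reference_path_estimates <- function() {
  tibble::tribble(
    ~equation, ~term,        ~estimate, ~std.error, ~statistic, ~df,      ~p.value,
    "total",   "(Intercept)", 1.137,     0.160,      7.104,      228.442,  0.001,
    "total",   "x_t1",        0.000,     0.007,     -0.001,      245.110,  0.999,
    "total",   "u1_t1",      -0.008,     0.030,     -0.279,      246.669,  0.781,
    "total",   "u2_t1",       0.013,     0.035,      0.360,      205.608,  0.720,
    "total",   "u3_t1",       0.021,     0.026,      0.796,      263.682,  0.427,
    "total",   "u4_t1",       0.591,     0.039,     15.229,      268.033,  0.001,
    "m1",      "(Intercept)", 1.286,     0.263,      4.882,      254.463,  0.001,
    "m1",      "x_t1",        0.019,     0.012,      1.487,      256.650,  0.138,
    "m1",      "u1_t1",       0.463,     0.048,      9.733,      309.039,  0.001,
    "m1",      "u2_t1",       0.104,     0.053,      1.956,      307.427,  0.051,
    "m1",      "u3_t1",       0.022,     0.044,      0.490,      260.604,  0.624,
    "m1",      "u4_t1",      -0.048,     0.066,     -0.735,      272.144,  0.463,
    "m2",      "(Intercept)", 1.461,     0.291,      5.021,      183.819,  0.001,
    "m2",      "x_t1",        0.032,     0.013,      2.553,      240.629,  0.011,
    "m2",      "u1_t1",       0.109,     0.049,      2.239,      282.341,  0.026,
    "m2",      "u2_t1",       0.355,     0.057,      6.187,      231.842,  0.001,
    "m2",      "u3_t1",       0.034,     0.044,      0.775,      252.301,  0.439,
    "m2",      "u4_t1",       0.173,     0.067,      2.571,      243.399,  0.011,
    "m3",      "(Intercept)", 1.303,     0.283,      4.596,      249.107,  0.001,
    "m3",      "x_t1",        0.005,     0.014,      0.376,      218.867,  0.707,
    "m3",      "u1_t1",       0.070,     0.052,      1.345,      277.309,  0.180,
    "m3",      "u2_t1",      -0.015,     0.058,     -0.254,      282.642,  0.800,
    "m3",      "u3_t1",       0.310,     0.046,      6.766,      291.092,  0.001,
    "m3",      "u4_t1",       0.266,     0.068,      3.913,      307.481,  0.001,
    "y",       "(Intercept)", 0.952,     0.168,      5.678,      217.535,  0.001,
    "y",       "m1_t2",       0.001,     0.030,      0.017,      187.838,  0.987,
    "y",       "m2_t2",       0.117,     0.031,      3.788,      175.303,  0.001,
    "y",       "m3_t2",       0.011,     0.025,      0.450,      264.596,  0.653,
    "y",       "x_t1",       -0.004,     0.007,     -0.518,      243.345,  0.605,
    "y",       "u1_t1",      -0.022,     0.032,     -0.697,      245.063,  0.487,
    "y",       "u2_t1",      -0.029,     0.035,     -0.818,      223.838,  0.414,
    "y",       "u3_t1",       0.013,     0.027,      0.489,      249.803,  0.625,
    "y",       "u4_t1",       0.568,     0.038,     14.917,      289.959,  0.001
  )
}
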