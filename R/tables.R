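#' Reference energy table (subject 1)
#'
#' Per-channel absolute-amplitude energies of the main feature segment for
#' one representative subject performing the six lower-limb actions (y1 raise
#' right leg ... y6 standing to sitting), over the 8-channel montage CH1
#' right rectus femoris ... CH8 left gastrocnemius. These values serve as a
#' worked-example fixture for the weighted feature method and as gain
#' templates for the synthetic generator.
#'
#' @return a `6 x 8` numeric matrix, rows `action1..action6`, columns
#'   `CH1..CH8`.
#' @export
table2_fixture <- function() {
  m <- matrix(c(
    4.4075,  7.3995,  3.3853, 3.0290,  2.5047, 10.0337,  6.0779, 6.1198,
    5.6125,  4.2509, 16.7769, 2.2035,  1.9899,  5.0036,  2.7665, 6.7932,
    2.7713,  6.8533,  4.1197, 8.5512,  3.7452, 16.5496,  5.3684, 3.8048,
    3.7745,  2.8812,  2.6002, 8.2039,  4.2894, 25.1282, 12.0314, 2.5562,
    31.3369, 13.8150, 23.4856, 2.1398, 18.2272, 14.9905, 24.0917, 2.6756,
    23.3024, 12.5947, 25.4307, 2.0793, 15.1958, 19.6991, 29.0533, 3.3588
  ), nrow = 6L, byrow = TRUE)
  dimnames(m) <- list(paste0("action", 1:6), paste0("CH", 1:8))
  m
}

#' Reference muscle-action correlation table (subject 1)
#'
#' The published channel weights corresponding to [table2_fixture()], i.e.
#' the values of `C[i] = 8 * e[i] / sum(e)` rounded to 4 decimal places.
#' Used as an independent check of [channel_weights()]; each row sums to 8
#' up to the printed rounding.
#'
#' @return a `6 x 8` numeric matrix, rows `action1..action6`, columns
#'   `CH1..CH8`.
#' @export
table3_fixture <- function() {
  m <- matrix(c(
    0.8208, 1.3780, 0.6304, 0.5641, 0.4664, 1.8686, 1.1319, 1.1397,
    0.9890, 0.7491, 2.9565, 0.3883, 0.3507, 0.8817, 0.4875, 1.1971,
    0.4283, 1.0592, 0.6367, 1.3216, 0.5788, 2.5577, 0.8297, 0.5880,
    0.4913, 0.3750, 0.3384, 1.0678, 0.5583, 3.2706, 1.5659, 0.3327,
    1.9172, 0.8452, 1.4368, 0.1309, 1.1151, 0.9171, 1.4739, 0.1637,
    1.4262, 0.7708, 1.5564, 0.1273, 0.9300, 1.2056, 1.7781, 0.2056
  ), nrow = 6L, byrow = TRUE)
  dimnames(m) <- list(paste0("action", 1:6), paste0("CH", 1:8))
  m
}
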