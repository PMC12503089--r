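## Shared fixtures: the preset study conditions used across tests.

scen_info <- function(id) scenario(id)$info

## Printed reference values for the 12 preset scenarios: calibrated parameters
## (2 dp) and optimal sampling times, used as external anchors.
reference_params <- list(
  `1` = c(1.24, 15.81, 1919.88, 0.00),
  `2` = c(1.79, 23.46, 2056.98, 0.00),
  `3` = c(1.15, 14.12, 2706.91, 0.00),
  `4` = c(1.49, 19.80, 2741.19, 0.00),
  `5` = c(1.24, 15.81, 1919.89, 0.00),
  `6` = c(1.82, 23.72, 2067.73, 1.63),
  `7` = c(1.15, 14.12, 2706.91, 0.00),
  `8` = c(1.49, 19.83, 2742.92, 0.25),
  `9` = c(1.24, 15.92, 1926.89, 0.66),
  `10` = c(2.23, 27.84, 2218.27, 27.31),
  `11` = c(1.15, 14.13, 2707.91, 0.10),
  `12` = c(1.59, 21.13, 2812.25, 10.68)
)

reference_times <- list(
  `1` = c(0.30, 29.67, 183.83),
  `2` = c(11.44, 69.91, 211.03),
  `3` = c(0.03, 29.54, 260.40),
  `4` = c(5.54, 69.76, 269.56),
  `5` = c(0.00, 0.35, 30.17, 184.44),
  `6` = c(0.00, 15.02, 77.01, 219.17),
  `7` = c(0.00, 0.07, 31.63, 262.93),
  `8` = c(0.00, 7.07, 73.83, 274.33),
  `9` = c(0.00, 3.28, 44.92, 202.59),
  `10` = c(0.00, 30.80, 108.87, 254.92),
  `11` = c(0.00, 0.91, 43.30, 277.31),
  `12` = c(0.00, 21.67, 108.27, 313.48)
)

## calibrate-or-fail helper so tests read cleanly
calibrated <- function(id) {
  cal <- calibrate(scen_info(id))
  stopifnot(cal$converged)
  cal$params
}
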