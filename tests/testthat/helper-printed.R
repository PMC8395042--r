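# Published marginal areas (km^2) of the four period transition blocks,
# in code order 1..10 (offshore, tidal flat, marsh, grassland,
# river/lake, fish pond, paddy, reservoir, construction, rainfed).
# One marginal cell of the published 2000-2009 block is inconsistent
# with its own column cells: grassland transfer-in prints 5.97 but the
# cells sum to 5.89; the value here is the cell sum, asserted as such.
printedMarginals <- list(
  `1990_2015` = list(
    out = c(469.22, 249.50, 112.11, 1.88, 0.13, 24.02, 4.62, 0.91,
            1.10, 12.46),
    `in` = c(37.93, 163.63, 214.84, 11.78, 2.52, 127.68, 124.94, 64.51,
             42.59, 85.53)),
  `1990_2000` = list(
    out = c(321.05, 180.67, 103.76, 1.98, 0.13, 20.77, 4.83, 1.07,
            1.07, 12.68),
    `in` = c(38.66, 252.28, 136.21, 1.80, 1.60, 72.34, 48.25, 6.20,
             14.42, 76.25)),
  `2000_2009` = list(
    out = c(218.94, 253.12, 75.85, 1.72, 1.60, 59.51, 38.59, 3.25,
            10.88, 57.84),
    `in` = c(82.10, 146.78, 136.70, 5.89, 2.45, 85.13, 74.86, 77.21,
             33.26, 76.92)),
  `2009_2015` = list(
    out = c(189.61, 150.68, 103.84, 5.62, 2.44, 69.69, 45.25, 30.14,
            15.66, 72.11),
    `in` = c(63.42, 166.81, 145.18, 12.08, 3.36, 99.50, 86.35, 18.23,
             24.33, 65.78)))
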