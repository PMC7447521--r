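# Shared fixtures: kept small so the whole suite stays fast.

# Single-region phantom spec used across the preprocessing tests.
demo_phantom_spec <- function(...) {
  phantom_spec(list(cuboid_region("caudal", c(16, 16, 16), 5,
                                  intensity_max = 60.17, time_50 = 39.66,
                                  slope = 10)),
               ...)
}

# Post-infusion frame grid: 16 frames over 3 h at 12-min spacing.
demo_times <- seq(12, 192, by = 12)

# Square polygon (pixel coordinates) as n x 2 matrix.
square_poly <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side))
}
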