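# Shared fixtures built in code.

# Two-level test frame: dark disk on a bright background.
two_level_frame <- function(width = 120, height = 100, cx = 60, cy = 50,
                            r = 20, disk = 20, bg = 150) {
  f <- matrix(bg, height, width)
  f[gazefuzz:::disk_mask(height, width, cx, cy, r)] <- disk
  f
}

# Membership parameter fixture reproducing the worked-example degrees
# (0.75/0.25 at 0.30, 0.00/1.00 at 0.50, 0.32/0.68 at 0.45).
fig_params <- function() example_membership_params()

# Independent trapezoidal-integration oracle for COG and BOA on the clipped
# union of the output membership functions, at grid step `dx`.
defuzz_oracle <- function(heights, dx = 1e-4) {
  x <- seq(0, 1, by = dx)
  mfL <- pmin(pmax(1 - 2 * x, 0), 1)
  mfM <- pmin(pmax(1 - 2 * abs(x - 0.5), 0), 1)
  mfH <- pmin(pmax(2 * x - 1, 0), 1)
  y <- pmax(pmin(mfL, heights[["L"]]), pmin(mfM, heights[["M"]]),
            pmin(mfH, heights[["H"]]))
  seg <- (y[-1] + y[-length(y)]) / 2 * dx
  area <- sum(seg)
  cog <- sum((x[-1] * y[-1] + x[-length(x)] * y[-length(y)]) / 2 * dx) / area
  cum <- cumsum(seg)
  i <- which(cum >= area / 2)[1]
  # interpolate the bisector inside its grid cell
  prev <- if (i > 1) cum[i - 1] else 0
  boa <- x[i] + dx * (area / 2 - prev) / seg[i]
  list(cog = cog, boa = boa, area = area)
}

# Aggregate per-label heights from an iv table, as defuzzify() does.
iv_heights <- function(ivs) {
  vapply(c(L = "L", M = "M", H = "H"),
         function(l) if (any(ivs$out == l)) max(ivs$iv[ivs$out == l]) else 0,
         numeric(1))
}
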