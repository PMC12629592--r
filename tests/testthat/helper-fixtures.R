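# Shared fixtures: all synthetic, built in code at test time.

# one horizontal microtubule truth row (the renderer consumes this schema)
makeMT <- function(anchor_x = 15000, anchor_y = 24 * 160, rate = 0,
                   lifetime = 1e6, lattice = 8000, id = 1L) {
  data.frame(id = id, anchor_x_nm = anchor_x, anchor_y_nm = anchor_y,
             growth_rate_um_min = rate, lifetime_s = lifetime,
             observed_lifetime_s = lifetime, censored = lifetime > 1e5,
             lattice_length_nm = lattice)
}

# analytic erfc edge profile sampled at pixel centres, optional shot noise
makeEdgeProfile <- function(xe, sigma = 120, A = 400, bg = 100, px = 160,
                            span = c(-1600, 1600), noisy = FALSE) {
  x <- seq(span[1], span[2], by = px)
  y <- bg + A * pnorm((xe - x) / sigma)
  if (noisy) y <- rpois(length(y), y)
  list(x = x, y = y)
}

# brute-force grid search over the edge position: for each candidate xe the
# remaining parameters (bg, A) enter linearly and are solved by weighted
# least squares (the same 1/I shot-noise weights the package fit uses);
# sigma is scanned on a coarse grid.  Independent of the
# Levenberg-Marquardt path.
gridSearchEdge <- function(x, y, step = 0.1, sigmas = seq(80, 180, by = 10)) {
  w <- 1 / pmax(y, 1)
  rssAt <- function(xe, sg) {
    b <- pnorm((xe - x) / sg)
    # closed-form weighted OLS of y on (1, b)
    mb <- sum(w * b) / sum(w); my <- sum(w * y) / sum(w)
    sxx <- sum(w * (b - mb)^2)
    beta <- if (sxx > 0) sum(w * (b - mb) * (y - my)) / sxx else 0
    sum(w * (y - my - beta * (b - mb))^2)
  }
  scan <- function(grid, sigmas) {
    best <- c(xe = NA_real_, sg = NA_real_, rss = Inf)
    for (sg in sigmas) for (xe in grid) {
      r <- rssAt(xe, sg)
      if (r < best["rss"]) best <- c(xe = xe, sg = sg, rss = r)
    }
    best
  }
  coarse <- scan(seq(min(x), max(x), by = 10), sigmas)
  fine <- scan(seq(coarse[["xe"]] - 15, coarse[["xe"]] + 15, by = step),
               seq(max(10, coarse[["sg"]] - 10), coarse[["sg"]] + 10,
                   by = 2))
  fine[["xe"]]
}
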