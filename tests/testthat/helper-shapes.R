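# Analytic shape rasterizers and brute-force oracles shared across tests.
# These are deliberately independent of the package's own rasterization and
# moment code paths.

# Rectangle of height h (along its long axis) and width w, long axis at
# `angle_deg` from the vertical image axis, rasterized by a direct
# point-in-rotated-rectangle membership test on 0-based pixel centers.
rect_mask <- function(h, w, angle_deg = 0, shape = c(300, 300)) {
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th))    # long axis, (row, col), pointing down
  v <- c(-sin(th), cos(th))   # perpendicular
  ctr <- (shape - 1) / 2
  r <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  dr <- r - ctr[1]; dc <- cc - ctr[2]
  pu <- dr * u[1] + dc * u[2]
  pv <- dr * v[1] + dc * v[2]
  abs(pu) <= h / 2 & abs(pv) <= w / 2
}

disk_mask <- function(radius, shape = c(101, 101)) {
  ctr <- (shape - 1) / 2
  r <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  (r - ctr[1])^2 + (cc - ctr[2])^2 <= radius^2
}

# brute-force second-order central moments: explicit double loop over
# pixels, integer coordinate arithmetic
brute_moments <- function(coords) {
  n <- nrow(coords)
  sr <- 0; sc <- 0
  for (i in seq_len(n)) {
    sr <- sr + coords[i, 1]
    sc <- sc + coords[i, 2]
  }
  rbar <- sr / n; cbar <- sc / n
  mu20 <- 0; mu02 <- 0; mu11 <- 0
  for (i in seq_len(n)) {
    dr <- coords[i, 1] - rbar
    dc <- coords[i, 2] - cbar
    mu20 <- mu20 + dr * dr
    mu02 <- mu02 + dc * dc
    mu11 <- mu11 + dr * dc
  }
  c(mu20 = unname(mu20), mu02 = unname(mu02), mu11 = unname(mu11))
}

# brute-force two-way ANOVA ICC oracle: explicit sum-of-squares loops
brute_icc <- function(x, model) {
  n <- nrow(x); k <- ncol(x)
  gm <- 0
  for (i in 1:n) for (j in 1:k) gm <- gm + x[i, j]
  gm <- gm / (n * k)
  ssr <- 0
  for (i in 1:n) {
    ri <- 0
    for (j in 1:k) ri <- ri + x[i, j]
    ssr <- ssr + (ri / k - gm)^2
  }
  msr <- k * ssr / (n - 1)
  ssc <- 0
  for (j in 1:k) {
    cj <- 0
    for (i in 1:n) cj <- cj + x[i, j]
    ssc <- ssc + (cj / n - gm)^2
  }
  msc <- n * ssc / (k - 1)
  sse <- 0
  for (i in 1:n) for (j in 1:k) {
    ri <- mean(x[i, ]); cj <- mean(x[, j])
    sse <- sse + (x[i, j] - ri - cj + gm)^2
  }
  mse <- sse / ((n - 1) * (k - 1))
  if (model == "two_way_mixed_3_1") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
}

# strip class/attributes, keep dim (for bit-exact raster comparisons)
unclass_dim <- function(x) {
  d <- dim(x)
  x <- as.vector(x)
  dim(x) <- d
  x
}

# minimal angulation record tibble for agreement tests
make_records <- function(image_id, fdi_codes, angles,
                         schema = fdi_schema()) {
  i <- match(as.character(fdi_codes), schema$fdi_code)
  tibble::tibble(
    image_id = image_id,
    fdi_code = as.character(fdi_codes),
    arch = schema$arch[i],
    side = schema$side[i],
    tooth_type = schema$tooth_type[i],
    angle_deg = angles,
    angle_abs_deg = abs(angles),
    angle_vs_border_deg = 90 - abs(angles),
    n_pixels_total = 2000L,
    n_pixels_retained = 1560L,
    degenerate_flag = FALSE,
    apical_fraction = 0.22
  )
}
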