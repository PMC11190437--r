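# independent oracles and small fixture builders shared across tests

# radial position of the intensity maximum of a circle of radius R blurred
# by an isotropic Gaussian of sd s: fixed point of r = R * I1(rR/s^2)/I0(rR/s^2)
blurred_ring_peak_r <- function(R, s) {
  r <- R
  for (i in 1:500) r <- R * besselI(r * R / s^2, 1) / besselI(r * R / s^2, 0)
  r
}

# numeric radial average of an image around a centre (nm coordinates)
radial_profile <- function(image, centre_nm, pixel_size_nm, radii_nm) {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  vapply(radii_nm, function(r) {
    p <- vapply(th, function(a) {
      prof <- sample_line_profile(image, centre_nm + r * c(cos(a), sin(a)),
                                  0, pixel_size_nm, half_length_nm = 0,
                                  step_nm = 1)
      prof$intensity[1]
    }, 0)
    mean(p)
  }, 0)
}

# exhaustive nearest-neighbour pairing (no tie-break subtleties: used on
# generic-position point sets only)
brute_force_pairs <- function(green, red, cutoff_nm = 500) {
  out <- data.frame(green_id = integer(), red_id = integer(),
                    distance_nm = numeric())
  for (i in seq_len(nrow(green))) {
    best <- NA_integer_; bd <- Inf
    for (j in seq_len(nrow(red))) {
      d <- sqrt((green$x_nm[i] - red$x_nm[j])^2 +
                  (green$y_nm[i] - red$y_nm[j])^2)
      if (d < bd) { bd <- d; best <- j }
    }
    if (is.finite(bd) && bd <= cutoff_nm)
      out <- rbind(out, data.frame(green_id = i, red_id = best,
                                   distance_nm = bd))
  }
  out
}

# reciprocal-best-hit resolution by explicit scan over all id pairs
brute_force_rbh <- function(ab, ba, thr = 1e-5) {
  best <- function(h, q) {
    s <- h[h$query_id == q, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    s <- s[order(s$e_value, -s$bitscore, s$subject_id), , drop = FALSE]
    s[1, ]
  }
  out <- data.frame(id_a = character(), id_b = character())
  for (a in sort(unique(ab$query_id))) {
    ha <- best(ab, a)
    if (is.null(ha) || ha$e_value > thr) next
    hb <- best(ba, ha$subject_id)
    if (is.null(hb) || hb$e_value > thr) next
    if (hb$subject_id == a)
      out <- rbind(out, data.frame(id_a = a, id_b = ha$subject_id))
  }
  out
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
enum_mwu_p <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  pooled <- c(g1, g2)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">"))
  }
  u_obs <- sum(outer(g1, g2, ">"))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  centre <- n1 * n2 / 2
  mean(abs(us - centre) >= abs(u_obs - centre))
}

# one noiseless point-sampled Gaussian image (closed-form field, no pixel
# integration) for profile-fit oracles
analytic_gaussian_image <- function(nr, nc, cx_nm, cy_nm, sigma_nm, px,
                                    amplitude = 1000) {
  x <- (seq_len(nc) - 1) * px
  y <- (seq_len(nr) - 1) * px
  amplitude * outer(exp(-(y - cy_nm)^2 / (2 * sigma_nm^2)),
                    exp(-(x - cx_nm)^2 / (2 * sigma_nm^2)))
}

default_config <- function(...) scene_config(...)

centre_of <- function(config) {
  c((config$image_size_px[2] - 1) / 2,
    (config$image_size_px[1] - 1) / 2) * config$pixel_size_nm
}
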