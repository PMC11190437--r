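#' Pair each green focus to its nearest red focus with a distance cutoff
#'
#' Euclidean nearest-neighbour assignment from green (tagged-protein) foci
#' to red (basal-body marker) foci; pairs farther apart than `cutoff_nm`
#' are dropped and reported as unpaired. Ties at equal distance are broken
#' to the brighter red focus, then to the lower (y, x) position.
#'
#' @param green_foci,red_foci data frames with `x_nm`, `y_nm` and
#'   optionally `amplitude` columns (focus records from [fit_centre()]).
#' @param cutoff_nm pairing cutoff in nm (default 500).
#' @return list with `pairs` (data frame: `green_id`, `red_id`,
#'   `distance_nm`) and `unpaired_green` (integer indices).
#' @export
pair_to_nearest <- function(green_foci, red_foci, cutoff_nm = 500) {
  ng <- nrow(green_foci); nr <- nrow(red_foci)
  pairs <- data.frame(green_id = integer(), red_id = integer(),
                      distance_nm = numeric())
  if (!ng) return(list(pairs = pairs, unpaired_green = integer()))
  if (!nr) return(list(pairs = pairs, unpaired_green = seq_len(ng)))
  amp <- if ("amplitude" %in% names(red_foci)) red_foci$amplitude else
    rep(0, nr)
  unpaired <- integer()
  for (i in seq_len(ng)) {
    d <- sqrt((red_foci$x_nm - green_foci$x_nm[i])^2 +
                (red_foci$y_nm - green_foci$y_nm[i])^2)
    cand <- which(d <= min(d) + 1e-9)
    if (length(cand) > 1L)  # tie: brighter red focus, then lower (y, x)
      cand <- cand[order(-amp[cand], red_foci$y_nm[cand],
                         red_foci$x_nm[cand])]
    k <- cand[1]
    if (d[k] > cutoff_nm) {
      unpaired <- c(unpaired, i)
    } else {
      pairs <- rbind(pairs, data.frame(green_id = i, red_id = k,
                                       distance_nm = d[k]))
    }
  }
  list(pairs = pairs, unpaired_green = unpaired)
}

# bilinear interpolation at continuous pixel coordinates (1-based, pixel
# centres at integers); positions must lie within the pixel-centre hull
.bilinear <- function(image, xp, yp) {
  nr <- nrow(image); nc <- ncol(image)
  x0 <- pmin(pmax(floor(xp), 1L), nc - 1L)
  y0 <- pmin(pmax(floor(yp), 1L), nr - 1L)
  fx <- xp - x0; fy <- yp - y0
  image[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    image[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
    image[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
    image[cbind(y0 + 1L, x0 + 1L)] * fx * fy
}

#' Sample an intensity profile along a straight line through a centre
#'
#' Bilinear interpolation at `position = -half_length_nm ... half_length_nm`
#' (step `step_nm`) along the direction `angle_deg` (0 = horizontal,
#' increasing towards the image's downward y axis). Samples falling outside
#' the image are clipped.
#'
#' @param image numeric matrix.
#' @param centre_nm numeric pair (x, y) in nm.
#' @param angle_deg line angle in degrees.
#' @param pixel_size_nm pixel pitch, nm.
#' @param half_length_nm half line length, nm.
#' @param step_nm sampling step, nm (default quarter pixel).
#' @return data frame: `position_nm`, `intensity`.
#' @export
sample_line_profile <- function(image, centre_nm, angle_deg, pixel_size_nm,
                                half_length_nm = 600,
                                step_nm = pixel_size_nm / 4) {
  if (!is.numeric(step_nm) || step_nm <= 0) stop("step_nm must be positive")
  nr <- nrow(image); nc <- ncol(image)
  cx <- centre_nm[1] / pixel_size_nm + 1
  cy <- centre_nm[2] / pixel_size_nm + 1
  if (cx < 1 || cx > nc || cy < 1 || cy > nr)
    stop("centre lies outside the image")
  pos <- seq(-half_length_nm, half_length_nm, by = step_nm)
  th <- angle_deg * pi / 180
  xp <- cx + pos * cos(th) / pixel_size_nm
  yp <- cy + pos * sin(th) / pixel_size_nm
  keep <- xp >= 1 & xp <= nc & yp >= 1 & yp <= nr
  data.frame(position_nm = pos[keep],
             intensity = .bilinear(image, xp[keep], yp[keep]))
}

#' Pseudo-diameter: maximum effective diameter over a 45-line angle sweep
#'
#' Intensity across the structure is sampled along 45 straight lines
#' through the centre at 0, 4, ..., 176 degrees (180 would duplicate 0).
#' A Gaussian is fitted to each profile and its standard deviation, scaled
#' by `diameter_scale`, is the line's effective diameter. Lines whose fit
#' fails or whose effective diameter exceeds `max_diameter_nm` are marked
#' invalid (outlier exclusion). The pseudo-diameter is the maximum over the
#' valid lines; ties go to the smallest angle.
#'
#' @param image numeric matrix.
#' @param centre_nm structure centre (x, y) in nm, from [fit_centre()].
#' @param pixel_size_nm pixel pitch, nm.
#' @param half_length_nm half line length, nm.
#' @param step_nm profile sampling step, nm.
#' @param diameter_scale multiplier from fitted sigma to effective
#'   diameter. The default 1 takes the standard deviation itself as the
#'   effective diameter; see [calibrate_diameter_scale()] for mapping
#'   measured values to true diameters.
#' @param max_diameter_nm per-line outlier bound, nm (default 500).
#' @return object of class `pseudo_diameter`: `profiles` (data frame:
#'   `angle_deg`, `sigma_nm`, `effective_diameter_nm`, `valid`),
#'   `pseudo_diameter_nm`, `argmax_angle_deg`, `n_valid`, `valid`. If all
#'   45 lines are invalid the structure is flagged unmeasurable
#'   (`valid = FALSE`, measurements `NA`).
#' @export
pseudo_diameter <- function(image, centre_nm, pixel_size_nm,
                            half_length_nm = 600,
                            step_nm = pixel_size_nm / 4,
                            diameter_scale = 1,
                            max_diameter_nm = 500) {
  angles <- seq(0, 176, by = 4)
  sig <- rep(NA_real_, length(angles))
  ok <- logical(length(angles))
  for (i in seq_along(angles)) {
    prof <- sample_line_profile(image, centre_nm, angles[i], pixel_size_nm,
                                half_length_nm, step_nm)
    if (nrow(prof) < 8L) next
    fit <- fit_gaussian_1d(prof$position_nm, prof$intensity)
    if (fit$converged && is.finite(fit$sigma) && fit$sigma > 0) {
      sig[i] <- fit$sigma
      ok[i] <- TRUE
    }
  }
  eff <- diameter_scale * sig
  valid <- ok & !is.na(eff) & eff <= max_diameter_nm
  profiles <- data.frame(angle_deg = angles, sigma_nm = sig,
                         effective_diameter_nm = eff, valid = valid)
  if (!any(valid)) {
    warning("all 45 line profiles invalid; structure unmeasurable")
    res <- list(profiles = profiles, pseudo_diameter_nm = NA_real_,
                argmax_angle_deg = NA_real_, n_valid = 0L, valid = FALSE)
  } else {
    k <- which(valid)[which.max(eff[valid])]  # which.max: first max, so
    res <- list(profiles = profiles,          # ties break to smallest angle
                pseudo_diameter_nm = eff[k],
                argmax_angle_deg = angles[k],
                n_valid = sum(valid), valid = TRUE)
  }
  class(res) <- "pseudo_diameter"
  res
}

#' @export
print.pseudo_diameter <- function(x, ...) {
  if (x$valid)
    cat(sprintf("pseudo-diameter %.1f nm at %d deg (%d/45 valid lines)\n",
                x$pseudo_diameter_nm, as.integer(x$argmax_angle_deg),
                x$n_valid))
  else cat("unmeasurable structure (no valid line profiles)\n")
  invisible(x)
}

#' Per-protein metrology summaries (mean and s.e.m.)
#'
#' Aggregates per-cell distance and pseudo-diameter records into per-protein
#' mean and standard error of the mean (sample SD over sqrt(n)).
#'
#' @param records data frame with `protein_id`, `distance_nm`,
#'   `pseudo_diameter_nm` (one row per cell).
#' @return data frame: `protein_id`, `n_cells`, `mean_distance_nm`,
#'   `sem_distance_nm`, `mean_pseudo_diameter_nm`,
#'   `sem_pseudo_diameter_nm`. Single-cell groups get `NA` s.e.m. with a
#'   warning.
#' @export
aggregate_metrology <- function(records) {
  if (!nrow(records)) stop("no metrology records")
  stopifnot(all(c("protein_id", "distance_nm", "pseudo_diameter_nm") %in%
                  names(records)))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- do.call(rbind, lapply(split(records, records$protein_id), function(g) {
    n <- nrow(g)
    data.frame(protein_id = g$protein_id[1], n_cells = n,
               mean_distance_nm = mean(g$distance_nm),
               sem_distance_nm = if (n >= 2) sem(g$distance_nm) else NA_real_,
               mean_pseudo_diameter_nm = mean(g$pseudo_diameter_nm),
               sem_pseudo_diameter_nm = if (n >= 2) sem(g$pseudo_diameter_nm)
                                        else NA_real_)
  }))
  rownames(out) <- NULL
  if (any(out$n_cells < 2))
    warning("single-cell group(s): s.e.m. undefined, set to NA")
  out
}

#' Calibrate the sigma-to-diameter scale on synthetic rings
#'
#' Renders noiseless rings of known diameters under a given optical
#' configuration, measures their pseudo-diameters (with the sigma scale at
#' 1), and regresses true on measured diameter. The fitted line maps
#' measured effective diameters to physical diameters under that PSF.
#'
#' @param config a [scene_config()].
#' @param true_diameters_nm ring diameters to render.
#' @param amplitude photons per ring.
#' @return list: `table` (data frame `true_diameter_nm`,
#'   `measured_pseudo_diameter_nm`), `intercept`, `slope`.
#' @export
calibrate_diameter_scale <- function(config,
                                     true_diameters_nm = c(220, 280, 340, 400),
                                     amplitude = 1e4) {
  px <- config$pixel_size_nm
  centre <- c((config$image_size_px[2] - 1) / 2,
              (config$image_size_px[1] - 1) / 2) * px
  measured <- vapply(true_diameters_nm, function(d) {
    sc <- render_scene(config, structures = list(
      annular_structure(centre, d, ring_weight = 1, amplitude = amplitude,
                        channel = "green")), noise = FALSE)
    pseudo_diameter(sc$images$green, centre, px,
                    max_diameter_nm = Inf)$pseudo_diameter_nm
  }, 0)
  tab <- data.frame(true_diameter_nm = true_diameters_nm,
                    measured_pseudo_diameter_nm = measured)
  fit <- stats::lm(true_diameter_nm ~ measured_pseudo_diameter_nm, data = tab)
  list(table = tab, intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]))
}
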