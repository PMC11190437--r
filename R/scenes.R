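#' Scene configuration for synthetic two-colour rendering
#'
#' Describes the virtual microscope used by [render_scene()]: field size,
#' pixel pitch, PSF width, and the two noise sources (photon shot noise and
#' camera read noise).
#'
#' Defaults emulate a 100x/NA 1.46 widefield system with an sCMOS-class
#' camera: 65 nm/px (6.5 um camera pixel over 100x magnification) and an
#' isotropic Gaussian PSF of sigma = 0.21 * lambda / NA with lambda = 510 nm
#' (green emission), giving ~73 nm.
#'
#' @param image_size_px integer pair, rows and columns of the field.
#' @param pixel_size_nm pixel pitch in nm/px.
#' @param psf_sigma_nm standard deviation of the Gaussian PSF, nm.
#' @param background_level expected background, photons per pixel.
#' @param read_noise_sd Gaussian read noise standard deviation, photons.
#' @param seed integer master seed; per-scene RNG streams are derived from
#'   `(seed, scene_index)` so each scene is independently reproducible.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(image_size_px = c(64L, 64L),
                         pixel_size_nm = 65,
                         psf_sigma_nm = 73,
                         background_level = 5,
                         read_noise_sd = 2,
                         seed = 1L) {
  image_size_px <- as.integer(image_size_px)
  if (length(image_size_px) != 2L || any(image_size_px < 1L))
    stop("image_size_px must be a positive integer pair")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be > 0")
  if (!is.numeric(psf_sigma_nm) || psf_sigma_nm <= 0)
    stop("psf_sigma_nm must be > 0")
  if (background_level < 0) stop("background_level must be >= 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  structure(list(image_size_px = image_size_px,
                 pixel_size_nm = pixel_size_nm,
                 psf_sigma_nm = psf_sigma_nm,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Point emitter (basal-body-marker-like punctum)
#'
#' @param centre_nm real pair, continuous image coordinates in nm. Origin is
#'   the centre of the first pixel; x runs along columns (rightward), y along
#'   rows (downward).
#' @param amplitude expected total photons emitted into the image.
#' @param channel `"green"` or `"red"`.
#' @return object of class `emitter`.
#' @export
emitter <- function(centre_nm, amplitude, channel = c("green", "red")) {
  channel <- match.arg(channel)
  if (length(centre_nm) != 2L || !is.numeric(centre_nm))
    stop("centre_nm must be a numeric pair")
  if (amplitude <= 0) stop("amplitude must be > 0")
  structure(list(centre_nm = as.numeric(centre_nm), amplitude = amplitude,
                 channel = channel),
            class = "emitter")
}

#' Annular appendage structure (transition-fibre-like)
#'
#' A circle of true diameter `true_diameter_nm` whose photons are spread
#' either on the circle itself (`ring_weight = 1`), uniformly over the
#' enclosed disc (`ring_weight = 0`), or a mixture.
#'
#' @param centre_nm real pair in nm (see [emitter()] for the convention).
#' @param true_diameter_nm true structure diameter, nm, in (0, 1000).
#' @param ring_weight fraction of intensity on the ring vs the filled disc.
#' @param amplitude expected total photons.
#' @param channel `"green"` or `"red"`.
#' @return object of class `annular_structure`.
#' @export
annular_structure <- function(centre_nm, true_diameter_nm, ring_weight = 1,
                              amplitude = 1e4, channel = c("green", "red")) {
  channel <- match.arg(channel)
  if (length(centre_nm) != 2L || !is.numeric(centre_nm))
    stop("centre_nm must be a numeric pair")
  if (true_diameter_nm <= 0 || true_diameter_nm >= 1000)
    stop("true_diameter_nm must be in (0, 1000)")
  if (ring_weight < 0 || ring_weight > 1) stop("ring_weight must be in [0,1]")
  if (amplitude <= 0) stop("amplitude must be > 0")
  structure(list(centre_nm = as.numeric(centre_nm),
                 true_diameter_nm = true_diameter_nm,
                 ring_weight = ring_weight, amplitude = amplitude,
                 channel = channel),
            class = "annular_structure")
}

# nm extent of the field: pixel centres at 0 .. (n-1)*px, bounds half a pixel
# beyond the outermost centres
.scene_bounds_nm <- function(config) {
  px <- config$pixel_size_nm
  list(x = c(-px / 2, (config$image_size_px[2] - 0.5) * px),
       y = c(-px / 2, (config$image_size_px[1] - 0.5) * px))
}

.in_bounds <- function(config, centre_nm, margin_nm = 0) {
  b <- .scene_bounds_nm(config)
  centre_nm[1] >= b$x[1] + margin_nm && centre_nm[1] <= b$x[2] - margin_nm &&
    centre_nm[2] >= b$y[1] + margin_nm && centre_nm[2] <= b$y[2] - margin_nm
}

# expected photons per pixel for one point source: analytic integration of
# the Gaussian PSF over each pixel area (sub-pixel truth is exact, not
# point-sampled)
.point_mass <- function(config, centre_nm, amplitude) {
  px <- config$pixel_size_nm
  s <- config$psf_sigma_nm
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  xe <- (seq_len(nc + 1) - 1.5) * px
  ye <- (seq_len(nr + 1) - 1.5) * px
  amplitude * outer(diff(stats::pnorm(ye, centre_nm[2], s)),
                    diff(stats::pnorm(xe, centre_nm[1], s)))
}

# structure = mixture of a sharp ring and a uniform disc, each discretised
# as point sources convolved analytically with the PSF
.structure_mass <- function(config, st, n_ring = 180L, n_disc_rings = 6L) {
  R <- st$true_diameter_nm / 2
  img <- matrix(0, config$image_size_px[1], config$image_size_px[2])
  add_ring <- function(img, radius, amp, npts) {
    th <- (seq_len(npts) - 1) / npts * 2 * pi
    for (t in th) {
      img <- img + .point_mass(config,
                               st$centre_nm + radius * c(cos(t), sin(t)),
                               amp / npts)
    }
    img
  }
  if (st$ring_weight > 0)
    img <- add_ring(img, R, st$amplitude * st$ring_weight, n_ring)
  if (st$ring_weight < 1) {
    # uniform disc: concentric rings with weights proportional to radius
    rj <- (seq_len(n_disc_rings) - 0.5) / n_disc_rings * R
    wj <- rj / sum(rj)
    damp <- st$amplitude * (1 - st$ring_weight)
    for (j in seq_len(n_disc_rings))
      img <- add_ring(img, rj[j], damp * wj[j], 12L * j)
  }
  img
}

.derive_seed <- function(seed, scene_index) {
  # distinct 32-bit streams per (seed, scene); doubles stay exact below 2^53
  x <- (as.numeric(seed) * 48271 + as.numeric(scene_index) * 16807)
  as.integer(x %% 2147483629)
}

# run `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a dual-channel synthetic scene
#'
#' The noiseless expectation in each channel is the background plus every
#' object convolved with the Gaussian PSF (integrated analytically over
#' pixel areas). With `noise = TRUE`, Poisson shot noise is applied to the
#' expectation and Gaussian read noise added on top. The returned ground
#' truth records every object and, for each structure, the distance to the
#' nearest red emitter.
#'
#' @param config a [scene_config()].
#' @param emitters list of [emitter()] objects.
#' @param structures list of [annular_structure()] objects.
#' @param noise logical; apply Poisson + read noise.
#' @param scene_index integer; combined with `config$seed` to derive this
#'   scene's RNG stream.
#' @return object of class `tf_scene`: `images` (named list `green`, `red`
#'   of matrices), `truth` (data frames `emitters`, `structures`,
#'   `pair_distances_nm`), `config`, `scene_index`.
#' @export
render_scene <- function(config, emitters = list(), structures = list(),
                         noise = TRUE, scene_index = 1L) {
  stopifnot(inherits(config, "scene_config"))
  for (e in emitters) {
    if (!inherits(e, "emitter")) stop("emitters must be emitter objects")
    if (!.in_bounds(config, e$centre_nm))
      stop(sprintf("emitter at (%.1f, %.1f) nm is outside image bounds",
                   e$centre_nm[1], e$centre_nm[2]))
  }
  for (st in structures) {
    if (!inherits(st, "annular_structure"))
      stop("structures must be annular_structure objects")
    if (!.in_bounds(config, st$centre_nm, margin_nm = st$true_diameter_nm / 2))
      stop(sprintf("structure at (%.1f, %.1f) nm extends outside image bounds",
                   st$centre_nm[1], st$centre_nm[2]))
  }

  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  expect <- list(green = matrix(config$background_level, nr, nc),
                 red = matrix(config$background_level, nr, nc))
  for (e in emitters)
    expect[[e$channel]] <- expect[[e$channel]] +
      .point_mass(config, e$centre_nm, e$amplitude)
  for (st in structures)
    expect[[st$channel]] <- expect[[st$channel]] + .structure_mass(config, st)

  images <- expect
  if (noise) {
    images <- .with_seed(.derive_seed(config$seed, scene_index), {
      lapply(expect, function(m) {
        n <- matrix(stats::rpois(length(m), as.vector(m)), nrow(m), ncol(m))
        if (config$read_noise_sd > 0)
          n <- n + matrix(stats::rnorm(length(m), 0, config$read_noise_sd),
                          nrow(m), ncol(m))
        n
      })
    })
  }

  em_df <- if (length(emitters)) {
    data.frame(object_id = seq_along(emitters),
               type = "emitter",
               x_nm = vapply(emitters, function(e) e$centre_nm[1], 0),
               y_nm = vapply(emitters, function(e) e$centre_nm[2], 0),
               amplitude = vapply(emitters, function(e) e$amplitude, 0),
               channel = vapply(emitters, function(e) e$channel, ""))
  } else {
    data.frame(object_id = integer(), type = character(), x_nm = numeric(),
               y_nm = numeric(), amplitude = numeric(), channel = character())
  }
  st_df <- if (length(structures)) {
    data.frame(object_id = seq_along(structures),
               type = "structure",
               x_nm = vapply(structures, function(s) s$centre_nm[1], 0),
               y_nm = vapply(structures, function(s) s$centre_nm[2], 0),
               diameter_nm = vapply(structures, function(s) s$true_diameter_nm, 0),
               ring_weight = vapply(structures, function(s) s$ring_weight, 0),
               amplitude = vapply(structures, function(s) s$amplitude, 0),
               channel = vapply(structures, function(s) s$channel, ""))
  } else {
    data.frame(object_id = integer(), type = character(), x_nm = numeric(),
               y_nm = numeric(), diameter_nm = numeric(),
               ring_weight = numeric(), amplitude = numeric(),
               channel = character())
  }

  red_idx <- which(em_df$channel == "red")
  pair <- data.frame(structure_id = integer(), emitter_id = integer(),
                     distance_nm = numeric())
  if (nrow(st_df) && length(red_idx)) {
    for (i in seq_len(nrow(st_df))) {
      d <- sqrt((em_df$x_nm[red_idx] - st_df$x_nm[i])^2 +
                  (em_df$y_nm[red_idx] - st_df$y_nm[i])^2)
      k <- which.min(d)
      pair <- rbind(pair, data.frame(structure_id = i,
                                     emitter_id = em_df$object_id[red_idx[k]],
                                     distance_nm = d[k]))
    }
  }

  structure(list(images = images,
                 truth = list(emitters = em_df, structures = st_df,
                              pair_distances_nm = pair),
                 config = config, scene_index = as.integer(scene_index)),
            class = "tf_scene")
}

#' Cell-cycle fixture: scenes with 2 or 4 basal-body-marker foci
#'
#' Generates one scene per cell at stages G1 (2 red foci), G1/S transition
#' (2 red foci, both basal bodies mature) and S phase (4 red foci), placing
#' green appendage structures according to a recruitment-timing rule:
#' * `early` - the green structure appears on both mature basal bodies at
#'   the G1/S transition, before marker-focus duplication;
#' * `late` - a single green structure until four red foci are present;
#' * `probasal` - green signal co-located with every red focus (recruited to
#'   probasal bodies in the previous cell cycle).
#'
#' @param config a [scene_config()]; the field must be at least ~4 um wide.
#' @param n_cells positive integer.
#' @param stage_mix named proportions over `c("G1","G1S","S")`, summing to 1.
#'   Counts are allocated deterministically by largest remainder.
#' @param tfp_timing recruitment-timing rule.
#' @param structure_diameter_nm diameter of the green structures.
#' @param amplitude photons per object.
#' @param noise logical, as in [render_scene()].
#' @return list with `scenes` (list of `tf_scene`) and `cells` (data frame:
#'   `cell_id`, `stage`, `red_focus_count`, `green_focus_count`,
#'   `green_on_probasal`).
#' @export
make_cell_cycle_fixture <- function(config, n_cells,
                                    stage_mix = c(G1 = 1/3, G1S = 1/3, S = 1/3),
                                    tfp_timing = c("early", "late", "probasal"),
                                    structure_diameter_nm = 340,
                                    amplitude = 2e4,
                                    noise = TRUE) {
  tfp_timing <- match.arg(tfp_timing)
  if (!is.numeric(n_cells) || n_cells <= 0) stop("n_cells must be positive")
  n_cells <- as.integer(n_cells)
  stages <- c("G1", "G1S", "S")
  if (is.null(names(stage_mix)) || !all(names(stage_mix) %in% stages) ||
      abs(sum(stage_mix) - 1) > 1e-8)
    stop("stage_mix must be named proportions over G1, G1S, S summing to 1")
  mix <- stage_mix[stages]; mix[is.na(mix)] <- 0
  # largest-remainder allocation of cells to stages
  raw <- mix * n_cells
  cnt <- floor(raw)
  rem <- n_cells - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  stage_of <- rep(stages, times = cnt)

  px <- config$pixel_size_nm
  fx <- (config$image_size_px[2] - 1) * px
  fy <- (config$image_size_px[1] - 1) * px
  c0 <- c(fx / 2 - 600, fy / 2)   # old mature basal body (x, y)

  scenes <- vector("list", n_cells)
  cells <- data.frame(cell_id = seq_len(n_cells), stage = stage_of,
                      red_focus_count = NA_integer_,
                      green_focus_count = NA_integer_,
                      green_on_probasal = FALSE)
  for (i in seq_len(n_cells)) {
    stage <- stage_of[i]
    jit <- .with_seed(.derive_seed(config$seed, 100000L + i),
                      stats::runif(2, -50, 50))
    oMBB <- c(c0[1], c0[2]) + jit
    oPBB <- oMBB + c(-250, 280)        # probasal body next to its mature body
    nMBB <- oMBB + c(1200, 0)          # maturing/new body
    nPBB <- nMBB + c(250, 280)
    red_pos <- switch(stage,
      G1 = list(oMBB, oPBB),
      G1S = list(oMBB, nMBB),          # both bodies mature, pre-duplication
      S = list(oMBB, oPBB, nMBB, nPBB))
    green_pos <- switch(tfp_timing,
      early = switch(stage, G1 = list(oMBB), G1S = list(oMBB, nMBB),
                     S = list(oMBB, nMBB)),
      late = switch(stage, G1 = list(oMBB), G1S = list(oMBB),
                    S = list(oMBB, nMBB)),
      probasal = red_pos)
    ems <- lapply(red_pos, function(p) emitter(p, amplitude, "red"))
    sts <- lapply(green_pos, function(p)
      annular_structure(p, structure_diameter_nm, ring_weight = 1,
                        amplitude = amplitude, channel = "green"))
    scenes[[i]] <- render_scene(config, ems, sts, noise = noise,
                                scene_index = i)
    cells$red_focus_count[i] <- length(red_pos)
    cells$green_focus_count[i] <- length(green_pos)
    cells$green_on_probasal[i] <- tfp_timing == "probasal"
  }
  list(scenes = scenes, cells = cells)
}

#' Write a scene as a two-page float TIFF (channel order green, red)
#'
#' Float TIFF samples are stored in `[0, 1]`, so pixel values are divided by
#' a per-scene `intensity_scale` (the maximum over both channels); the scale
#' is returned and recorded by [write_scenes()] so images round-trip exactly.
#'
#' @param scene a `tf_scene`.
#' @param path output file path.
#' @return the intensity scale, invisibly.
#' @export
write_scene_tiff <- function(scene, path) {
  stopifnot(inherits(scene, "tf_scene"))
  sc <- max(1, max(scene$images$green), max(scene$images$red))
  pages <- list(pmax(scene$images$green, 0) / sc,
                pmax(scene$images$red, 0) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(sc)
}

#' Read a scene TIFF written by [write_scene_tiff()]
#'
#' @param path TIFF path.
#' @param intensity_scale scale recorded at write time.
#' @return named list of matrices `green`, `red`.
#' @export
read_scene_tiff <- function(path, intensity_scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L) stop("expected a two-page (green, red) TIFF")
  list(green = pages[[1]] * intensity_scale,
       red = pages[[2]] * intensity_scale)
}

#' Write a scene set: TIFFs plus a ground-truth CSV
#'
#' @param scenes list of `tf_scene` objects.
#' @param dir output directory (created if needed).
#' @return path of the ground-truth CSV, invisibly.
#' @export
write_scenes <- function(scenes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    f <- file.path(dir, sprintf("scene_%04d.tif", i))
    scale <- write_scene_tiff(sc, f)
    tr <- sc$truth
    both <- rbind(
      if (nrow(tr$emitters))
        cbind(tr$emitters[, c("object_id", "type", "x_nm", "y_nm", "channel")],
              diameter_nm = NA_real_),
      if (nrow(tr$structures))
        cbind(tr$structures[, c("object_id", "type", "x_nm", "y_nm", "channel")],
              diameter_nm = tr$structures$diameter_nm))
    if (!is.null(both) && nrow(both)) {
      both <- cbind(scene_id = i, file = basename(f),
                    intensity_scale = scale, both)
      rows[[length(rows) + 1L]] <- both
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scene_id = integer(), file = character(),
               intensity_scale = numeric(), object_id = integer(),
               type = character(), x_nm = numeric(), y_nm = numeric(),
               channel = character(), diameter_nm = numeric())
  out <- file.path(dir, "ground_truth.csv")
  utils::write.csv(truth, out, row.names = FALSE)
  invisible(out)
}
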