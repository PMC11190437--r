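#' Pipeline configuration
#'
#' One nested configuration drives the end-to-end screen: scene rendering,
#' focus detection, geometry measurement, the inclusion gate, and the
#' group-comparison stage. The default demo cohort contains three
#' synthetic proteins: a ring-like transition-fibre candidate, a
#' point-like basal-body-width control at the barrel, and a point-like
#' transition-zone control beyond the distal gate, so that exactly the
#' ring-like candidate passes the gate.
#'
#' @param seed master seed; every stochastic stage derives its stream from
#'   it.
#' @param n_cells cells simulated per protein.
#' @param scene named list of [scene_config()] arguments.
#' @param detection named list: `prominence` (photon threshold for
#'   [detect_maxima()]), `window_px` (fit window).
#' @param geometry named list: `cutoff_nm`, `half_length_nm`, `step_nm`
#'   (`NULL` = quarter pixel), `diameter_scale`, `max_diameter_nm`.
#' @param gate named list of [control_baselines()] arguments.
#' @param stats named list: `alpha`.
#' @param proteins list of protein descriptors: `id`, `kind` (`"ring"` or
#'   `"point"`), `offset_nm` (true distance from the red marker focus),
#'   and for rings `diameter_nm`.
#' @param out_dir optional output directory for [run_screen()] tables.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_cells = 6L,
                            scene = list(),
                            detection = list(prominence = 50, window_px = 15L),
                            geometry = list(cutoff_nm = 500,
                                            half_length_nm = 600,
                                            step_nm = NULL,
                                            diameter_scale = 1,
                                            max_diameter_nm = 500),
                            gate = list(poc5_mean_distance_nm = 150,
                                        tzp150_mean_distance_nm = 450,
                                        bbp136_mean_pseudo_diameter_nm = 110),
                            stats = list(alpha = 0.05),
                            proteins = NULL,
                            out_dir = NULL) {
  if (is.null(proteins)) {
    proteins <- list(
      list(id = "TFP340", kind = "ring", offset_nm = 300, diameter_nm = 340),
      list(id = "BBP136", kind = "point", offset_nm = 200),
      list(id = "TZP150", kind = "point", offset_nm = 480))
  }
  cfg <- structure(list(seed = as.integer(seed),
                        n_cells = as.integer(n_cells),
                        scene = scene, detection = detection,
                        geometry = geometry, gate = gate, stats = stats,
                        proteins = proteins, out_dir = out_dir),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema-style checks on types, ranges and required fields; invalid
#' configurations are rejected before any computation.
#'
#' @param config a `pipeline_config` (or plain list with its fields).
#' @return the config, invisibly, if valid; otherwise an error.
#' @export
validate_pipeline_config <- function(config) {
  need <- c("seed", "n_cells", "scene", "detection", "geometry", "gate",
            "stats", "proteins")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  sc <- config$scene
  if (!is.null(sc$pixel_size_nm) && sc$pixel_size_nm <= 0)
    stop("scene.pixel_size_nm must be > 0")
  if (!is.null(sc$psf_sigma_nm) && sc$psf_sigma_nm <= 0)
    stop("scene.psf_sigma_nm must be > 0")
  if (config$n_cells < 2L) stop("n_cells must be >= 2")
  if (config$detection$prominence <= 0) stop("detection.prominence must be > 0")
  g <- config$gate
  do.call(control_baselines, g)   # bounds and ordering checks
  if (config$stats$alpha < 0 || config$stats$alpha > 1)
    stop("stats.alpha must be in [0, 1]")
  for (p in config$proteins) {
    if (is.null(p$id) || is.null(p$kind) || is.null(p$offset_nm))
      stop("each protein needs id, kind, offset_nm")
    if (!p$kind %in% c("ring", "point")) stop("protein kind must be ring or point")
    if (p$kind == "ring" && is.null(p$diameter_nm))
      stop("ring proteins need diameter_nm")
  }
  invisible(config)
}

#' Write / read a pipeline configuration as JSON
#'
#' The JSON round-trips losslessly: `read_pipeline_config()` re-validates
#' and returns an equivalent `pipeline_config`.
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return `write_pipeline_config()`: the path, invisibly;
#'   `read_pipeline_config()`: the config.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  raw$seed <- as.integer(raw$seed)
  raw$n_cells <- as.integer(raw$n_cells)
  cfg <- structure(raw, class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

# deterministic fingerprint of the scientific configuration: md5 of its
# canonical JSON text, excluding the output location
.config_hash <- function(config) {
  core <- unclass(config)
  core$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(core, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the end-to-end screen on a synthetic cohort
#'
#' Executes simulate, detect, measure, gate and stats stages: renders
#' `n_cells` scenes per protein (one red marker focus plus the protein's
#' green structure at its true offset, noise on), detects and sub-pixel
#' centres foci in both channels, pairs green to nearest red and measures
#' pseudo-diameters, aggregates per-protein metrology and applies the
#' inclusion gate, and compares each candidate's per-cell pseudo-diameters
#' against the barrel-width control by Mann-Whitney U. With `out_dir` set,
#' writes `foci.csv`, `measurements.csv`, `metrology.csv`,
#' `candidates.csv`, `comparisons.json` and `manifest.json`; outputs are
#' byte-identical across reruns with the same configuration.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list: `foci`, `measurements`, `metrology`,
#'   `candidates` (metrology plus gate verdicts), `comparisons`,
#'   `manifest`.
#' @export
run_screen <- function(config) {
  validate_pipeline_config(config)
  scfg <- do.call(scene_config, c(config$scene, list(seed = config$seed)))
  px <- scfg$pixel_size_nm
  geom <- config$geometry
  step_nm <- if (is.null(geom$step_nm)) px / 4 else geom$step_nm
  centre0 <- c((scfg$image_size_px[2] - 1) / 2,
               (scfg$image_size_px[1] - 1) / 2) * px

  scenes <- .stage("simulate", {
    out <- list(); idx <- 0L
    for (p in config$proteins) {
      for (cell in seq_len(config$n_cells)) {
        idx <- idx + 1L
        ang <- .with_seed(.derive_seed(scfg$seed, 500000L + idx),
                          stats::runif(1, 0, 2 * pi))
        red_at <- centre0
        green_at <- centre0 + p$offset_nm * c(cos(ang), sin(ang))
        ems <- list(emitter(red_at, 2e4, "red"))
        sts <- if (p$kind == "ring")
          list(annular_structure(green_at, p$diameter_nm, ring_weight = 1,
                                 amplitude = 2e4, channel = "green"))
        else NULL
        if (p$kind == "point")
          ems <- c(ems, list(emitter(green_at, 2e4, "green")))
        sc <- render_scene(scfg, ems, sts %||% list(), noise = TRUE,
                           scene_index = idx)
        out[[idx]] <- list(scene = sc, protein_id = p$id, cell_id = cell)
      }
    }
    out
  })

  foci <- .stage("detect", {
    rows <- lapply(scenes, function(s) {
      g <- locate_foci(s$scene$images$green, px, config$detection$prominence,
                       config$detection$window_px, "green")
      r <- locate_foci(s$scene$images$red, px, config$detection$prominence,
                       config$detection$window_px, "red")
      both <- rbind(g, r)
      if (nrow(both))
        cbind(protein_id = s$protein_id, cell_id = s$cell_id, both)
    })
    do.call(rbind, Filter(Negate(is.null), rows))
  })

  measurements <- .stage("measure", {
    rows <- lapply(scenes, function(s) {
      f <- foci[foci$protein_id == s$protein_id & foci$cell_id == s$cell_id, ]
      g <- f[f$channel == "green", , drop = FALSE]
      r <- f[f$channel == "red", , drop = FALSE]
      if (!nrow(g) || !nrow(r)) return(NULL)
      pr <- pair_to_nearest(g, r, geom$cutoff_nm)
      if (!nrow(pr$pairs)) return(NULL)
      k <- pr$pairs$green_id[1]   # brightest green focus is listed first
      pd <- pseudo_diameter(s$scene$images$green,
                            c(g$x_nm[k], g$y_nm[k]), px,
                            half_length_nm = geom$half_length_nm,
                            step_nm = step_nm,
                            diameter_scale = geom$diameter_scale,
                            max_diameter_nm = geom$max_diameter_nm)
      data.frame(protein_id = s$protein_id, cell_id = s$cell_id,
                 distance_nm = pr$pairs$distance_nm[1],
                 pseudo_diameter_nm = pd$pseudo_diameter_nm,
                 argmax_angle_deg = pd$argmax_angle_deg,
                 n_valid_profiles = pd$n_valid)
    })
    out <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(out) || !nrow(out)) stop("no measurable cells")
    out
  })

  candidates <- .stage("gate", {
    metrology <- aggregate_metrology(measurements)
    apply_inclusion_gate(metrology, do.call(control_baselines, config$gate))
  })

  comparisons <- .stage("stats", {
    ctrl_id <- config$proteins[[which.min(vapply(config$proteins, function(p)
      if (p$kind == "point") p$offset_nm else Inf, 0))]]$id
    ctrl <- measurements$pseudo_diameter_nm[measurements$protein_id == ctrl_id]
    out <- list()
    for (p in config$proteins) {
      if (p$id == ctrl_id) next
      x <- measurements$pseudo_diameter_nm[measurements$protein_id == p$id]
      if (length(x) < 2 || length(ctrl) < 2) next
      m <- mann_whitney_u(x, ctrl)
      out[[p$id]] <- list(vs = ctrl_id, u_statistic = m$u_statistic,
                          p_value = m$p_value, n1 = m$n1, n2 = m$n2,
                          median1 = m$median1, median2 = m$median2,
                          iqr1 = m$iqr1, iqr2 = m$iqr2)
    }
    out
  })

  manifest <- list(pipeline = "tfscreen::run_screen",
                   package_version = as.character(utils::packageVersion("tfscreen")),
                   config_hash = .config_hash(config),
                   seed = config$seed,
                   n_scenes = length(scenes),
                   n_foci = nrow(foci),
                   n_measurements = nrow(measurements),
                   n_candidates = nrow(candidates))

  result <- list(foci = foci, measurements = measurements,
                 metrology = candidates[setdiff(names(candidates),
                                                "gate_verdict")],
                 candidates = candidates, comparisons = comparisons,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, f) utils::write.csv(df, file.path(config$out_dir, f),
                                           row.names = FALSE)
    foci_out <- foci
    foci_out$manifest_id <- manifest$config_hash
    wr(foci_out, "foci.csv")
    meas_out <- measurements; meas_out$manifest_id <- manifest$config_hash
    wr(meas_out, "measurements.csv")
    cand_out <- candidates; cand_out$manifest_id <- manifest$config_hash
    wr(cand_out, "candidates.csv")
    jsonlite::write_json(comparisons,
                         file.path(config$out_dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
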