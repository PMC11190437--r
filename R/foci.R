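#' Detect local maxima by topographic prominence
#'
#' Finds local intensity maxima (8-connectivity) and scores each by its
#' prominence: the peak height minus the highest saddle connecting it to a
#' higher peak, computed by flooding the image in order of decreasing
#' intensity with union-find merging. The global maximum's prominence is its
#' height above the image background (minimum pixel). Plateaus collapse to a
#' single peak; ties between equal-height pixels are broken to the lower
#' (y, x) position.
#'
#' @param image numeric matrix.
#' @param prominence_threshold positive; peaks with prominence at or below
#'   this are dropped.
#' @param channel optional channel label carried through to the output.
#' @return data frame of peak candidates sorted by decreasing intensity:
#'   `row`, `col` (1-based pixels), `value`, `prominence`, `channel`.
#' @export
detect_maxima <- function(image, prominence_threshold, channel = NA_character_) {
  if (!is.matrix(image) || !length(image)) stop("image must be a nonempty matrix")
  if (!is.numeric(prominence_threshold) || prominence_threshold <= 0)
    stop("prominence_threshold must be positive")
  nr <- nrow(image); nc <- ncol(image)
  v <- as.vector(image)
  n <- length(v)
  rows <- ((seq_len(n) - 1L) %% nr) + 1L
  cols <- ((seq_len(n) - 1L) %/% nr) + 1L
  ord <- order(-v, rows, cols)
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  comp_peak <- integer(n)        # root -> index of the component's peak pixel
  processed <- logical(n)
  peak_prom <- rep(NA_real_, n)  # peak pixel -> prominence once dethroned

  for (p in ord) {
    r <- rows[p]; cc <- cols[p]
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc2 <- cc + dc
      if (rr >= 1L && rr <= nr && cc2 >= 1L && cc2 <= nc) {
        q <- (cc2 - 1L) * nr + rr
        if (processed[q]) nb <- c(nb, q)
      }
    }
    processed[p] <- TRUE
    if (!length(nb)) {           # new peak
      comp_peak[p] <- p
      next
    }
    roots <- unique(vapply(nb, find, 0L))
    # attach p to the component whose peak is highest (earliest rank)
    pk_rank <- rank_of[comp_peak[roots]]
    keep <- roots[which.min(pk_rank)]
    parent[p] <- keep
    for (rt in roots) {
      if (rt == keep) next
      # the lower peak is saturated here: saddle height = v[p]
      dead_peak <- comp_peak[rt]
      peak_prom[dead_peak] <- v[dead_peak] - v[p]
      parent[rt] <- keep
    }
  }
  # surviving component peaks: prominence above image background
  roots <- unique(vapply(which(comp_peak > 0L), find, 0L))
  for (rt in roots) {
    pk <- comp_peak[rt]
    if (is.na(peak_prom[pk])) peak_prom[pk] <- v[pk] - min(v)
  }
  pk_idx <- which(!is.na(peak_prom) & peak_prom > prominence_threshold)
  out <- data.frame(row = rows[pk_idx], col = cols[pk_idx],
                    value = v[pk_idx], prominence = peak_prom[pk_idx],
                    channel = rep(channel, length(pk_idx)))
  out[order(-out$value, out$row, out$col), , drop = FALSE]
}

#' Sub-pixel focus centring by orthogonal 1D Gaussian fits
#'
#' Around a seed pixel (from [detect_maxima()] or a manually supplied
#' position), the window's column sums give an x-profile and its row sums a
#' y-profile; each is fitted with [fit_gaussian_1d()] and the two fitted
#' centres combine into a sub-pixel centre in nm. The window is clipped at
#' image borders.
#'
#' @param image numeric matrix.
#' @param peak either a one-row data frame with `row`/`col` (as returned by
#'   [detect_maxima()]) or an integer pair `c(row, col)`.
#' @param pixel_size_nm pixel pitch, nm.
#' @param window_px odd window side length in pixels (default 15, about
#'   1 um at 65 nm/px).
#' @param channel optional channel label.
#' @return one-row data frame (a focus record): `x_nm`, `y_nm`, `amplitude`
#'   (estimated total photons), `sigma_x_nm`, `sigma_y_nm`, `offset`,
#'   `fit_rmse`, `valid`, `channel`. Non-converged fits or centres escaping
#'   the window give `valid = FALSE`.
#' @export
fit_centre <- function(image, peak, pixel_size_nm, window_px = 15L,
                       channel = NA_character_) {
  if (is.data.frame(peak)) {
    r0 <- peak$row[1]; c0 <- peak$col[1]
    if (!is.na(peak$channel[1]) && is.na(channel)) channel <- peak$channel[1]
  } else {
    r0 <- peak[1]; c0 <- peak[2]
  }
  window_px <- as.integer(window_px)
  if (window_px < 5L || window_px %% 2L == 0L)
    stop("window_px must be an odd integer >= 5")
  h <- (window_px - 1L) %/% 2L
  rr <- max(1L, r0 - h):min(nrow(image), r0 + h)
  cc <- max(1L, c0 - h):min(ncol(image), c0 + h)
  win <- image[rr, cc, drop = FALSE]

  fx <- fit_gaussian_1d(cc, colSums(win))
  fy <- fit_gaussian_1d(rr, rowSums(win))
  valid <- fx$converged && fy$converged &&
    fx$centre >= min(cc) - 0.5 && fx$centre <= max(cc) + 0.5 &&
    fy$centre >= min(rr) - 0.5 && fy$centre <= max(rr) + 0.5 &&
    is.finite(fx$sigma) && is.finite(fy$sigma) && fx$sigma > 0 && fy$sigma > 0
  # total-photon estimate: 1D profile amplitude times sqrt(2*pi)*sigma (px)
  amp <- if (valid) mean(c(fx$amplitude * sqrt(2 * pi) * fx$sigma,
                           fy$amplitude * sqrt(2 * pi) * fy$sigma)) else NA_real_
  data.frame(x_nm = (fx$centre - 1) * pixel_size_nm,
             y_nm = (fy$centre - 1) * pixel_size_nm,
             amplitude = amp,
             sigma_x_nm = fx$sigma * pixel_size_nm,
             sigma_y_nm = fy$sigma * pixel_size_nm,
             offset = mean(c(fx$offset, fy$offset)),
             fit_rmse = sqrt(mean(c(fx$rmse^2, fy$rmse^2))),
             valid = valid,
             channel = channel)
}

#' Detect and centre all foci of one channel in a scene image
#'
#' Convenience wrapper: [detect_maxima()] then [fit_centre()] per peak,
#' dropping invalid fits with a message.
#'
#' @inheritParams detect_maxima
#' @inheritParams fit_centre
#' @return data frame of focus records (possibly zero rows).
#' @export
locate_foci <- function(image, pixel_size_nm, prominence_threshold,
                        window_px = 15L, channel = NA_character_) {
  peaks <- detect_maxima(image, prominence_threshold, channel)
  if (!nrow(peaks)) {
    return(data.frame(x_nm = numeric(), y_nm = numeric(),
                      amplitude = numeric(), sigma_x_nm = numeric(),
                      sigma_y_nm = numeric(), offset = numeric(),
                      fit_rmse = numeric(), valid = logical(),
                      channel = character()))
  }
  foci <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i)
    fit_centre(image, peaks[i, ], pixel_size_nm, window_px, channel)))
  if (any(!foci$valid))
    message(sum(!foci$valid), " focus fit(s) did not converge; excluded")
  foci[foci$valid, , drop = FALSE]
}
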