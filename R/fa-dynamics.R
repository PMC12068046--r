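# --- focal-adhesion dynamics: tracking, phase rates, effect sizes ----------

# Per-frame adhesion segmentation: background-subtracted threshold then
# connected-component labelling.
segment_adhesion_frame <- function(img, threshold = NULL,
                                   min_area = 6L) {
  bg <- median(img)
  x <- img - bg
  # default detection threshold: well above the background noise floor
  # (6 robust SDs) and 5% of the frame maximum, whichever is larger
  thr <- threshold %||% max(6 * stats::mad(x), 0.05 * max(x), 1e-9)
  lab <- EBImage::bwlabel(x > thr)
  lmat <- EBImage::imageData(lab)
  storage.mode(lmat) <- "integer"
  nlab <- max(lmat)
  if (nlab == 0L)
    return(list(labels = lmat, meta = data.frame(label = integer(0))))
  areas <- label_areas(lmat, nlab)
  inten <- label_sums(x, lmat, nlab) / pmax(areas, 1L)
  cx <- label_sums(row(lmat), lmat, nlab) / pmax(areas, 1L)
  cy <- label_sums(col(lmat), lmat, nlab) / pmax(areas, 1L)
  mxx <- label_sums(row(lmat)^2, lmat, nlab) / pmax(areas, 1L) - cx^2
  myy <- label_sums(col(lmat)^2, lmat, nlab) / pmax(areas, 1L) - cy^2
  mxy <- label_sums(row(lmat) * col(lmat), lmat, nlab) /
    pmax(areas, 1L) - cx * cy
  dd <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- pmax((mxx + myy + dd) / 2, 1e-6)
  l2 <- pmax((mxx + myy - dd) / 2, 1e-6)
  meta <- data.frame(label = seq_len(nlab), area = areas,
                     intensity = inten, x = cx, y = cy,
                     axial_ratio = sqrt(l1 / l2))
  keep <- meta$area >= min_area
  meta <- meta[keep, , drop = FALSE]
  list(labels = lmat, meta = meta)
}

#' Segment and track focal adhesions in a time-lapse movie
#'
#' Adhesions are segmented per frame by background-subtracted automatic
#' thresholding and linked between consecutive frames by mask overlap
#' (largest overlap wins). Merges and splits terminate tracks; there is no
#' gap closing, so an adhesion vanishing for one frame starts a new track.
#'
#' @param movie list of frame matrices.
#' @param frame_interval_min minutes between frames (must be known).
#' @param threshold optional fixed segmentation threshold
#'   (background-subtracted units); default automatic per frame.
#' @param min_area minimum adhesion area (px).
#' @return list of \code{fa_track} objects (per-frame time, mean
#'   intensity, centroid, axial ratio, area).
#' @export
segment_track_adhesions <- function(movie, frame_interval_min,
                                    threshold = NULL, min_area = 6L) {
  if (missing(frame_interval_min) || is.null(frame_interval_min) ||
      !is.finite(frame_interval_min))
    stop("frame interval must be known")
  if (length(movie) < 5L) stop("need at least 5 frames")
  segs <- lapply(movie, segment_adhesion_frame, threshold = threshold,
                 min_area = min_area)
  open_tracks <- list()   # label -> accumulating data.frame
  done <- list()
  next_id <- 1L
  prev <- NULL
  for (f in seq_along(segs)) {
    cur <- segs[[f]]
    cur_rows <- cur$meta
    assign_from <- rep(NA_integer_, nrow(cur_rows))  # prev label linked
    if (!is.null(prev) && nrow(prev$meta) > 0L && nrow(cur_rows) > 0L) {
      both <- prev$labels > 0L & cur$labels > 0L
      if (any(both)) {
        ov <- table(prev = prev$labels[both], cur = cur$labels[both])
        ov_df <- as.data.frame(ov, stringsAsFactors = FALSE)
        ov_df <- ov_df[ov_df$Freq > 0, ]
        ov_df$prev <- as.integer(ov_df$prev)
        ov_df$cur <- as.integer(ov_df$cur)
        # keep only labels that survived the area filter
        ov_df <- ov_df[ov_df$prev %in% prev$meta$label &
                         ov_df$cur %in% cur_rows$label, , drop = FALSE]
        # greedy one-to-one assignment, largest overlap first; the
        # losing side of a merge/split terminates or starts a new track
        ov_df <- ov_df[order(-ov_df$Freq), , drop = FALSE]
        used_prev <- integer(0); used_cur <- integer(0)
        for (r in seq_len(nrow(ov_df))) {
          p <- ov_df$prev[r]; cc <- ov_df$cur[r]
          if (p %in% used_prev || cc %in% used_cur) next
          assign_from[match(cc, cur_rows$label)] <- p
          used_prev <- c(used_prev, p); used_cur <- c(used_cur, cc)
        }
      }
    }
    new_open <- list()
    for (i in seq_len(nrow(cur_rows))) {
      lab <- cur_rows$label[i]
      row <- data.frame(frame = f, t_min = (f - 1) * frame_interval_min,
                        intensity = cur_rows$intensity[i],
                        x = cur_rows$x[i], y = cur_rows$y[i],
                        axial_ratio = cur_rows$axial_ratio[i],
                        area = cur_rows$area[i])
      p <- assign_from[i]
      key <- as.character(lab)
      if (!is.na(p) && !is.null(open_tracks[[as.character(p)]])) {
        tr <- open_tracks[[as.character(p)]]
        tr$frames <- rbind(tr$frames, row)
        new_open[[key]] <- tr
      } else {
        new_open[[key]] <- list(track_id = next_id, frames = row)
        next_id <- next_id + 1L
      }
    }
    # tracks with no continuation terminate
    continued <- as.character(assign_from[!is.na(assign_from)])
    for (key in names(open_tracks)) {
      if (!(key %in% continued)) done <- c(done, list(open_tracks[[key]]))
    }
    open_tracks <- new_open
    prev <- cur
  }
  done <- c(done, unname(open_tracks))
  done <- done[order(vapply(done, function(t) t$track_id, integer(1)))]
  lapply(done, function(t)
    new_fa_track(t$frames, t$track_id, frame_interval_min))
}

#' Fit assembly/disassembly rates and phase lengths of one track
#'
#' The peak frame is the argmax of the median-smoothed intensity; the
#' assembly phase runs birth to peak and the disassembly phase peak to
#' death. Rates are least-squares slopes of ln(intensity) against time
#' (minutes) over the respective phases (disassembly reported positive);
#' the stability phase is the contiguous run of frames around the peak
#' with intensity at or above \code{stability_frac} of the peak. Phases
#' with fewer than 3 usable points get NA rates.
#'
#' @param track an \code{fa_track}.
#' @param stability_frac plateau definition (fraction of peak).
#' @param smooth_k median smoothing window (frames, odd).
#' @return The track with fields k_a, k_d (1/min), assembly_frames,
#'   disassembly_frames, stability_frames, r2_assembly, r2_disassembly.
#' @export
fit_phase_rates <- function(track, stability_frac = 0.9, smooth_k = 3L) {
  stopifnot(inherits(track, "fa_track"))
  fr <- track$frames
  if (nrow(fr) < 5L) stop("track shorter than 5 frames")
  sm <- if (nrow(fr) >= smooth_k) as.numeric(runmed(fr$intensity, smooth_k))
        else fr$intensity
  if (diff(range(fr$intensity)) < 1e-12) {
    # constant track: zero rates, stability spans the whole track
    half <- ceiling(nrow(fr) / 2)
    track$k_a <- 0; track$k_d <- 0
    track$r2_assembly <- NA_real_; track$r2_disassembly <- NA_real_
    track$assembly_frames <- half
    track$disassembly_frames <- nrow(fr) - half + 1L
    track$stability_frames <- nrow(fr)
    return(track)
  }
  peak <- which.max(sm)
  fit_slope <- function(idx) {
    ok <- idx[fr$intensity[idx] > 0]
    if (length(ok) < 3L) return(c(NA_real_, NA_real_))
    y <- log(fr$intensity[ok])
    f <- lm(y ~ fr$t_min[ok])
    ss_res <- sum(f$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    c(unname(coef(f)[2]), r2)
  }
  asm <- fit_slope(seq_len(peak))
  dis <- fit_slope(peak:nrow(fr))
  ipk <- sm[peak]
  stab <- which(sm >= stability_frac * ipk)
  # contiguous run containing the peak
  runs <- split(stab, cumsum(c(1, diff(stab) != 1)))
  stab_run <- runs[[which(vapply(runs, function(r) peak %in% r,
                                 logical(1)))]]
  track$k_a <- asm[1]
  track$k_d <- if (is.na(dis[1])) NA_real_ else -dis[1]
  track$r2_assembly <- asm[2]
  track$r2_disassembly <- dis[2]
  track$assembly_frames <- peak
  track$disassembly_frames <- nrow(fr) - peak + 1L
  track$stability_frames <- length(stab_run)
  track
}

#' Filter tracks by lifetime and shape
#'
#' Keeps tracks present for at least \code{min_frames} frames and with
#' mean axial ratio strictly below \code{max_axial_ratio} (the filters
#' applied to adhesion tracks before effect-size analysis). Idempotent.
#'
#' @param tracks list of \code{fa_track}.
#' @param min_frames minimum track length (frames).
#' @param max_axial_ratio exclusive upper bound on the mean axial ratio.
#' @return Filtered list.
#' @export
filter_tracks <- function(tracks, min_frames = 5L, max_axial_ratio = 3) {
  keep <- vapply(tracks, function(t) {
    nrow(t$frames) >= min_frames &&
      mean(t$frames$axial_ratio) < max_axial_ratio
  }, logical(1))
  tracks[keep]
}

#' Hedges' g (small-sample corrected standardized mean difference)
#'
#' g = (mean(b) - mean(a)) / s_pooled * J with
#' J = 1 - 3 / (4 (n_a + n_b) - 9).
#'
#' @param a,b numeric samples.
#' @return g (dimensionless).
#' @export
hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  j <- 1 - 3 / (4 * (na + nb) - 9)
  (mean(b) - mean(a)) / sqrt(sp2) * j
}

#' Effect-size magnitude label
#'
#' Bins |g|: below 0.2 none, 0.2-0.5 small (S), 0.5-0.8 medium (M),
#' 0.8-1.2 large (L), 1.2 and above very large (VL).
#'
#' @param g effect size.
#' @return One of "none", "S", "M", "L", "VL".
#' @export
effect_size_label <- function(g) {
  ag <- abs(g)
  if (ag < 0.2) "none" else if (ag < 0.5) "S" else if (ag < 0.8) "M"
  else if (ag < 1.2) "L" else "VL"
}

#' Hedges' g with BCa bootstrap confidence interval and Mann-Whitney test
#'
#' Estimation-statistics comparison of two groups: the point estimate is
#' \code{\link{hedges_g}} (b versus a); the 95 percent interval is a
#' bias-corrected and accelerated (BCa) bootstrap over within-group
#' resamples; a two-sided Mann-Whitney p-value is attached.
#'
#' @param a,b numeric samples (n >= 3 each).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return Object of class \code{effect_size_result}: g, ci_low, ci_high,
#'   label, n_a, n_b, mann_whitney_p, n_boot, seed.
#' @export
hedges_g_bootstrap <- function(a, b, n_boot = 5000L, seed = 1L,
                               conf = 0.95) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 3L, nb >= 3L)
  g <- hedges_g(a, b)
  boots <- with_seed(derive_seed(seed, "bca-boot"), {
    ia <- matrix(sample.int(na, na * n_boot, replace = TRUE), nrow = na)
    ib <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = nb)
    ma <- colMeans(matrix(a[ia], nrow = na))
    mb <- colMeans(matrix(b[ib], nrow = nb))
    va <- (colSums(matrix(a[ia]^2, nrow = na)) - na * ma^2) / (na - 1)
    vb <- (colSums(matrix(b[ib]^2, nrow = nb)) - nb * mb^2) / (nb - 1)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    j <- 1 - 3 / (4 * (na + nb) - 9)
    (mb - ma) / sqrt(sp2) * j
  })
  boots <- boots[is.finite(boots)]
  # bias correction
  z0 <- qnorm((sum(boots < g) + 0.5 * sum(boots == g)) / length(boots))
  z0 <- min(max(z0, -4), 4)
  # acceleration from jackknife over all observations
  jack <- c(vapply(seq_len(na), function(i) hedges_g(a[-i], b),
                   numeric(1)),
            vapply(seq_len(nb), function(i) hedges_g(a, b[-i]),
                   numeric(1)))
  d <- mean(jack) - jack
  accel <- sum(d^3) / (6 * max(sum(d^2), 1e-30)^1.5)
  alpha <- (1 - conf) / 2
  za <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + za) / (1 - accel * (z0 + za)))
  ci <- unname(quantile(boots, adj, names = FALSE))
  mw <- suppressWarnings(wilcox.test(b, a, alternative = "two.sided"))
  structure(list(g = g, ci_low = ci[1], ci_high = ci[2],
                 label = effect_size_label(g), n_a = na, n_b = nb,
                 mann_whitney_p = mw$p.value, n_boot = n_boot,
                 seed = seed),
            class = "effect_size_result")
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("Hedges' g = %.3f (%s), %d%% CI [%.3f, %.3f], n = %d/%d\n",
              x$g, x$label, 95, x$ci_low, x$ci_high, x$n_a, x$n_b))
  cat(sprintf("Two-sided Mann-Whitney p = %.3g\n", x$mann_whitney_p))
  invisible(x)
}
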