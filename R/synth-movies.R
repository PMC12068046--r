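# Exponential intensity profile of one adhesion: assembly at rate k_a up to
# the peak, then decay at k_d; times in minutes from birth.
fa_profile <- function(t, t_peak, k_a, k_d, i_peak = 1) {
  ifelse(t <= t_peak,
         i_peak * exp(-k_a * (t_peak - t)),
         i_peak * exp(-k_d * (t - t_peak)))
}

# Mean-preserving lognormal dispersion of a nominal rate across tracks.
per_track_rates <- function(k, n, cv) {
  if (cv <= 0 || k == 0) return(rep(k, n))
  sdlog <- sqrt(log(1 + cv^2))
  k * rlnorm(n, -sdlog^2 / 2, sdlog)
}

new_fa_track <- function(df, track_id, frame_interval_min) {
  structure(list(track_id = track_id, frames = df,
                 frame_interval_min = frame_interval_min),
            class = "fa_track")
}

#' Simulate focal-adhesion intensity traces with known rates
#'
#' Each track's mean intensity follows I(t) = I_peak exp(k_a (t - t_peak))
#' during assembly and I_peak exp(-k_d (t - t_peak)) during disassembly,
#' plus additive Gaussian noise. Ground truth stores the exact phase
#' boundaries and rates. Traces are the statistical layer behind
#' \code{\link{generate_fa_movie}}.
#'
#' @param n_tracks number of tracks.
#' @param k_a assembly rate (1/min), > 0.
#' @param k_d disassembly rate (1/min), >= 0.
#' @param frame_interval_min minutes between frames (1.5 or 3 in the
#'   imaging protocols emulated here).
#' @param assembly_frames,disassembly_frames range (min, max) of phase
#'   lengths in frames, drawn per track.
#' @param noise_sd additive intensity noise SD (peak intensity is 1, so
#'   0.1 corresponds to SNR 10 at the peak).
#' @param rate_cv coefficient of variation of per-track rates (lognormal,
#'   mean-preserving); 0 gives every track the nominal rates.
#' @param seed integer seed.
#' @return list with \code{tracks} (list of \code{fa_track}) and
#'   \code{truth} (track_id, per-track k_a, k_d, birth/peak/death frame).
#' @export
generate_fa_traces <- function(n_tracks = 50L, k_a = 0.1, k_d = 0.05,
                               frame_interval_min = 1.5,
                               assembly_frames = c(10L, 16L),
                               disassembly_frames = c(10L, 16L),
                               noise_sd = 0.1, rate_cv = 0, seed = 1L) {
  stopifnot(k_a > 0, k_d >= 0, rate_cv >= 0)
  with_seed(seed, {
    kas <- per_track_rates(k_a, n_tracks, rate_cv)
    kds <- per_track_rates(k_d, n_tracks, rate_cv)
    tracks <- vector("list", n_tracks)
    truth <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      na <- sample(assembly_frames[1]:assembly_frames[2], 1L)
      nd <- sample(disassembly_frames[1]:disassembly_frames[2], 1L)
      frames <- 0:(na + nd)
      t_min <- frames * frame_interval_min
      t_peak <- na * frame_interval_min
      inten <- fa_profile(t_min, t_peak, kas[i], kds[i])
      if (noise_sd > 0) inten <- inten + rnorm(length(inten), 0, noise_sd)
      df <- data.frame(frame = frames, t_min = t_min,
                       intensity = inten, x = NA_real_, y = NA_real_,
                       axial_ratio = 2, area = 24)
      tracks[[i]] <- new_fa_track(df, i, frame_interval_min)
      truth[[i]] <- data.frame(track_id = i, k_a = kas[i], k_d = kds[i],
                               birth_frame = 0L, peak_frame = na,
                               death_frame = na + nd)
    }
    list(tracks = tracks, truth = do.call(rbind, truth))
  })
}

#' Render a synthetic focal-adhesion movie
#'
#' Places non-interacting elliptical adhesions on a grid; each follows the
#' exponential assembly/decay profile of \code{\link{generate_fa_traces}}.
#' Tracks are born and die within the movie; pixel noise is additive
#' Gaussian.
#'
#' @inheritParams generate_fa_traces
#' @param n_frames movie length in frames.
#' @param noise_sd additive pixel noise SD.
#' @param seed integer seed.
#' @return list with \code{movie} (list of frame matrices), \code{truth}
#'   (per-track rates and phase boundaries, centre coordinates) and
#'   \code{frame_interval_min}.
#' @export
generate_fa_movie <- function(n_tracks = 25L, k_a = 0.1, k_d = 0.05,
                              frame_interval_min = 1.5, n_frames = 40L,
                              noise_sd = 0.01, rate_cv = 0, seed = 1L) {
  stopifnot(k_a > 0, k_d >= 0, rate_cv >= 0)
  with_seed(seed, {
    kas <- per_track_rates(k_a, n_tracks, rate_cv)
    kds <- per_track_rates(k_d, n_tracks, rate_cv)
    per_side <- ceiling(sqrt(n_tracks))
    size <- per_side * 24L + 24L
    centres <- expand.grid(x = seq(20, size - 20, length.out = per_side),
                           y = seq(20, size - 20, length.out = per_side))
    centres <- centres[seq_len(n_tracks), ]
    na <- sample(8:14, n_tracks, replace = TRUE)
    nd <- sample(8:14, n_tracks, replace = TRUE)
    birth <- vapply(seq_len(n_tracks), function(i)
      sample.int(max(n_frames - na[i] - nd[i], 1L), 1L), integer(1))
    orient <- runif(n_tracks, 0, pi)
    movie <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      img <- matrix(0.005, size, size)
      for (i in seq_len(n_tracks)) {
        if (f < birth[i] || f > birth[i] + na[i] + nd[i]) next
        t <- (f - birth[i]) * frame_interval_min
        inten <- fa_profile(t, na[i] * frame_interval_min, kas[i], kds[i])
        xs <- max(1, floor(centres$x[i] - 8)):min(size, ceiling(centres$x[i] + 8))
        ys <- max(1, floor(centres$y[i] - 8)):min(size, ceiling(centres$y[i] + 8))
        dx <- outer(xs - centres$x[i], rep(1, length(ys)))
        dy <- outer(rep(1, length(xs)), ys - centres$y[i])
        u <- dx * cos(orient[i]) + dy * sin(orient[i])
        v <- -dx * sin(orient[i]) + dy * cos(orient[i])
        m <- (u / 5)^2 + (v / 2.5)^2 <= 1
        sub <- img[xs, ys]; sub[m] <- pmax(sub[m], inten); img[xs, ys] <- sub
      }
      if (noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow = size)
      movie[[f]] <- pmax(img, 0)
    }
    truth <- data.frame(track_id = seq_len(n_tracks), x = centres$x,
                        y = centres$y, k_a = kas, k_d = kds,
                        birth_frame = birth, peak_frame = birth + na,
                        death_frame = birth + na + nd)
    list(movie = movie, truth = truth,
         frame_interval_min = frame_interval_min)
  })
}

#' Simulate a 3D invasion z-stack with known per-plane counts
#'
#' Renders nuclei plus GFP blobs at each plane to match the requested
#' counts; a configurable fraction of additional low-intensity decoy blobs
#' exercises the dual intensity filter of the counting stage. Plane 1 is
#' the plate bottom (depth 0).
#'
#' @param counts_per_plane non-negative integer vector, one per plane
#'   (plane 1 = bottom, subsequent planes inside the gel).
#' @param decoy_fraction decoy blobs added per plane, as a fraction of the
#'   requested count.
#' @param decoy_intensity decoy intensity relative to true cells.
#' @param plane_spacing_um spacing between planes (micrometres).
#' @param image_size plane side length (px).
#' @param seed integer seed.
#' @return list with \code{nuclear}, \code{gfp} (lists of plane matrices),
#'   \code{depth_um}, \code{truth} (requested counts) and
#'   \code{n_decoys}.
#' @export
generate_invasion_stack <- function(counts_per_plane, decoy_fraction = 0,
                                    decoy_intensity = 0.1,
                                    plane_spacing_um = 30,
                                    image_size = 256L, seed = 1L) {
  stopifnot(all(counts_per_plane >= 0))
  with_seed(seed, {
    n_planes <- length(counts_per_plane)
    nuclear <- gfp <- vector("list", n_planes)
    n_decoys <- integer(n_planes)
    for (p in seq_len(n_planes)) {
      nimg <- matrix(0.01, image_size, image_size)
      gimg <- matrix(0.01, image_size, image_size)
      n_true <- counts_per_plane[p]
      n_dec <- as.integer(round(n_true * decoy_fraction))
      n_decoys[p] <- n_dec
      total <- n_true + n_dec
      if (total > 0) {
        per_side <- ceiling(sqrt(total))
        gpos <- expand.grid(
          x = seq(12, image_size - 12, length.out = max(per_side, 2)),
          y = seq(12, image_size - 12, length.out = max(per_side, 2)))
        gpos <- gpos[sample.int(nrow(gpos), total), , drop = FALSE]
        inten <- c(rep(1, n_true), rep(decoy_intensity, n_dec))
        for (i in seq_len(total)) {
          xs <- max(1, floor(gpos$x[i] - 7)):min(image_size, ceiling(gpos$x[i] + 7))
          ys <- max(1, floor(gpos$y[i] - 7)):min(image_size, ceiling(gpos$y[i] + 7))
          dx <- outer(xs - gpos$x[i], rep(1, length(ys)))
          dy <- outer(rep(1, length(xs)), ys - gpos$y[i])
          rr <- sqrt(dx^2 + dy^2)
          nm <- rr <= 4; gm <- rr <= 6
          sub <- nimg[xs, ys]; sub[nm] <- pmax(sub[nm], 0.6 * inten[i])
          nimg[xs, ys] <- sub
          sub <- gimg[xs, ys]; sub[gm] <- pmax(sub[gm], 0.5 * inten[i])
          gimg[xs, ys] <- sub
        }
      }
      nuclear[[p]] <- EBImage::gblur(nimg, 1) +
        matrix(rnorm(length(nimg), 0, 0.004), image_size)
      gfp[[p]] <- EBImage::gblur(gimg, 1) +
        matrix(rnorm(length(gimg), 0, 0.004), image_size)
    }
    list(nuclear = nuclear, gfp = gfp,
         depth_um = (seq_len(n_planes) - 1) * plane_spacing_um,
         truth = as.integer(counts_per_plane), n_decoys = n_decoys)
  })
}
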