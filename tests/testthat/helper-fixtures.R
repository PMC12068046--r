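# Shared fixtures built in code (no binary files).

# A field with one synthetic cell: disk cell of radius r_cell, concentric
# disk nucleus of radius r_nuc, optional programmed log10 nuclear:ring
# marker ratio. Returns images plus a segmented/regioned cell_field.
make_disk_cell <- function(r_cell = 30, r_nuc = 10, size = 101L,
                           ratio = NULL, bg = 0.02, i_ring = 0.2,
                           ring_width = 4L, band_width = 3L) {
  ctr <- (size + 1) / 2
  dx <- outer(seq_len(size) - ctr, rep(1, size))
  dy <- outer(rep(1, size), seq_len(size) - ctr)
  rr <- sqrt(dx^2 + dy^2)
  cellm <- rr <= r_cell
  nucm <- rr <= r_nuc
  dna <- matrix(bg, size, size); dna[nucm] <- 0.6
  tub <- matrix(bg, size, size); tub[cellm] <- 0.35
  marker <- matrix(bg, size, size)
  if (!is.null(ratio)) {
    marker[cellm] <- bg + i_ring
    marker[nucm] <- bg + i_ring * 10^ratio
  }
  field <- segment_cells(dna, tub)
  field <- define_regions(field, ring_width, band_width)
  list(dna = dna, tubulin = tub, marker = marker, field = field,
       cell_mask = cellm, nucleus_mask = nucm)
}

# A cell_field built directly from given label matrices (bypasses
# segmentation) for analytic region tests.
make_field_from_masks <- function(nuclei, cells) {
  storage.mode(nuclei) <- storage.mode(cells) <- "integer"
  nlab <- max(nuclei)
  meta <- data.frame(cell_id = seq_len(nlab),
                     x = rep(NA_real_, nlab), y = rep(NA_real_, nlab),
                     is_border = rep(FALSE, nlab))
  structure(list(nuclei = nuclei, cells = cells, meta = meta,
                 dim = dim(nuclei)),
            class = "cell_field")
}

disk_mask <- function(size, cx, cy, r) {
  dx <- outer(seq_len(size) - cx, rep(1, size))
  dy <- outer(rep(1, size), seq_len(size) - cy)
  sqrt(dx^2 + dy^2) <= r
}

ellipse_mask <- function(size, cx, cy, a, b) {
  dx <- outer(seq_len(size) - cx, rep(1, size))
  dy <- outer(rep(1, size), seq_len(size) - cy)
  (dx / a)^2 + (dy / b)^2 <= 1
}

# Linearly separable five-class feature set mimicking archetype geometry
# summaries (for classifier tests without rendering).
make_archetype_features <- function(n_per_class = 60L, seed = 1L,
                                    noise = 0.05) {
  centres <- rbind(
    spindly = c(area = 0.4, axial = 3.5, solidity = 0.95, prot = 0),
    large_round = c(1.0, 1.05, 0.98, 0),
    triangular = c(0.5, 1.0, 0.80, 3),
    fan = c(0.6, 1.3, 0.90, 1),
    small_round = c(0.15, 1.0, 0.98, 0))
  set.seed(seed)
  cls <- rep(rownames(centres), each = n_per_class)
  x <- centres[cls, ] + matrix(rnorm(length(cls) * 4, 0, noise),
                               ncol = 4)
  colnames(x) <- c("area", "axial_ratio", "solidity", "protrusions")
  list(features = as.data.frame(x), labels = cls)
}

# Brute-force agglomerative clustering oracle: distance 1 - uncentered
# PCC, average (or complete) linkage, merging the closest pair each step.
# Returns the partition at a similarity threshold (root-merge rule).
brute_force_phenoclusters <- function(m, threshold,
                                      linkage = "average") {
  n <- nrow(m)
  norms <- sqrt(rowSums(m^2))
  s <- tcrossprod(m / norms)
  d0 <- 1 - s
  clusters <- as.list(seq_len(n))
  heights <- list()
  dist_fun <- function(a, b) {
    vals <- d0[a, b, drop = FALSE]
    if (linkage == "average") mean(vals) else max(vals)
  }
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dd <- dist_fun(clusters[[i]], clusters[[j]])
      if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    heights[[length(heights) + 1L]] <- list(members = merged,
                                            height = bestd)
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  # cut: union merges with similarity (1 - height) > threshold
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (h in heights) {
    if (1 - h$height > threshold) {
      r <- find(h$members[1])
      for (mm in h$members[-1]) parent[find(mm)] <- r
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (valid without ties).
mann_whitney_enum <- function(a, b) {
  n <- length(a); m <- length(b)
  pool <- c(a, b)
  rk <- rank(pool)
  stat <- function(ii) sum(rk[ii]) - length(ii) * (length(ii) + 1) / 2
  u_obs <- stat(seq_len(n))
  mu <- n * m / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2L, function(ii)
    sum(rk[ii]) - n * (n + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Same partition up to label renaming?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
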