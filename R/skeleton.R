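# Binary-image utilities and topology-preserving thinning.
#
# The measurement chain reduces the cortical ring mask to a one-pixel-wide
# medial-axis skeleton whose loop length is the centerline length CL. The
# thinning operator is Guo-Hall two-subiteration thinning followed by a
# unit-width cleanup pass; it preserves 8-connectivity of the foreground and
# the ring's interior hole, and the skeleton is always a subset of the mask.

# result[i, j] = m[i + dr, j + dc], zero-padded at the borders
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

neighbor_stack <- function(m) {
  # p2..p9 clockwise from north
  list(p2 = shift_mat(m, -1L, 0L), p3 = shift_mat(m, -1L, 1L),
       p4 = shift_mat(m, 0L, 1L),  p5 = shift_mat(m, 1L, 1L),
       p6 = shift_mat(m, 1L, 0L),  p7 = shift_mat(m, 1L, -1L),
       p8 = shift_mat(m, 0L, -1L), p9 = shift_mat(m, -1L, -1L))
}

# Label 8-connected (or 4-connected) foreground components by iterative
# frontier dilation; returns an integer matrix of labels (0 = background).
label_components <- function(m, connectivity = 8L) {
  offs <- if (connectivity == 8L)
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  else
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  lab <- matrix(0L, nrow(m), ncol(m))
  fg <- m > 0
  k <- 0L
  repeat {
    seed <- which(fg & lab == 0L)
    if (length(seed) == 0L) break
    k <- k + 1L
    comp <- matrix(FALSE, nrow(m), ncol(m))
    comp[seed[1]] <- TRUE
    repeat {
      grown <- comp
      for (o in offs) grown <- grown | shift_mat(comp + 0L, o[1], o[2]) > 0
      grown <- grown & fg
      if (identical(grown, comp)) break
      comp <- grown
    }
    lab[comp] <- k
  }
  lab
}

# Number of interior holes: 4-connected background components not touching
# the grid border (4-connectivity for background pairs with 8-connected
# foreground).
count_holes <- function(m) {
  lab <- label_components(1L - (m > 0), connectivity = 4L)
  if (max(lab) == 0L) return(0L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  length(setdiff(seq_len(max(lab)), c(0L, border)))
}

# Chamfer (1, sqrt 2) distance-to-background transform by min-plus
# relaxation; converges in about max-thickness iterations.
distance_transform <- function(m) {
  d <- matrix(0, nrow(m), ncol(m))
  d[m > 0] <- Inf
  offs <- list(c(-1L, 0L, 1), c(1L, 0L, 1), c(0L, -1L, 1), c(0L, 1L, 1),
               c(-1L, -1L, sqrt(2)), c(-1L, 1L, sqrt(2)),
               c(1L, -1L, sqrt(2)), c(1L, 1L, sqrt(2)))
  shift_num <- function(x, dr, dc) {
    nr <- nrow(x); nc <- ncol(x)
    out <- matrix(0, nr, nc)     # outside the grid counts as background
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs - dr, cs - dc] <- x[rs, cs]
    out
  }
  repeat {
    d_new <- d
    for (o in offs) d_new <- pmin(d_new, shift_num(d, o[1], o[2]) + o[3])
    improved <- any(d_new < d - 1e-9)
    d <- d_new
    if (!improved) break
  }
  d
}

# Guo-Hall two-subiteration thinning to a unit-width, topology-preserving
# skeleton.
guo_hall_thin <- function(m) {
  m <- matrix(as.integer(m > 0), nrow(m), ncol(m))
  repeat {
    changed <- FALSE
    for (sub in 0:1) {
      p <- neighbor_stack(m)
      C <- (1L - p$p2) * (p$p3 | p$p4) + (1L - p$p4) * (p$p5 | p$p6) +
           (1L - p$p6) * (p$p7 | p$p8) + (1L - p$p8) * (p$p9 | p$p2)
      N1 <- (p$p9 | p$p2) + (p$p3 | p$p4) + (p$p5 | p$p6) + (p$p7 | p$p8)
      N2 <- (p$p2 | p$p3) + (p$p4 | p$p5) + (p$p6 | p$p7) + (p$p8 | p$p9)
      N <- pmin(N1, N2)
      m3 <- if (sub == 0) ((p$p6 | p$p7 | (1L - p$p9)) & p$p8)
            else ((p$p2 | p$p3 | (1L - p$p5)) & p$p4)
      del <- m == 1L & C == 1L & N >= 2L & N <= 3L & m3 == 0L
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  strip_thick_pixels(m)
}

# Medial band of a ring mask: pixels equidistant (within one chamfer step)
# from the interior hole and the exterior background, per separate distance
# transforms to each. Thinning erodes at equal speed from both sides of this
# band by construction, so the skeleton lands on the mid-wall centerline even
# when the hole is tiny relative to the outer boundary (where plain
# homotopic thinning, which can only erode where a pixel's neighborhood is
# already sparse, drifts the skeleton toward the hole). Returns NULL when the
# band does not itself form a ring.
equidistant_band <- function(m, tol = 1.0) {
  bg_lab <- label_components(1L - (m > 0), connectivity = 4L)
  if (max(bg_lab) == 0L) return(NULL)
  border <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                     bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
  interior <- setdiff(seq_len(max(bg_lab)), c(0L, border))
  if (length(interior) == 0L) return(NULL)
  inner_bg <- matrix(as.integer(bg_lab %in% interior), nrow(m), ncol(m))
  outer_bg <- matrix(as.integer(bg_lab > 0L & !(bg_lab %in% interior)),
                     nrow(m), ncol(m))
  d_in <- distance_transform(1L - inner_bg)
  d_out <- distance_transform(1L - outer_bg)
  band <- matrix(as.integer(m > 0 & abs(d_in - d_out) <= tol + 1e-9),
                 nrow(m), ncol(m))
  # widen until the band is a connected ring (thin walls can leave gaps)
  for (extra in c(0, 0.5, 1)) {
    if (extra > 0)
      band <- matrix(as.integer(m > 0 & abs(d_in - d_out) <= tol + extra),
                     nrow(m), ncol(m))
    lab <- label_components(band)
    if (max(lab) == 1L && count_holes(band) >= 1L) return(band)
  }
  NULL
}

# Remove leftover pixels that still sit in a 2x2 foreground block, deleting
# only pixels whose removal keeps the local curve connected (crossing number
# A == 1) and that are not endpoints. Deterministic scan order.
strip_thick_pixels <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ring_off <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                   c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  neigh_seq <- function(i, j) {
    vapply(ring_off, function(o) {
      r <- i + o[1]; c <- j + o[2]
      if (r < 1 || r > nr || c < 1 || c > nc) 0L else m[r, c]
    }, integer(1))
  }
  repeat {
    blk <- m & shift_mat(m, 0L, 1L) & shift_mat(m, 1L, 0L) & shift_mat(m, 1L, 1L)
    idx <- which(blk == 1L)
    if (length(idx) == 0L) break
    progress <- FALSE
    cand <- which(m == 1L & (blk |
      shift_mat(blk + 0L, 0L, -1L) | shift_mat(blk + 0L, -1L, 0L) |
      shift_mat(blk + 0L, -1L, -1L)) > 0)
    for (ij in cand) {
      i <- ((ij - 1L) %% nr) + 1L
      j <- ((ij - 1L) %/% nr) + 1L
      # still in a 2x2 block?
      in_blk <- FALSE
      for (di in c(-1L, 0L)) for (dj in c(-1L, 0L)) {
        r <- i + di; c <- j + dj
        if (r >= 1 && c >= 1 && r + 1 <= nr && c + 1 <= nc &&
            m[r, c] && m[r + 1, c] && m[r, c + 1] && m[r + 1, c + 1])
          in_blk <- TRUE
      }
      if (!in_blk) next
      s <- neigh_seq(i, j)
      b <- sum(s)
      a <- sum(s == 0L & c(s[-1], s[1]) == 1L)   # 0 -> 1 transitions
      if (a == 1L && b >= 2L && b <= 6L) {
        m[i, j] <- 0L
        progress <- TRUE
      }
    }
    if (!progress) break
  }
  m
}

#' Skeletonize a cortical ring mask
#'
#' Reduces a binary bone mask to a one-pixel-wide, topology-preserving
#' skeleton of its medial axis. Stray components smaller than `min_size`
#' pixels (segmentation debris) are removed first. The mask is expected to be
#' a single 8-connected ring (one interior hole); a filled mask without a
#' hole triggers a warning and the downstream open-ring fallback, while
#' multiple components after cleanup are an error.
#'
#' @param mask a [roi_mask()] (or binary matrix) of the bone region.
#' @param min_size minimum component size in pixels kept before thinning.
#' @return integer 0/1 matrix of the skeleton, with attributes
#'   `pixel_spacing` (mm) and `n_holes`.
#' @export
skeletonize_mask <- function(mask, min_size = 5L) {
  if (inherits(mask, "roi_mask")) {
    sp <- mask$pixel_spacing
    m <- mask$values
  } else {
    sp <- attr(mask, "pixel_spacing")
    m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  }
  if (sum(m) == 0L) stop("empty mask: nothing to skeletonize", call. = FALSE)
  lab <- label_components(m)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L)
    stop("mask has no component of at least ", min_size, " pixels",
         call. = FALSE)
  if (length(keep) > 1L)
    stop("mask has ", length(keep), " components after small-object cleanup; ",
         "expected a single ring", call. = FALSE)
  m <- matrix(as.integer(lab == keep), nrow(m), ncol(m))
  holes <- count_holes(m)
  if (holes == 0L)
    warning("bone mask has no interior hole (filled ring); ",
            "centerline extraction will use the open-ring fallback",
            call. = FALSE)
  band <- if (holes >= 1L) equidistant_band(m)
  skel <- guo_hall_thin(if (is.null(band)) m else band)
  structure(skel, pixel_spacing = sp, n_holes = holes)
}
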