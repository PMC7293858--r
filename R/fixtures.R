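# Synthetic polygonal curves with known topology.  All generators use a
# nominal 3.8 Angstrom point spacing so the curves pass the chain-break
# filter and behave like C-alpha traces; none attempts realistic protein
# secondary-structure statistics.

# evaluate expr under set.seed(seed) without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# points on a circular arc: center + R*(cos(t) u + sin(t) v), t over
# [from, to] with n_pts points
arc_points <- function(n_pts, radius, center, u, v, from, to) {
  t <- seq(from, to, length.out = n_pts)
  outer(cos(t), radius * u) + outer(sin(t), radius * v) +
    matrix(center, n_pts, 3L, byrow = TRUE)
}

# resample a waypoint polyline so consecutive spacing is <= max_step;
# waypoints are hit exactly, duplicated junctions collapsed
resample_polyline <- function(waypoints, max_step = 3.5) {
  out <- waypoints[1L, , drop = FALSE]
  for (k in seq_len(nrow(waypoints) - 1L)) {
    a <- waypoints[k, ]; b <- waypoints[k + 1L, ]
    n <- max(1L, ceiling(sqrt(sum((b - a)^2)) / max_step))
    s <- seq_len(n) / n
    out <- rbind(out, outer(1 - s, a) + outer(s, b))
  }
  out
}

#' Planar zigzag trace (zero writhe everywhere)
#'
#' All points lie in the z = 0 plane, so every segment pair is coplanar
#' and every writhe-table entry is exactly 0.
#'
#' @param n_points number of points.
#' @param step point spacing (Angstrom).
#' @param angle half-opening of the zigzag (radians).
#' @return A [ca_trace()].
#' @export
make_planar_zigzag <- function(n_points = 40L, step = 3.8, angle = pi / 3) {
  k <- seq_len(n_points) - 1L
  dir <- ifelse(k %% 2L == 0L, angle, -angle)
  dx <- c(0, step * cos(dir[-n_points]))
  dy <- c(0, step * sin(dir[-n_points]))
  pts <- cbind(cumsum(dx), cumsum(dy), 0)
  ca_trace(pts, structure_id = "planar_zigzag")
}

#' Helical trace
#'
#' Points on a circular helix; the writhe of the full chain grows with the
#' number of turns.  Defaults approximate alpha-helical geometry (radius
#' 2.3 A, rise 1.5 A, 100 degrees per residue, ~3.8 A spacing).
#'
#' @param n_points number of points.
#' @param radius helix radius (Angstrom).
#' @param rise rise per point (Angstrom).
#' @param turn_angle rotation per point (radians).
#' @return A [ca_trace()].
#' @export
make_helix <- function(n_points = 40L, radius = 2.3, rise = 1.5,
                       turn_angle = 100 * pi / 180) {
  k <- seq_len(n_points) - 1L
  pts <- cbind(radius * cos(k * turn_angle),
               radius * sin(k * turn_angle),
               k * rise)
  ca_trace(pts, structure_id = "helix")
}

#' Seeded protein-like random-walk trace
#'
#' A self-avoiding random walk with fixed step length emulating a C-alpha
#' trace: consecutive virtual bonds keep their angle in the range
#' observed for protein backbones (the cosine of the direction change is
#' drawn uniformly from `cos_angle_range`), and every new point must stay
#' at least `min_separation` from all non-bonded predecessors (excluded
#' volume).  Steps violating the constraint are redrawn; in the rare
#' dead-end the walk restarts.  Deterministic given the seed; the
#' caller's RNG state is left untouched.
#'
#' @param n_points number of points.
#' @param step step length (Angstrom).
#' @param seed integer seed.
#' @param min_separation excluded-volume distance to non-consecutive
#'   points (Angstrom).
#' @param cos_angle_range range for the cosine of the angle between
#'   consecutive step directions; the default spans C-alpha virtual bond
#'   angles of roughly 75-150 degrees.
#' @return A [ca_trace()].
#' @export
make_random_walk <- function(n_points = 64L, step = 3.8, seed = 1L,
                             min_separation = 4.0,
                             cos_angle_range = c(-0.26, 0.866)) {
  pts <- with_seed(seed, {
    repeat {
      p <- matrix(NA_real_, n_points, 3L)
      p[1L, ] <- c(0, 0, 0)
      d <- rnorm(3L); d <- d / sqrt(sum(d^2))
      p[2L, ] <- p[1L, ] + step * d
      stuck <- FALSE
      for (i in 3:n_points) {
        placed <- FALSE
        for (try in 1:100) {
          # new direction at a constrained angle from the previous one
          ca <- runif(1L, cos_angle_range[1L], cos_angle_range[2L])
          sa <- sqrt(1 - ca^2)
          phi <- runif(1L, 0, 2 * pi)
          ref <- if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
          e1 <- ref - sum(ref * d) * d; e1 <- e1 / sqrt(sum(e1^2))
          e2 <- c(d[2L] * e1[3L] - d[3L] * e1[2L],
                  d[3L] * e1[1L] - d[1L] * e1[3L],
                  d[1L] * e1[2L] - d[2L] * e1[1L])
          cand_d <- ca * d + sa * (cos(phi) * e1 + sin(phi) * e2)
          cand <- p[i - 1L, ] + step * cand_d
          prev <- p[seq_len(i - 2L), , drop = FALSE]
          if (min(sqrt(rowSums((prev - matrix(cand, nrow(prev), 3L,
                                              byrow = TRUE))^2))) >=
              min_separation) {
            p[i, ] <- cand; d <- cand_d; placed <- TRUE
            break
          }
        }
        if (!placed) { stuck <- TRUE; break }
      }
      if (!stuck) break
    }
    p
  })
  ca_trace(pts, structure_id = sprintf("random_walk_%d", seed))
}

#' Planar ring with straight tails
#'
#' A near-closed planar polygonal ring (termini `closure` Angstrom apart)
#' padded on both sides by straight tails that diverge in-plane, so that
#' the ring interval satisfies the closed-loop criteria while the tails
#' stay far apart.  The ring's segment interval is attached as attribute
#' `"ring_interval"`.
#'
#' @param ring_segments number of segments in the ring.
#' @param tail_points points per tail.
#' @param step nominal spacing (Angstrom).
#' @param closure distance between the ring termini (Angstrom).
#' @return A [ca_trace()].
#' @export
make_ring_with_tails <- function(ring_segments = 20L, tail_points = 8L,
                                 step = 3.8, closure = 5) {
  R <- ring_segments * step / (2 * pi)
  gap <- 2 * asin(pmin(1, closure / (2 * R)))
  ring <- arc_points(ring_segments + 1L, R, c(0, 0, 0),
                     c(1, 0, 0), c(0, 1, 0), gap / 2, 2 * pi - gap / 2)
  # tails leave the termini at 45 degrees from radial, diverging
  t_in <- ring[1L, ] / sqrt(sum(ring[1L, ]^2))
  t_out <- ring[nrow(ring), ] / sqrt(sum(ring[nrow(ring), ]^2))
  rot2 <- function(v, a) c(cos(a) * v[1L] - sin(a) * v[2L],
                           sin(a) * v[1L] + cos(a) * v[2L], 0)
  d_in <- rot2(t_in, pi / 4)
  d_out <- rot2(t_out, -pi / 4)
  k <- seq_len(tail_points)
  tail_in <- ring[rep(1L, tail_points), ] + outer(rev(k), step * d_in)
  tail_out <- ring[rep(nrow(ring), tail_points), ] + outer(k, step * d_out)
  pts <- rbind(tail_in, ring, tail_out)
  tr <- ca_trace(pts, structure_id = "ring_with_tails")
  attr(tr, "ring_interval") <- c(tail_points, tail_points + ring_segments - 1L)
  tr
}

#' Single-chain polygonal Hopf link
#'
#' One connected trace modelling a 1-link: a near-closed ring, a short
#' linker, and a second near-closed ring threaded once through the first,
#' padded with straight entry/exit tails.  For the linked default the
#' mutual writhe of the two ring sub-chains is close to the linking
#' number of the completed rings, +1 for `handedness = 1`.  Setting
#' `separation` large gives the unlinked variant.  The two ring segment
#' intervals are attached as attributes `"ring1_interval"` and
#' `"ring2_interval"`.
#'
#' @param ring_segments segments per ring (>= 12).
#' @param tail_points points per terminal tail.
#' @param step nominal spacing (Angstrom).
#' @param closure ring terminus gap (Angstrom); must allow loop detection
#'   (< 7 A).
#' @param handedness +1 or -1; -1 mirrors the curve, flipping the sign of
#'   every writhe quantity.
#' @param separation distance of the second ring's centre from the
#'   first's (Angstrom); the default `NULL` places it at one radius, the
#'   interlinked Hopf geometry.  Use e.g. 100 for distant unlinked rings.
#' @return A [ca_trace()].
#' @export
make_hopf_link_chain <- function(ring_segments = 24L, tail_points = 6L,
                                 step = 3.8, closure = 2.0,
                                 handedness = 1, separation = NULL) {
  if (ring_segments < 12L) stop("need >= 12 segments per ring")
  if (!handedness %in% c(-1, 1)) stop("'handedness' must be +1 or -1")
  R <- ring_segments * step / (2 * pi)
  if (is.null(separation)) separation <- R
  gap <- 2 * asin(pmin(1, closure / (2 * R)))

  # ring 1 in the xy-plane centred at the origin, gap facing +x
  ring1 <- arc_points(ring_segments + 1L, R, c(0, 0, 0),
                      c(1, 0, 0), c(0, 1, 0), gap / 2, 2 * pi - gap / 2)
  # ring 2 in the xz-plane centred on the x-axis; at separation = R it
  # threads through ring 1's hole (crossings of z = 0 at x = 0 and x = 2R);
  # traversed so that the completed rings link with number +1
  c2 <- c(separation, 0, 0)
  ring2 <- arc_points(ring_segments + 1L, R, c2,
                      c(1, 0, 0), c(0, 0, -1), gap / 2, 2 * pi - gap / 2)

  # entry tail leaves ring 1 perpendicular to both ring planes so it
  # neither threads ring 2 nor crosses ring 1's disc
  k <- seq_len(tail_points)
  tail_in <- ring1[rep(1L, tail_points), ] + outer(rev(k), step * c(0, 0, 1))
  tail_out <- ring2[rep(nrow(ring2), tail_points), ] +
    outer(k, step * c(1, 0, 0))

  linker <- resample_polyline(rbind(ring1[nrow(ring1), ], ring2[1L, ]))
  linker <- linker[-c(1L, nrow(linker)), , drop = FALSE]

  pts <- rbind(tail_in, ring1, linker, ring2, tail_out)
  if (handedness < 0) pts[, 3L] <- -pts[, 3L]
  tr <- ca_trace(pts, structure_id = "hopf_link_chain")
  r1_first <- tail_points
  r2_first <- tail_points + ring_segments + 1L + nrow(linker)
  attr(tr, "ring1_interval") <- c(r1_first, r1_first + ring_segments - 1L)
  attr(tr, "ring2_interval") <- c(r2_first, r2_first + ring_segments - 1L)
  tr
}

#' Two closed polygonal rings (Hopf link or unlinked)
#'
#' The closed-curve counterpart of [make_hopf_link_chain()]: two closed
#' polygons whose linking number is exactly `handedness` when
#' interlinked (`separation = NULL`) and 0 when far apart.  Used to pin
#' the normalisation of the Gauss integral to integer linking numbers.
#'
#' @inheritParams make_hopf_link_chain
#' @return List of two closed polygons, each an `n x 3` matrix of
#'   vertices (the closing edge from last back to first vertex is
#'   implied).
#' @export
make_hopf_rings <- function(ring_segments = 24L, step = 3.8,
                            handedness = 1, separation = NULL) {
  R <- ring_segments * step / (2 * pi)
  if (is.null(separation)) separation <- R
  t <- 2 * pi * (seq_len(ring_segments) - 1L) / ring_segments
  p1 <- cbind(R * cos(t), R * sin(t), 0)
  p2 <- cbind(separation + R * cos(t), 0, -R * sin(t))
  if (handedness < 0) {
    p1[, 3L] <- -p1[, 3L]
    p2[, 3L] <- -p2[, 3L]
  }
  list(p1, p2)
}

#' Linking number of two closed polygons
#'
#' Direct cross-pair Gauss-integral sum over all segment pairs of two
#' closed polygons (closing edges included); an integer up to numerical
#' error for non-intersecting curves.
#'
#' @param poly1,poly2 `n x 3` vertex matrices of closed polygons.
#' @return The linking number (real; integer up to numerics).
#' @export
polygon_linking_number <- function(poly1, poly2) {
  close_up <- function(p) rbind(p, p[1L, ])
  a <- close_up(as.matrix(poly1)); b <- close_up(as.matrix(poly2))
  na <- nrow(a) - 1L; nb <- nrow(b) - 1L
  total <- 0
  for (i in seq_len(na))
    for (j in seq_len(nb))
      total <- total + segment_pair_writhe(a[i, ], a[i + 1L, ],
                                           b[j, ], b[j + 1L, ])
  total
}

#' Near-closed loop pierced by a straight rod
#'
#' A single trace modelling a poke: a near-closed planar ring, a linker
#' that dives below the ring plane well outside the ring, and a straight
#' vertical rod of `rod_segments` segments crossing the plane at
#' (`offset`, 0), i.e. through the ring's centre for `offset = 0`, near
#' the rim for `offset` close to the ring radius, and outside for larger
#' values.  Ring and rod segment intervals are attached as attributes
#' `"ring_interval"` and `"rod_interval"`.
#'
#' @param ring_segments segments in the ring.
#' @param rod_segments segments in the rod.
#' @param offset x-offset of the rod from the ring centre (Angstrom).
#' @param step nominal spacing (Angstrom).
#' @param closure ring terminus gap (Angstrom).
#' @return A [ca_trace()].
#' @export
make_pierced_loop <- function(ring_segments = 20L, rod_segments = 10L,
                              offset = 0, step = 3.8, closure = 5) {
  R <- ring_segments * step / (2 * pi)
  gap <- 2 * asin(pmin(1, closure / (2 * R)))
  ring <- arc_points(ring_segments + 1L, R, c(0, 0, 0),
                     c(1, 0, 0), c(0, 1, 0), gap / 2, 2 * pi - gap / 2)

  rod_len <- rod_segments * step
  z0 <- -rod_len / 2
  dive <- z0 - step  # linker hands over one bond length below the rod start
  linker <- resample_polyline(rbind(ring[nrow(ring), ],
                                    c(R + 8, -5, 0),
                                    c(R + 8, -5, dive),
                                    c(offset, 0, dive)))
  linker <- linker[-1L, , drop = FALSE]
  rod <- cbind(offset, 0, z0 + step * (seq_len(rod_segments + 1L) - 1L))
  tail_out <- cbind(offset, 0,
                    max(rod[, 3L]) + step * seq_len(3L))

  pts <- rbind(ring, linker, rod, tail_out)
  tr <- ca_trace(pts, structure_id = "pierced_loop")
  attr(tr, "ring_interval") <- c(0L, ring_segments - 1L)
  rod_first <- ring_segments + 1L + nrow(linker)
  attr(tr, "rod_interval") <- c(rod_first, rod_first + rod_segments - 1L)
  tr
}
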