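# Label-to-membrane distances, cleft widths, and condition comparisons.

#' Planar membrane model
#'
#' @param point Any point on the plane, Angstrom.
#' @param normal Plane normal (normalized internally).
#' @return An object of class `membrane_plane`.
#' @export
membrane_plane <- function(point, normal) {
  n <- sqrt(sum(normal^2))
  if (n < 1e-12) stop("normal must be non-zero")
  structure(list(kind = "plane", point = point, normal = normal / n),
            class = c("membrane_plane", "membrane"))
}

#' Triangulated membrane model
#'
#' @param vertices n x 3 matrix of vertex coordinates, Angstrom.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `membrane_mesh`.
#' @export
membrane_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (nrow(faces) == 0) stop("mesh has no faces")
  if (max(faces) > nrow(vertices) || min(faces) < 1) {
    stop("face indices outside vertex list")
  }
  structure(list(kind = "mesh", vertices = vertices, faces = faces),
            class = c("membrane_mesh", "membrane"))
}

# Exact point-to-triangle distance (Ericson's region decomposition).
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sqrt(sum((p - (a + ab * v + ac * w))^2))
}

#' Shortest distance from a point to a membrane
#'
#' Planes use the exact normal projection `|(p - p0) . n|`; meshes take
#' the minimum exact point-to-triangle distance over all faces.
#'
#' @param point Numeric length-3 coordinates, Angstrom.
#' @param membrane A `membrane_plane` or `membrane_mesh`.
#' @return Distance in Angstrom (>= 0).
#' @export
shortest_distance <- function(point, membrane) {
  if (inherits(membrane, "membrane_plane")) {
    return(abs(sum((point - membrane$point) * membrane$normal)))
  }
  if (inherits(membrane, "membrane_mesh")) {
    v <- membrane$vertices; f <- membrane$faces
    return(min(vapply(seq_len(nrow(f)), function(i) {
      point_triangle_distance(point, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])
    }, numeric(1))))
  }
  stop("membrane must be a membrane_plane or membrane_mesh")
}

#' Distance statistics of particle centers to a membrane
#'
#' Per-particle shortest distances, their mean and SD (n - 1
#' denominator), and optionally the fraction falling inside a supplied
#' reach interval (e.g. the predicted 110-190 Angstrom range).
#'
#' @param centers n x 3 matrix (or data frame with x, y, z) of particle
#'   centers, Angstrom.
#' @param membrane A membrane model.
#' @param range Optional length-2 closed interval for
#'   `fraction_in_range`.
#' @return An object of class `distance_stats`: list with `distances`,
#'   `mean`, `sd`, `n`, `fraction_in_range`, `range`.
#' @export
distance_stats <- function(centers, membrane, range = NULL) {
  if (is.data.frame(centers)) centers <- as.matrix(centers[, c("x", "y", "z")])
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3)
  if (nrow(centers) < 1) stop("need at least one center")
  d <- vapply(seq_len(nrow(centers)),
              function(i) shortest_distance(centers[i, ], membrane),
              numeric(1))
  structure(
    list(distances = d, mean = mean(d),
         sd = if (length(d) > 1) stats::sd(d) else 0, n = length(d),
         fraction_in_range = if (!is.null(range)) mean(in_reach(d, range)) else NA_real_,
         range = range),
    class = "distance_stats"
  )
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf("Membrane distances: %.1f +/- %.1f Angstrom (n = %d)\n",
              x$mean, x$sd, x$n))
  if (!is.null(x$range)) {
    cat(sprintf("  fraction in [%g, %g]: %.3f\n",
                x$range[1], x$range[2], x$fraction_in_range))
  }
  invisible(x)
}

#' Cleft width between two membranes
#'
#' Samples a grid of points on the postsynaptic membrane patch and
#' measures the shortest distance from each to the presynaptic
#' membrane. Exact for parallel planes (all widths equal the plane
#' separation); for tilted or curved membranes the widths vary with
#' local geometry.
#'
#' @param pre_membrane,post_membrane Membrane models (the grid is laid
#'   on `post_membrane`, which must be a plane or mesh).
#' @param patch_extent Half-width of the sampled square patch, Angstrom
#'   (plane membranes; default 300).
#' @param spacing Grid spacing, Angstrom (default 10).
#' @return An object of class `cleft_width_stats`: list with `widths`,
#'   `mean`, `sd`, `n`.
#' @export
cleft_width <- function(pre_membrane, post_membrane, patch_extent = 300,
                        spacing = 10) {
  pts <- if (inherits(post_membrane, "membrane_plane")) {
    n <- post_membrane$normal
    # orthonormal basis in the plane
    seed_vec <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- seed_vec - sum(seed_vec * n) * n
    u <- u / sqrt(sum(u^2))
    v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
           n[1] * u[2] - n[2] * u[1])
    g <- seq(-patch_extent, patch_extent, by = spacing)
    gg <- expand.grid(s = g, t = g)
    t(apply(gg, 1, function(r) post_membrane$point + r[1] * u + r[2] * v))
  } else {
    post_membrane$vertices
  }
  w <- vapply(seq_len(nrow(pts)),
              function(i) shortest_distance(pts[i, ], pre_membrane),
              numeric(1))
  structure(list(widths = w, mean = mean(w), sd = stats::sd(w), n = length(w)),
            class = "cleft_width_stats")
}

#' Compare cleft widths between two conditions
#'
#' Two-sample unequal-variance (Welch) comparison of the width samples;
#' the statistic, degrees of freedom, p-value and effect size are
#' reported, not thresholded.
#'
#' @param stats_a,stats_b `cleft_width_stats` (or any list with a
#'   `widths` vector of length >= 2).
#' @return List with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `difference`, `effect_size` (difference / pooled SD).
#' @export
compare_conditions <- function(stats_a, stats_b) {
  wa <- stats_a$widths; wb <- stats_b$widths
  if (length(wa) < 2 || length(wb) < 2) stop("need at least two widths per condition")
  if (stats::sd(wa) == 0 && stats::sd(wb) == 0 && mean(wa) == mean(wb)) {
    # degenerate identical constant samples: no evidence of difference
    return(list(statistic = 0, df = length(wa) + length(wb) - 2, p_value = 1,
                mean_a = mean(wa), mean_b = mean(wb), difference = 0,
                effect_size = 0))
  }
  tt <- stats::t.test(wa, wb, var.equal = FALSE)
  pooled <- sqrt((stats::var(wa) + stats::var(wb)) / 2)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(wa), mean_b = mean(wb),
       difference = mean(wa) - mean(wb),
       effect_size = if (pooled > 0) (mean(wa) - mean(wb)) / pooled else 0)
}

#' Synthetic membrane-distance scene
#'
#' Places `n` dimer midpoints at true normal distances drawn from a
#' Gaussian above a planar postsynaptic membrane — the generative
#' counterpart of the in-situ distance measurement, with lateral
#' positions uniform over a patch.
#'
#' @param n Number of labels (default 93, the in-situ sample size).
#' @param mean_distance,sd_distance Gaussian parameters of the true
#'   normal distances, Angstrom (defaults 156 and 28).
#' @param membrane A `membrane_plane` (default z = 0 plane).
#' @param patch_extent Lateral half-extent, Angstrom.
#' @return List with `centers` (n x 3) and `membrane`.
#' @export
simulate_label_distances <- function(n = 93L, mean_distance = 156,
                                     sd_distance = 28,
                                     membrane = membrane_plane(c(0, 0, 0), c(0, 0, 1)),
                                     patch_extent = 1000) {
  d <- stats::rnorm(n, mean_distance, sd_distance)
  xy <- matrix(stats::runif(2 * n, -patch_extent, patch_extent), ncol = 2)
  base <- membrane$point
  nrm <- membrane$normal
  seed_vec <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed_vec - sum(seed_vec * nrm) * nrm; u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2], nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  centers <- t(vapply(seq_len(n), function(i) {
    base + xy[i, 1] * u + xy[i, 2] * v + d[i] * nrm
  }, numeric(3)))
  list(centers = centers, membrane = membrane, true_distances = d)
}
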