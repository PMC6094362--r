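# Geometry: centerlines, sphere node layouts, assembled discretizations.

#' Amplitude envelope of a tapered helix
#'
#' \code{E(x) = 1 - exp(-(k_E x)^2)} describes how the helix amplitude grows
#' from zero at the head junction (x = 0) to its steady value; the growth
#' rate \code{taper_rate} (k_E) has units 1/length.  A rate of 0 is the
#' untapered sentinel and returns exactly 1 everywhere.
#'
#' @param x axial coordinate measured from the junction, >= 0.
#' @param taper_rate k_E >= 0; 0 means untapered.
#' @return Scale factors in [0, 1).
#' @examples
#' envelope(0, 2)            # 0: the tapered helix meets the axis
#' envelope(1/2, 2)          # 1 - exp(-1)
#' envelope(c(0, 1, 5), 0)   # untapered: all 1
#' @export
envelope <- function(x, taper_rate) {
  stopifnot(is.numeric(x), is.numeric(taper_rate), taper_rate >= 0)
  if (any(x < 0))
    stop("axial coordinate must be >= 0: the flagellum is parameterized from the junction outward")
  if (taper_rate == 0) return(rep(1, length(x)))
  1 - exp(-(taper_rate * x)^2)
}

# Analytic centerline point and derivative at axial offset xi from the
# junction (xi in [0, L]); vectorized over xi.  The lab x coordinate is
# x0 + xi; chirality flips the y component (mirror through the x-z plane).
helix_curve <- function(spec, xi, phase = spec$phase, x0 = 0) {
  k <- spec$k; b <- spec$b; s <- spec$chirality
  E <- envelope(xi, spec$k_E)
  dE <- if (spec$k_E > 0) 2 * spec$k_E^2 * xi * exp(-(spec$k_E * xi)^2) else
    rep(0, length(xi))
  cs <- cos(k * xi - phase); sn <- sin(k * xi - phase)
  pts <- cbind(x = x0 + xi, y = s * b * E * cs, z = b * E * sn)
  drv <- cbind(1, s * b * (dE * cs - E * k * sn), b * (dE * sn + E * k * cs))
  list(points = pts, deriv = drv)
}

#' Helix centerline polyline
#'
#' Samples the flagellum centerline uniformly in the axial coordinate,
#' returning the ordered polyline, unit tangents, and segment lengths.
#'
#' @param spec a \code{\link{filament_spec}}.
#' @param n_nodes number of polyline points; at least \code{8 * n_turns}.
#' @param phase helix phase (radians); defaults to the spec's phase.
#' @param x0 axial offset of the junction end.
#' @return A list with \code{points} (n x 3), \code{tangents} (n x 3, unit),
#'   \code{seg_lengths} (n-1), and \code{arc_length} (their sum).
#' @examples
#' fl <- filament_spec(1, 8, 2, 1/16)
#' cl <- helix_centerline(fl, 200)
#' cl$arc_length  # close to n_turns * sqrt(lambda^2 + (2 pi b)^2)
#' @export
helix_centerline <- function(spec, n_nodes, phase = spec$phase, x0 = 0) {
  stopifnot(inherits(spec, "filament_spec"))
  if (n_nodes < 8 * spec$n_turns)
    stop("n_nodes too small: need at least 8 points per helix turn to resolve the centerline")
  xi <- seq(0, spec$L, length.out = n_nodes)
  hc <- helix_curve(spec, xi, phase, x0)
  tg <- hc$deriv / sqrt(rowSums(hc$deriv^2))
  seg <- sqrt(rowSums(diff(hc$points)^2))
  list(points = hc$points, tangents = tg, seg_lengths = seg,
       arc_length = sum(seg))
}

# Midpoint quadrature along the centerline: collocation nodes at segment
# midpoints with analytic tangents and arclength weights |r'(xi)| dxi.
# This is the discretization used by the RFT line integrals.
helix_quadrature <- function(spec, nodes_per_turn, phase = spec$phase,
                             x0 = 0) {
  n_seg <- max(8L, as.integer(ceiling(nodes_per_turn * spec$n_turns)))
  dxi <- spec$L / n_seg
  xi <- (seq_len(n_seg) - 0.5) * dxi
  hc <- helix_curve(spec, xi, phase, x0)
  speed <- sqrt(rowSums(hc$deriv^2))
  list(points = hc$points, tangents = hc$deriv / speed,
       weights = speed * dxi)
}

#' Centerline discretization of a filament for the coupled solver
#'
#' Builds the regularized-Stokeslet representation of the flagellum: one
#' collocation node per centerline panel (midpoint rule), with the
#' single-layer integral over each panel evaluated by sub-quadrature along
#' the analytic curve at a spacing of about half the regularization
#' length.  The blob size defaults to the filament cross-section radius
#' (eps = r), tying the regularization to the physical thickness; for
#' standalone filament studies that require quantitative agreement with
#' no-slip cylinder resistance, pass
#' \code{eps_factor = microswim_filament_eps_factor()} (the cylinder-drag
#' calibrated value, about 1.64).
#'
#' @param spec a \code{\link{filament_spec}}.
#' @param nodes_per_turn collocation panels per helix turn (default 32).
#' @param phase helix phase.
#' @param x0 axial offset of the junction end.
#' @param label part label for the nodes (default 2, flagellum).
#' @param eps_factor blob size in units of the cross-section radius.
#' @return A \code{\link{discretization}}.
#' @export
filament_discretization <- function(spec, nodes_per_turn = 32,
                                    phase = spec$phase, x0 = 0,
                                    label = 2L, eps_factor = 1) {
  n_seg <- max(8L, as.integer(ceiling(nodes_per_turn * spec$n_turns)))
  dxi <- spec$L / n_seg
  xi <- (seq_len(n_seg) - 0.5) * dxi
  hc <- helix_curve(spec, xi, phase, x0)
  # panel arc is near-uniform; pick one sub-count for all panels
  eps <- eps_factor * spec$r
  arc <- dxi * max(sqrt(rowSums(hc$deriv^2)))
  m <- max(1L, as.integer(ceiling(arc / (eps / 2))))
  off <- ((seq_len(m) - 0.5) / m - 0.5) * dxi
  xi_sub <- rep(xi, each = m) + rep(off, times = n_seg)
  hs <- helix_curve(spec, xi_sub, phase, x0)
  w_sub <- sqrt(rowSums(hs$deriv^2)) * (dxi / m)
  node_of <- rep(seq_len(n_seg), each = m)
  w_node <- as.numeric(rowsum(w_sub, node_of))
  discretization(hc$points, rep(as.integer(label), n_seg),
                 rep(eps, n_seg), w_node, phase,
                 src = list(points = hs$points, weights = w_sub,
                            node = node_of))
}

#' Labeled point-set discretization
#'
#' Container for the node layout of a body or assembly: node positions, a
#' part label per node (1 = head, 2 = flagellum), a regularization length
#' \code{eps} per node, and a quadrature weight (surface area for head
#' nodes, arclength for flagellum nodes).
#'
#' @param nodes n x 3 matrix of positions.
#' @param label integer part label per node.
#' @param eps regularization length per node, > 0.
#' @param weight quadrature weight per node, > 0.
#' @param phase helix phase used to generate the layout.
#' @param src optional panel sub-quadrature for slender parts: a list with
#'   \code{points} (m x 3), \code{weights} (m) and \code{node} (m, owning
#'   node index).  When a node's weight is spread over several source
#'   points, the single-layer integral over its panel is evaluated by
#'   sub-quadrature instead of one-point quadrature, which is essential
#'   for centerline distributions whose node spacing exceeds the
#'   regularization length.  Nodes absent from \code{src$node} act as
#'   their own (single) source point.
#' @return An object of class \code{"discretization"}.
#' @export
discretization <- function(nodes, label, eps, weight, phase = 0,
                           src = NULL) {
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 3, length(label) == nrow(nodes),
            length(eps) == nrow(nodes), length(weight) == nrow(nodes),
            all(eps > 0), all(weight > 0))
  n <- nrow(nodes)
  if (is.null(src)) {
    src <- list(points = nodes, weights = weight, node = seq_len(n))
  } else {
    stopifnot(is.list(src), ncol(src$points) == 3,
              length(src$weights) == nrow(src$points),
              length(src$node) == nrow(src$points),
              all(src$node %in% seq_len(n)))
    covered <- unique(src$node)
    if (length(covered) < n) {
      rest <- setdiff(seq_len(n), covered)
      src <- list(points = rbind(src$points, nodes[rest, , drop = FALSE]),
                  weights = c(src$weights, weight[rest]),
                  node = c(src$node, rest))
    }
  }
  structure(list(nodes = nodes, label = as.integer(label), eps = eps,
                 weight = weight, phase = phase, src = src),
            class = "discretization")
}

#' @export
print.discretization <- function(x, ...) {
  cat("Discretization:", nrow(x$nodes), "nodes (",
      paste(sprintf("part %d: %d", sort(unique(x$label)),
                    tabulate(x$label)[sort(unique(x$label))]),
            collapse = ", "), ")\n")
  invisible(x)
}

# Mean inter-node spacing of a quasi-uniform layout of n points on a sphere
# of radius R: the side of the equal-area square, sqrt(4 pi R^2 / n).
sphere_spacing <- function(R, n) sqrt(4 * pi * R^2 / n)

#' Quasi-uniform sphere node layout
#'
#' Places \code{n_nodes} points on a sphere with the Fibonacci (golden-angle
#' spiral) layout, a deterministic quasi-uniform covering.  Each node
#' carries an equal area weight \code{4 pi R^2 / n} and a regularization
#' length \code{eps_factor * sqrt(4 pi R^2 / n)} (a multiple of the mean
#' node spacing; see \code{\link{calibrate_head_eps_factor}}).
#'
#' @param spec a \code{\link{head_spec}}.
#' @param n_nodes number of nodes, >= 50.
#' @param center sphere center (3-vector).
#' @param eps_factor blob size in units of the mean node spacing.
#' @return A \code{\link{discretization}} with all labels 1.
#' @export
sphere_nodes <- function(spec, n_nodes, center = c(0, 0, 0),
                         eps_factor = microswim_eps_factor()) {
  stopifnot(inherits(spec, "head_spec"), n_nodes >= 50)
  R <- spec$R
  i <- seq_len(n_nodes) - 1
  z <- 1 - (2 * i + 1) / n_nodes
  rho <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  th <- ga * i
  nodes <- unname(R * cbind(rho * cos(th), rho * sin(th), z))
  nodes <- sweep(nodes, 2, center, "+")
  h <- sphere_spacing(R, n_nodes)
  discretization(nodes, rep(1L, n_nodes), rep(eps_factor * h, n_nodes),
                 rep(4 * pi * R^2 / n_nodes, n_nodes))
}

#' Discretize a head-plus-flagellum assembly
#'
#' Builds the labeled point set for the composite swimmer: a Fibonacci
#' layout on the head surface (label 1) and midpoint-rule nodes along the
#' flagellum centerline (label 2), with the centerline starting on the x
#' axis at \code{x0 = R + gap}.  Flagellum nodes use the filament radius as
#' regularization length; head nodes use the calibrated multiple of the
#' mean surface spacing.
#'
#' @param assembly an \code{\link{assembly_spec}}.
#' @param nodes_per_turn flagellum resolution (default 32 per helix turn).
#' @param n_head head resolution (default 600 nodes).
#' @param phase helix phase for this snapshot.
#' @param eps_factor head blob size in mean-spacing units.
#' @return A \code{\link{discretization}} with both parts labeled.
#' @examples
#' asm <- assembly_spec(head_spec(2), filament_spec(1, 8, 2, 1/16))
#' disc <- assemble(asm, nodes_per_turn = 16, n_head = 100)
#' @export
assemble <- function(assembly, nodes_per_turn = 32, n_head = 600,
                     phase = assembly$filament$phase,
                     eps_factor = microswim_eps_factor()) {
  stopifnot(inherits(assembly, "assembly_spec"))
  hd <- sphere_nodes(assembly$head, n_head, eps_factor = eps_factor)
  x0 <- assembly$head$R + assembly$gap
  fd <- filament_discretization(assembly$filament, nodes_per_turn, phase, x0)
  d2 <- sqrt(rowSums(fd$nodes^2))
  if (any(d2 < assembly$head$R))
    stop("geometric interpenetration: flagellum node inside the head")
  nh <- nrow(hd$nodes)
  discretization(rbind(hd$nodes, fd$nodes),
                 c(hd$label, fd$label),
                 c(hd$eps, fd$eps),
                 c(hd$weight, fd$weight), phase,
                 src = list(points = fd$src$points,
                            weights = fd$src$weights,
                            node = fd$src$node + nh))
}

#' Export a labeled point cloud as legacy VTK poly-data
#'
#' Writes nodes and their part labels in ASCII legacy VTK format for
#' visualization (e.g., in ParaView).
#'
#' @param disc a \code{\link{discretization}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_vtk_points <- function(disc, path) {
  stopifnot(inherits(disc, "discretization"))
  n <- nrow(disc$nodes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "microswim point cloud", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  write(t(disc$nodes), con, ncolumns = 3)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS part int 1", "LOOKUP_TABLE default"), con)
  write(disc$label, con, ncolumns = 9)
  invisible(path)
}
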