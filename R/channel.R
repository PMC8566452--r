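#' Constricted microchannel geometry
#'
#' Describes the constriction device: a straight upstream section of width
#' `upstream_width`, a 45 degree tapered entrance narrowing to the
#' constriction (`width` x `depth` cross-section, `length` long), and a
#' matching tapered expansion back to the upstream width. The four
#' variants are nested sub-domains of the complete device: `model1` is the
#' full channel, `model2` and `model3` keep progressively shorter straight
#' sections around the constriction, and `model4` keeps only the tapered
#' entry and the first stretch of the bore. `model3` is the production
#' default.
#'
#' @param variant one of `"model1"`, `"model2"`, `"model3"`, `"model4"`
#' @param width constriction width (um)
#' @param depth channel depth (um, constant everywhere)
#' @param length constriction length (um)
#' @param taper_angle taper angle in degrees (45 by default)
#' @param upstream_width width of the wide sections (um)
#' @param upstream_length,downstream_length straight-section lengths (um);
#'   defaults depend on the variant
#' @return a `channel_geometry` list with the wall polyline (`poly`:
#'   x versus half-width), the centreline `yc`, depth bounds `zlo`/`zhi`,
#'   domain size and the taper-entrance / constriction-entrance /
#'   constriction-exit plane positions `x_taper`, `x_entry`, `x_exit`
#' @export
channel_geometry <- function(variant = c("model3", "model1", "model2", "model4"),
                             width = 6, depth = 15, length = 50,
                             taper_angle = 45, upstream_width = 30,
                             upstream_length = NULL, downstream_length = NULL) {
  variant <- match.arg(variant)
  stopifnot(width > 0, depth > 0, length > 0, upstream_width > width)
  defaults <- list(model1 = c(40, 40), model2 = c(25, 25),
                   model3 = c(15, 15), model4 = c(15, 0))
  dl <- defaults[[variant]]
  if (is.null(upstream_length)) upstream_length <- dl[1]
  if (is.null(downstream_length)) downstream_length <- dl[2]

  lt <- (upstream_width - width) / 2 / tan(taper_angle * pi / 180)
  hu <- upstream_width / 2
  hc <- width / 2
  x_taper <- upstream_length
  x_entry <- x_taper + lt

  if (variant == "model4") {
    # entry part only: taper plus a short stretch of the bore, no full
    # constriction and no exit expansion
    bore <- min(length / 5, length)
    x_exit <- x_entry + bore
    poly <- rbind(c(0, hu), c(x_taper, hu), c(x_entry, hc), c(x_exit, hc))
    Lx <- x_exit
  } else {
    x_exit <- x_entry + length
    x_expand <- x_exit + lt
    Lx <- x_expand + downstream_length
    poly <- rbind(c(0, hu), c(x_taper, hu), c(x_entry, hc),
                  c(x_exit, hc), c(x_expand, hu), c(Lx, hu))
  }
  structure(list(variant = variant, width = width, depth = depth,
                 length = length, taper_angle = taper_angle,
                 upstream_width = upstream_width,
                 upstream_length = upstream_length,
                 downstream_length = downstream_length,
                 poly = poly, yc = hu, zlo = 0, zhi = depth,
                 Lx = Lx, x_taper = x_taper, x_entry = x_entry, x_exit = x_exit),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("channel %s: constriction %g x %g um^2, length %g um, taper %g deg\n",
              x$variant, x$width, x$depth, x$length, x$taper_angle))
  cat(sprintf("  domain length %g um; planes: taper %g, entry %g, exit %g um\n",
              x$Lx, x$x_taper, x$x_entry, x$x_exit))
  invisible(x)
}

#' Voxelise a channel geometry onto a lattice
#'
#' Builds the solid mask used by the lattice-Boltzmann solver. Site
#' centres lie at `(i + 1/2) dx` along the axis (periodic) and at
#' `(j - 1/2) dx` transversally, so one solid layer pads the fluid on each
#' transverse side and the halfway bounce-back rule places the no-slip
#' plane exactly on the geometric wall when the wall falls between site
#' centres.
#'
#' @param geom a [channel_geometry]
#' @param dx grid spacing (um)
#' @return a list with the integer `solid` mask (1 = wall), `dims`, `dx`
#'   and the site-centre coordinate vectors `x`, `y`, `z`
#' @export
build_channel <- function(geom, dx = 1) {
  stopifnot(inherits(geom, "channel_geometry"), dx > 0)
  if (geom$width < 3 * dx)
    stop("constriction width ", geom$width, " um is under-resolved at dx = ", dx)
  Nx <- round(geom$Lx / dx)
  Ny <- round(geom$upstream_width / dx) + 2L
  Nz <- round(geom$depth / dx) + 2L
  x <- (seq_len(Nx) - 0.5) * dx
  y <- (seq_len(Ny) - 1.5) * dx   # first/last layer outside [0, W_up]
  z <- (seq_len(Nz) - 1.5) * dx
  h <- stats::approx(geom$poly[, 1], geom$poly[, 2], xout = x, rule = 2)$y
  solid <- array(0L, c(Nx, Ny, Nz))
  for (i in seq_len(Nx)) {
    iny <- abs(y - geom$yc) < h[i]
    inz <- z > geom$zlo & z < geom$zhi
    solid[i, , ] <- 1L - outer(iny, inz, "&")
  }
  list(solid = as.integer(solid), dims = c(Nx, Ny, Nz), dx = dx,
       x = x, y = y, z = z, geom = geom)
}
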