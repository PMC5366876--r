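#' Irradiation geometry constructor
#'
#' Defaults reproduce the lymphocyte setup: a 10 um spherical nucleus, a
#' tangential 80 um^2 circular source emitting 5 parallel ions per run
#' (fluence 0.0625 per um^2), a concentric 14.22 um scoring sphere that
#' encloses the rotated source disc, and a stack of 50 slabs of 200 nm for
#' depth-local LET.
#'
#' @param nucleusDiameter um
#' @param scoringDiameter um
#' @param sourceArea um^2
#' @param primariesPerRun ions per run
#' @param slabThickness um
#' @param nSlabs slab count
#' @return a [NucleusGeometry-class]
#' @export
nucleusGeometry <- function(nucleusDiameter = 10, scoringDiameter = 14.22,
                            sourceArea = 80, primariesPerRun = 5L,
                            slabThickness = 0.2, nSlabs = 50L) {
  methods::new("NucleusGeometry",
               nucleusDiameter = nucleusDiameter,
               scoringDiameter = scoringDiameter,
               sourceArea = sourceArea,
               primariesPerRun = as.integer(primariesPerRun),
               slabThickness = slabThickness, nSlabs = as.integer(nSlabs))
}

#' @describeIn nucleusGeometry planar fluence of one run (1/um^2)
#' @param geometry a [NucleusGeometry-class]
#' @export
fluence <- function(geometry) geometry@primariesPerRun / geometry@sourceArea

setMethod("show", "NucleusGeometry", function(object) {
  cat(sprintf(paste0("NucleusGeometry: nucleus %g um, scoring sphere %g um,\n",
                     "  source %g um^2 tangential disc, %d primaries/run ",
                     "(fluence %g um^-2),\n  %d slabs x %g um\n"),
              object@nucleusDiameter, object@scoringDiameter,
              object@sourceArea, object@primariesPerRun, fluence(object),
              object@nSlabs, object@slabThickness))
})

#' Uniform random 3D rotation
#'
#' Rotation matrix drawn uniformly from SO(3) via a normalized quaternion of
#' four standard normals.
#'
#' @return 3x3 orthonormal matrix with determinant +1
#' @export
randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Draw the source frame and primary ions of one run
#'
#' Rotates the tangential source disc by a uniformly random 3D rotation
#' about the nucleus centre, then starts `primariesPerRun` ions from
#' positions uniform on the disc, all exactly parallel and perpendicular to
#' it. In the unrotated frame the disc lies in the plane tangent to the
#' nucleus at its "south pole" and the beam travels towards +z.
#'
#' @param geometry a [NucleusGeometry-class]
#' @param rotation optional fixed rotation matrix (default: random)
#' @return list with elements `rotation` (3x3 matrix), `starts`
#'   (primaries x 3 matrix, um), `direction` (unit length-3)
#' @export
makeRun <- function(geometry, rotation = NULL) {
  if (is.null(rotation)) rotation <- randomRotation()
  n <- geometry@primariesPerRun
  rdisc <- sqrt(geometry@sourceArea / pi)
  rn <- geometry@nucleusDiameter / 2
  r <- rdisc * sqrt(stats::runif(n))
  ph <- stats::runif(n, 0, 2 * pi)
  p0 <- cbind(r * cos(ph), r * sin(ph), rep(-rn, n))
  list(rotation = rotation,
       starts = p0 %*% t(rotation),
       direction = drop(rotation %*% c(0, 0, 1)))
}

#' Dose from point energy deposits
#'
#' Sum of deposit energies inside a region divided by the region's water
#' mass at unit density. An empty selection gives 0 Gy.
#'
#' @param deposits data.frame with columns x, y, z (um) and energy (eV)
#' @param regionVolume region volume (um^3)
#' @param inRegion logical vector selecting in-region deposits, or a
#'   predicate `function(deposits)` returning one; default selects deposits
#'   within `radius` of the origin
#' @param radius convenience spherical region radius (um), used when
#'   `inRegion` is NULL
#' @return absorbed dose (Gy)
#' @export
#' @examples
#' doseFromDeposits(data.frame(x = 0, y = 0, z = 0, energy = 1000), 1)
doseFromDeposits <- function(deposits, regionVolume, inRegion = NULL,
                             radius = Inf) {
  stopifnot(regionVolume > 0)
  if (is.null(inRegion)) {
    inRegion <- if (is.finite(radius))
      deposits$x^2 + deposits$y^2 + deposits$z^2 <= radius^2
    else rep(TRUE, nrow(deposits))
  } else if (is.function(inRegion)) inRegion <- inRegion(deposits)
  eV <- sum(deposits$energy[inRegion])
  eV * .const$J_per_eV / (regionVolume * .const$kg_per_um3)
}

#' LET from dose and fluence
#'
#' Classical relation LET = D / (0.1602 x phi), with the numerical factor
#' converting units at the density of liquid water, so that
#' D[Gy] = 0.1602 x LET[keV/um] x phi[1/um^2].
#'
#' @param dose Gy
#' @param phi fluence (1/um^2), positive
#' @return LET (keV/um)
#' @export
letFromDoseFluence <- function(dose, phi) {
  if (any(phi <= 0)) stop("fluence must be positive", call. = FALSE)
  dose / (.const$gy_per_kev_um_fluence * phi)
}

#' @rdname letFromDoseFluence
#' @param let LET (keV/um)
#' @export
doseFromLetFluence <- function(let, phi) {
  if (any(phi <= 0)) stop("fluence must be positive", call. = FALSE)
  .const$gy_per_kev_um_fluence * let * phi
}

#' Spherical-cap scoring volume for stoppers
#'
#' For an ion whose range is shorter than the nucleus diameter, the dose
#' reference volume is reduced to the spherical cap of height equal to the
#' range, measured from the beam's entry pole.
#'
#' @param geometry a [NucleusGeometry-class]
#' @param range ion range (um), positive
#' @return volume (um^3)
#' @export
capVolume <- function(geometry, range) {
  stopifnot(range > 0)
  d <- geometry@nucleusDiameter
  r <- d / 2
  if (range >= d) return(4 / 3 * pi * r^3)
  h <- range
  pi * h^2 * (3 * r - h) / 3
}

## Volume of the nucleus slice with beam-frame depth in [a, b], depth
## measured from the tangent source plane (0 at the entry pole).
.sliceVolume <- function(geometry, a, b) {
  r <- geometry@nucleusDiameter / 2
  za <- pmin(pmax(a - r, -r), r)     # depth -> centred coordinate
  zb <- pmin(pmax(b - r, -r), r)
  f <- function(z) r^2 * z - z^3 / 3
  pi * (f(zb) - f(za))
}

#' Depth-local dose and LET in slabs
#'
#' Scores the energy deposited within each slab's intersection with the
#' nucleus (slabs are perpendicular to the beam axis, starting at the source
#' plane) and converts it to dose over the slab-sphere intersection volume
#' and to LET through the dose-fluence relation. Deposits are first rotated
#' back into the beam frame of the run.
#'
#' @param deposits data.frame with x, y, z (um), energy (eV)
#' @param geometry a [NucleusGeometry-class]
#' @param rotation the run's source rotation (3x3); identity by default
#' @param phi fluence used in the LET conversion; by default the run fluence
#' @param stopDepths optional per-primary stopping depths (um); when given,
#'   each slab's fluence counts only tracks reaching it
#' @return data.frame: depth_mid, energy_eV, volume, dose, let
#' @export
slabProfile <- function(deposits, geometry, rotation = diag(3),
                        phi = fluence(geometry), stopDepths = NULL) {
  rn <- geometry@nucleusDiameter / 2
  P <- as.matrix(deposits[, c("x", "y", "z")]) %*% rotation  # = t(R) %*% p
  inside <- rowSums(P^2) <= rn^2
  depth <- P[inside, 3] + rn
  en <- deposits$energy[inside]
  edges <- seq(0, by = geometry@slabThickness,
               length.out = geometry@nSlabs + 1L)
  bin <- findInterval(depth, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L; bin[bin > geometry@nSlabs] <- geometry@nSlabs
  eslab <- vapply(seq_len(geometry@nSlabs),
                  function(i) sum(en[bin == i]), numeric(1))
  vol <- .sliceVolume(geometry, edges[-length(edges)], edges[-1])
  dose <- ifelse(vol > 0,
                 eslab * .const$J_per_eV / (vol * .const$kg_per_um3), 0)
  phiSlab <- if (is.null(stopDepths)) rep(phi, geometry@nSlabs)
  else vapply(edges[-length(edges)], function(a)
    sum(stopDepths > a) / geometry@sourceArea, numeric(1))
  let <- ifelse(phiSlab > 0, dose / (.const$gy_per_kev_um_fluence * phiSlab), 0)
  data.frame(depth_mid = 0.5 * (edges[-1] + edges[-length(edges)]),
             energy_eV = eslab, volume = vol, dose = dose, let = let)
}
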