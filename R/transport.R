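#' Secondary-electron kernel parameters
#'
#' The transport surrogate splits every sampled collision transfer into a
#' small deposit at the collision point (`localShare` eV, representing the
#' target's binding/vibrational share) and an electron share that is carried
#' away along a straight, forward-biased direction. The electron's path
#' length is exponential with scale `s0 * (E_e / 1 keV)^exponent` um, capped
#' at `cap` um, and its energy is dropped in equal chunks of about
#' `chunkTarget` eV spread uniformly along that path. The constants are
#' documented tuning knobs of the kernel, not physical claims.
#'
#' @param localShare energy (eV) deposited at the collision point
#' @param chunkTarget target size (eV) of individual electron deposits
#' @param s0 path-length scale (um) for a 1 keV electron share
#' @param exponent growth of the scale with electron energy
#' @param cap maximum path length (um)
#' @return parameter list
#' @export
kernelParams <- function(localShare = 15, chunkTarget = 40,
                         s0 = 0.05, exponent = 1.7, cap = 5) {
  list(localShare = localShare, chunkTarget = chunkTarget,
       s0 = s0, exponent = exponent, cap = cap)
}

.kernelScale <- function(e_eV, kp) pmin(kp$s0 * (e_eV / 1000)^kp$exponent, kp$cap)

.orthoBasis <- function(d) {
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  b1 <- c(d[2] * a[3] - d[3] * a[2], d[3] * a[1] - d[1] * a[3],
          d[1] * a[2] - d[2] * a[1])
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(d[2] * b1[3] - d[3] * b1[2], d[3] * b1[1] - d[1] * b1[3],
          d[1] * b1[2] - d[2] * b1[1])
  rbind(b1, b2, d)
}

## Forward-biased unit vectors relative to ion direction d:
## cos(theta) uniform on (0, 1) (forward hemisphere), azimuth uniform.
.electronDirections <- function(n, d) {
  ct <- stats::runif(n)
  st <- sqrt(1 - ct^2)
  ph <- stats::runif(n, 0, 2 * pi)
  B <- .orthoBasis(d)
  cbind(st * cos(ph), st * sin(ph), ct) %*% B
}

#' Displace a secondary electron's energy
#'
#' Places the electron share of one collision as one or more point deposits
#' along a straight forward-biased path; the deposited energy sums to the
#' input exactly. Used internally by [simulateTrack()]; exported for
#' inspection and testing.
#'
#' @param energy electron share (eV, > 0)
#' @param origin collision point (um, length-3)
#' @param direction ion direction (unit, length-3); the electron is emitted
#'   forward-biased around it
#' @param kp kernel parameters, see [kernelParams()]
#' @return data.frame with columns x, y, z, energy, kind
#' @export
electronKernel <- function(energy, origin, direction, kp = kernelParams()) {
  stopifnot(energy > 0)
  L <- stats::rexp(1) * .kernelScale(energy, kp)
  L <- min(L, kp$cap)
  w <- .electronDirections(1, direction)
  n <- max(1L, ceiling(energy / kp$chunkTarget))
  frac <- (seq_len(n) - 0.5) / n
  data.frame(x = origin[1] + frac * L * w[1],
             y = origin[2] + frac * L * w[2],
             z = origin[3] + frac * L * w[3],
             energy = rep(energy / n, n),
             kind = "electron_kernel")
}

.scaledStoppingQuiet <- function(ion, E, baseline)
  stoppingH(baseline, E) * scalingFactor(ion@Z, betaFromEnergy(E))

.scaledImfpQuiet <- function(ion, E, baseline)
  imfpH(baseline, E) * scalingFactor(ion@Z, betaFromEnergy(E))

#' Simulate one ion track
#'
#' Event-by-event slowing down along a straight line: free flights are
#' exponential with mean 1/(scaled IMFP), each collision transfers an energy
#' sampled from the baseline spectrum (deposited partly at the collision
#' point and partly through the electron kernel), and a small continuous
#' residual closes any gap between the discrete collision losses and the
#' scaled stopping power, so the mean energy loss per unit path equals the
#' scaled stopping power. The track ends when the energy falls below
#' `floorEnergy` (the remaining energy is deposited at the endpoint) or when
#' the ion leaves the scoring sphere.
#'
#' Randomness is drawn from the current RNG stream; call `set.seed()` for a
#' reproducible track.
#'
#' @param ion an [IonSpec-class], symbol or Z
#' @param energy initial energy (MeV/u), at least `floorEnergy`
#' @param start position (um, length-3) relative to the nucleus centre
#' @param direction unit direction (length-3); an error is raised if missing
#'   or not normalized
#' @param baseline a [BaselineTable-class]
#' @param scoringRadius radius (um) of the sphere in which the ion is
#'   followed (deposits placed by the electron kernel may land outside)
#' @param floorEnergy transport cutoff (MeV/u)
#' @param trackId integer label attached to all deposits
#' @param kp kernel parameters, see [kernelParams()]
#' @return a [TrackRecord-class]
#' @export
#' @examples
#' set.seed(1)
#' tr <- simulateTrack("H", 0.25, c(0, 0, -5), c(0, 0, 1))
simulateTrack <- function(ion, energy, start, direction,
                          baseline = defaultBaseline(),
                          scoringRadius = 14.22 / 2, floorEnergy = 0.01,
                          trackId = 1L, kp = kernelParams()) {
  ion <- .asIon(ion)
  if (missing(direction) || length(direction) != 3 || anyNA(direction))
    stop("direction must be a length-3 unit vector", call. = FALSE)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("direction must be normalized to |d| = 1", call. = FALSE)
  if (energy < floorEnergy) stop("initial energy below transport floor", call. = FALSE)
  .checkSpan(baseline, energy)

  A <- as.numeric(ion@A)
  E <- energy
  pos <- as.numeric(start)
  depth <- 0
  dep <- list(); ndep <- 0L
  pushDep <- function(m) {
    ndep <<- ndep + 1L
    dep[[ndep]] <<- m
  }
  path <- list(c(0, E))
  stopped <- FALSE; exitE <- 0

  repeat {
    # evaluate rates at the anticipated mid-chunk energy to avoid a
    # first-order lag while the stopping power varies along the chunk;
    # the expected chunk loss accounts for an early boundary exit
    S0 <- .scaledStoppingQuiet(ion, E, baseline)
    bq0 <- sum(pos * direction)
    rem <- -bq0 + sqrt(max(bq0^2 - (sum(pos^2) - scoringRadius^2), 0))
    expLoss <- min(0.02 * E * A * 1e6, S0 * 1000 * rem)
    Em <- max(E - 0.5 * expLoss / (A * 1e6), min(baseline@energy))
    rate <- .scaledImfpQuiet(ion, Em, baseline)
    mt   <- meanTransfer(baseline, Em)
    Ssc  <- .scaledStoppingQuiet(ion, Em, baseline)
    rres <- max(0, Ssc * 1000 - rate * mt)      # eV per um, continuous residual

    budget <- 0.02 * E * A * 1e6                # eV to lose in this chunk
    nb <- max(8L, ceiling(1.3 * budget / mt))
    s   <- stats::rexp(nb) / rate
    tau <- sampleTransfer(baseline, Em, nb)
    loss <- tau + rres * s
    cl <- cumsum(loss)
    j <- findInterval(budget, cl) + 1L          # first index exceeding budget
    j <- min(j, nb)

    remaining <- (E - floorEnergy) * A * 1e6
    jstop <- if (cl[j] >= remaining) which(cl >= remaining)[1] else 0L

    keep <- seq_len(if (jstop > 0L) jstop else j)
    pcum <- cumsum(s[keep])
    pts  <- cbind(pos[1] + pcum * direction[1],
                  pos[2] + pcum * direction[2],
                  pos[3] + pcum * direction[3])
    rad2 <- rowSums(pts^2)
    out <- which(rad2 > scoringRadius^2)

    if (length(out) && (jstop == 0L || out[1] < jstop)) {
      k <- out[1]                               # exits during flight k
      p0 <- if (k == 1L) pos else pts[k - 1L, ]
      # solve |p0 + t d| = R for t in (0, s_k]
      bq <- sum(p0 * direction); cq <- sum(p0^2) - scoringRadius^2
      t  <- -bq + sqrt(max(bq^2 - cq, 0))
      kkeep <- seq_len(k - 1L)
      lost <- if (k > 1L) cl[k - 1L] else 0
      lost <- lost + rres * t
      if (rres > 0 && t > 0)
        pushDep(cbind(p0[1] + 0.5 * t * direction[1],
                      p0[2] + 0.5 * t * direction[2],
                      p0[3] + 0.5 * t * direction[3], rres * t, 1))
      if (k > 1L) {
        collide <- .depositCollisions(pts[kkeep, , drop = FALSE],
                                      tau[kkeep], s[kkeep], rres,
                                      direction, kp)
        pushDep(collide)
      }
      E <- E - lost / (A * 1e6)
      depth <- depth + (if (k > 1L) pcum[k - 1L] else 0) + t
      path[[length(path) + 1L]] <- c(depth, E)
      exitE <- max(E, 0)
      break
    }

    if (jstop > 0L) {                           # stops at collision jstop
      kkeep <- seq_len(jstop - 1L)
      if (jstop > 1L)
        pushDep(.depositCollisions(pts[kkeep, , drop = FALSE],
                                   tau[kkeep], s[kkeep], rres,
                                   direction, kp))
      spent <- if (jstop > 1L) cl[jstop - 1L] else 0
      rest <- E * A * 1e6 - spent               # all remaining energy
      pushDep(cbind(pts[jstop, 1], pts[jstop, 2], pts[jstop, 3], rest, 1))
      depth <- depth + pcum[jstop]
      path[[length(path) + 1L]] <- c(depth, 0)
      E <- 0; stopped <- TRUE
      break
    }

    pushDep(.depositCollisions(pts, tau[keep], s[keep], rres, direction, kp))
    E <- E - cl[j] / (A * 1e6)
    pos <- pts[j, ]
    depth <- depth + pcum[j]
    path[[length(path) + 1L]] <- c(depth, E)
    if (E < floorEnergy) {                      # numerical guard
      pushDep(cbind(pos[1], pos[2], pos[3], E * A * 1e6, 1))
      E <- 0; stopped <- TRUE
      path[[length(path) + 1L]] <- c(depth, 0)
      break
    }
  }

  M <- do.call(rbind, dep[seq_len(ndep)])
  if (is.null(M) || nrow(M) == 0L)
    M <- matrix(numeric(0), 0, 5)
  deposits <- data.frame(x = M[, 1], y = M[, 2], z = M[, 3],
                         energy = M[, 4],
                         kind = c("ion_local", "electron_kernel")[M[, 5]],
                         track_id = rep(as.integer(trackId), nrow(M)))
  pm <- do.call(rbind, path)
  colnames(pm) <- c("depth", "energy")
  methods::new("TrackRecord", ion = ion, initialEnergy = energy,
               deposits = deposits, path = pm,
               stoppedInside = stopped, exitEnergy = exitE)
}

## Vectorized deposition for a block of collisions at positions `pts`:
## local share + continuous residual at the collision point, electron share
## spread along per-electron straight paths.
.depositCollisions <- function(pts, tau, s, rres, direction, kp) {
  n <- length(tau)
  local <- pmin(tau, kp$localShare) + rres * s
  eshare <- pmax(tau - kp$localShare, 0)
  out <- cbind(pts[, 1], pts[, 2], pts[, 3], local, rep(1, n))
  he <- which(eshare > 0)
  if (length(he)) {
    e <- eshare[he]
    L <- pmin(stats::rexp(length(he)) * .kernelScale(e, kp), kp$cap)
    W <- .electronDirections(length(he), direction)
    nch <- pmax(1L, ceiling(e / kp$chunkTarget))
    idx <- rep.int(he, nch)
    rei <- rep.int(seq_along(he), nch)
    within <- sequence(nch)
    frac <- (within - 0.5) / rep.int(nch, nch)
    d <- frac * L[rei]
    km <- cbind(pts[idx, 1] + d * W[rei, 1],
                pts[idx, 2] + d * W[rei, 2],
                pts[idx, 3] + d * W[rei, 3],
                (e / nch)[rei], rep(2, length(idx)))
    out <- rbind(out, km)
  }
  out
}

#' Deterministic ion range in water
#'
#' Integrates the reciprocal (Barkas-scaled) stopping power downward from
#' the initial energy. `method = "extrapolate10"` implements the range rule
#' used for stoppers: the depth at which the energy has decreased to 10% of
#' its initial value, linearly extrapolated to zero energy along the local
#' slope of the depth-energy curve. `method = "csda"` integrates the full
#' continuous-slowing path down to the table floor.
#'
#' @param ion an [IonSpec-class], symbol or Z
#' @param energy initial energy (MeV/u), at least 0.01
#' @param baseline a [BaselineTable-class]
#' @param method range definition, see Details
#' @param n number of integration nodes
#' @return range in um
#' @export
#' @examples
#' computeRange("H", 0.25)  # about 4 um
computeRange <- function(ion, energy, baseline = defaultBaseline(),
                         method = c("extrapolate10", "csda"), n = 8000L) {
  method <- match.arg(method)
  ion <- .asIon(ion)
  if (energy < .applicabilityFloor)
    stop("initial energy below the 0.01 MeV/u applicability floor", call. = FALSE)
  .checkSpan(baseline, energy)
  A <- as.numeric(ion@A)
  floorE <- min(baseline@energy)
  Eg <- exp(seq(log(energy), log(floorE), length.out = n))
  S <- .scaledStoppingQuiet(ion, Eg, baseline)
  seg <- -diff(Eg) * 1000 * A * 0.5 * (1 / S[-1] + 1 / S[-n])
  d <- c(0, cumsum(seg))
  if (method == "csda") return(d[n])
  E10 <- 0.1 * energy
  d10 <- stats::approx(Eg, d, xout = E10)$y
  d10 + E10 * 1000 * A / .scaledStoppingQuiet(ion, E10, baseline)
}

setMethod("show", "TrackRecord", function(object) {
  cat(sprintf(paste0("TrackRecord: %s at %.4g MeV/u, %d deposits, ",
                     "depth %.3g um, %s\n"),
              object@ion@name, object@initialEnergy, nrow(object@deposits),
              max(object@path[, "depth"]),
              if (object@stoppedInside) "stopped inside"
              else sprintf("exited with %.4g MeV/u", object@exitEnergy)))
})
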