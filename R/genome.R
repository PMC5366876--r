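## Human-proportioned chromosome sizes (Mbp, haploid 1..22 + X); the model
## genome is diploid and rescaled to the requested total length.
.karyotypeMbp <- c(245, 243, 198, 190, 182, 171, 159, 145, 138, 134, 135,
                   133, 114, 107, 102, 90, 83, 80, 59, 63, 48, 51, 155)

.chromLengths <- function(genomeLength) {
  w <- rep(.karyotypeMbp, 2)
  len <- floor(genomeLength * w / sum(w))
  len[length(len)] <- len[length(len)] + (genomeLength - sum(len))
  len
}

## Largest-remainder apportionment of n into parts proportional to w.
.apportion <- function(n, w) {
  x <- n * w / sum(w)
  f <- floor(x)
  rem <- n - sum(f)
  if (rem > 0) {
    o <- order(x - f, decreasing = TRUE)[seq_len(rem)]
    f[o] <- f[o] + 1
  }
  pmax(as.integer(f), 1L)
}

#' Build the voxelized chromatin model
#'
#' Lays the genome out as a randomized lattice walk on a cubic grid
#' (50 nm voxels by default) confined to the spherical nucleus. Each
#' chromosome is one walk over distinct voxels with directional persistence;
#' when the walk gets locally trapped it restarts from a free voxel, which
#' emulates a chromatin loop returning to a nuclear attachment site.
#' Genomic coordinates increase monotonically along each walk, so spatial
#' and genomic proximity are correlated at the voxel scale. Loop (~100 kbp)
#' and 1 Mbp domain boundaries are recorded per chromosome.
#'
#' Uses the current RNG stream.
#'
#' @param geometry a [NucleusGeometry-class]
#' @param genomeLength total genome size in bp (default human diploid)
#' @param bpPerVoxel DNA content per chromatin fiber voxel (bp)
#' @param voxelSize voxel edge (um)
#' @return a [ChromatinModel-class]
#' @export
buildNucleusModel <- function(geometry, genomeLength = 6.4e9,
                              bpPerVoxel = 5500, voxelSize = 0.05) {
  rn <- geometry@nucleusDiameter / 2
  G <- as.integer(ceiling(geometry@nucleusDiameter / voxelSize))
  ax <- (seq_len(G) - 0.5) * voxelSize - rn
  nTot <- as.integer(round(genomeLength / bpPerVoxel))
  inside <- outer(ax^2, ax^2, "+")            # G x G matrix of x^2+y^2
  insideMask <- logical(G^3)
  r2 <- rn^2
  for (k in seq_len(G)) {
    sl <- inside + ax[k]^2 <= r2
    insideMask[((k - 1L) * G * G + 1L):(k * G * G)] <- sl
  }
  capacity <- sum(insideMask)
  if (nTot > 0.95 * capacity)
    stop("genome too large for the nuclear volume at this voxel size",
         call. = FALSE)

  chromLen <- .chromLengths(genomeLength)
  nPerChrom <- .apportion(nTot, chromLen)
  occ <- integer(G^3)
  voxelKey <- integer(nTot)
  chromosome <- integer(nTot)
  bpStart <- numeric(nTot)
  stepDir <- matrix(0, nTot, 3)
  offs <- c(1L, -1L, G, -G, G * G, -(G * G))
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  insideIdx <- which(insideMask)

  pickFree <- function() {
    for (i in 1:200) {
      cand <- insideIdx[sample.int(length(insideIdx), 1L)]
      if (occ[cand] == 0L) return(cand)
    }
    free <- insideIdx[occ[insideIdx] == 0L]
    free[sample.int(length(free), 1L)]
  }

  w <- 0L
  for (cc in seq_along(chromLen)) {
    cur <- pickFree()
    ijk <- c((cur - 1L) %% G, ((cur - 1L) %/% G) %% G, (cur - 1L) %/% (G * G)) + 1L
    prev <- 0L
    for (v in seq_len(nPerChrom[cc])) {
      w <- w + 1L
      occ[cur] <- w
      voxelKey[w] <- cur
      chromosome[w] <- cc
      bpStart[w] <- (v - 1) * bpPerVoxel + 1
      if (v == nPerChrom[cc]) {
        stepDir[w, ] <- if (prev > 0L) dirs[prev, ] else c(0, 0, 1)
        break
      }
      ok <- logical(6)
      for (d in 1:6) {
        nijk <- ijk + dirs[d, ]
        ok[d] <- all(nijk >= 1L) && all(nijk <= G) &&
          { lin <- cur + offs[d]; insideMask[lin] && occ[lin] == 0L }
      }
      d <- if (prev > 0L && ok[prev] && stats::runif(1) < 0.6) prev
           else if (any(ok)) { cand <- which(ok); cand[sample.int(length(cand), 1L)] }
           else 0L
      if (d == 0L) {                          # trapped: loop re-attachment
        stepDir[w, ] <- if (prev > 0L) dirs[prev, ] else c(0, 0, 1)
        cur <- pickFree()
        ijk <- c((cur - 1L) %% G, ((cur - 1L) %/% G) %% G,
                 (cur - 1L) %/% (G * G)) + 1L
        prev <- 0L
      } else {
        stepDir[w, ] <- dirs[d, ]
        cur <- cur + offs[d]
        ijk <- ijk + dirs[d, ]
        prev <- d
      }
    }
  }

  loopStarts <- lapply(chromLen, function(L) {
    s <- cumsum(stats::runif(ceiling(L / 8e4), 8e4, 1.2e5))
    c(1, s[s < L] + 1)
  })
  domainStarts <- lapply(chromLen, function(L) seq(1, L, by = 1e6))

  methods::new("ChromatinModel", voxelSize = voxelSize, gridDim = G,
               voxelKey = voxelKey, chromosome = chromosome,
               bpStart = bpStart, stepDir = stepDir, occupancy = occ,
               bpPerVoxel = bpPerVoxel, genomeLength = genomeLength,
               chromLengths = as.numeric(chromLen),
               loopStarts = loopStarts, domainStarts = domainStarts)
}

setMethod("show", "ChromatinModel", function(object) {
  cat(sprintf(paste0("ChromatinModel: %.3g bp in %d voxels of %g nm ",
                     "(%d chromosomes)\n  occupied fraction of grid sphere: %.3f\n"),
              object@genomeLength, length(object@voxelKey),
              object@voxelSize * 1000, length(object@chromLengths),
              length(object@voxelKey) / .insideCount(object)))
})

.insideCount <- function(model) {
  # voxels of the embedding sphere (recomputed; grid mask is not stored)
  G <- model@gridDim; v <- model@voxelSize
  rn <- G * v / 2
  ax <- (seq_len(G) - 0.5) * v - rn
  n <- 0L
  xy <- outer(ax^2, ax^2, "+")
  for (k in seq_len(G)) n <- n + sum(xy + ax[k]^2 <= rn^2)
  n
}

## Map lab positions (um, nucleus-centred) to walk indices (0 = no DNA).
.positionToVoxel <- function(model, x, y, z) {
  G <- model@gridDim; v <- model@voxelSize
  rn <- G * v / 2
  i <- floor((x + rn) / v) + 1
  j <- floor((y + rn) / v) + 1
  k <- floor((z + rn) / v) + 1
  ok <- i >= 1 & i <= G & j >= 1 & j <= G & k >= 1 & k <= G
  widx <- integer(length(x))
  lin <- (k[ok] - 1) * G * G + (j[ok] - 1) * G + i[ok]
  widx[ok] <- model@occupancy[lin]
  widx
}

## Sub-voxel genomic coordinate: project the position onto the walk
## direction through the voxel, so spatial offsets map to bp offsets; the
## strand is decided by the side of the walk axis the position falls on,
## so the sugar-phosphate group hit is a deterministic function of the
## position (repeated deposits at one point accumulate on one group).
.voxelBp <- function(model, widx, x, y, z) {
  v <- model@voxelSize
  G <- model@gridDim
  rn <- G * v / 2
  key <- model@voxelKey[widx]
  ci <- ((key - 1) %% G + 0.5) * v - rn
  cj <- (((key - 1) %/% G) %% G + 0.5) * v - rn
  ck <- ((key - 1) %/% (G * G) + 0.5) * v - rn
  d <- model@stepDir[widx, , drop = FALSE]
  dx <- x - ci; dy <- y - cj; dz <- z - ck
  frac <- (dx * d[, 1] + dy * d[, 2] + dz * d[, 3]) / v + 0.5
  frac <- pmin(pmax(frac, 0), 1 - 1e-9)
  chrom <- model@chromosome[widx]
  pos <- model@bpStart[widx] + floor(frac * model@bpPerVoxel)
  pos <- pmin(pos, model@chromLengths[chrom])
  # transverse basis vector: cyclic successor of the dominant walk axis
  ax <- max.col(abs(d), ties.method = "first")
  side <- cbind(dx, dy, dz)[cbind(seq_along(widx), ax %% 3L + 1L)]
  list(chromosome = chrom, pos = pos,
       strand = ifelse(side >= 0, "+", "-"))
}

#' Depth profile of DNA mass
#'
#' Mean base-pair content of each scoring slab, averaged over random
#' rotations of the chromatin model about the nucleus centre. Sums to the
#' genome length (voxels never leave the nucleus under rotation).
#'
#' @param model a [ChromatinModel-class]
#' @param geometry a [NucleusGeometry-class]
#' @param nRotations number of random rotations averaged
#' @return numeric vector of bp per slab
#' @export
dnaMassPerSlab <- function(model, geometry, nRotations = 100L) {
  stopifnot(nRotations >= 1L)
  G <- model@gridDim; v <- model@voxelSize
  rn <- G * v / 2
  key <- model@voxelKey
  coords <- cbind(((key - 1) %% G + 0.5) * v - rn,
                  (((key - 1) %/% G) %% G + 0.5) * v - rn,
                  ((key - 1) %/% (G * G) + 0.5) * v - rn)
  # per-voxel bp weight; tail voxels of a chromosome may carry less
  bp <- rep(model@bpPerVoxel, length(key))
  tails <- cumsum(tabulate(model@chromosome))
  bp[tails] <- model@chromLengths - model@bpStart[tails] + 1
  edges <- seq(0, by = geometry@slabThickness,
               length.out = geometry@nSlabs + 1L)
  acc <- numeric(geometry@nSlabs)
  for (r in seq_len(nRotations)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    depth <- drop(coords %*% u) + geometry@nucleusDiameter / 2
    b <- findInterval(depth, edges, rightmost.closed = TRUE)
    b[b < 1L] <- 1L; b[b > geometry@nSlabs] <- geometry@nSlabs
    acc <- acc + vapply(seq_len(geometry@nSlabs),
                        function(i) sum(bp[b == i]), numeric(1))
  }
  acc / nRotations
}

#' Direct strand-break probability ramp
#'
#' Probability that the energy accumulated in a single sugar-phosphate group
#' breaks the strand: zero up to 5 eV, rising linearly to one at 37.5 eV.
#'
#' @param e accumulated energy (eV); vectorized
#' @return probability in [0, 1]
#' @export
#' @examples
#' directSbProbability(c(5, 21.25, 37.5))
directSbProbability <- function(e) {
  stopifnot(all(e >= 0))
  pmin(pmax((e - 5) / 32.5, 0), 1)
}

#' Damage-model parameters
#'
#' Tunable surrogate parameters of the break-induction stage. `f_dna` is the
#' probability that a deposit inside a chromatin voxel hits a sugar-phosphate
#' group (it absorbs the DNA volume fraction, hydration shell and histone
#' screening). The hydroxyl-radical surrogate spawns a radical from a
#' non-DNA deposit with probability `p_oh`, walks it isotropically with step
#' `oh_step` um for at most `oh_steps` steps (encoding the scavenging
#' lifetime), reacts with deoxyribose in a chromatin voxel with probability
#' `p_deoxy`, and removes radicals beyond `k_max` per voxel and track
#' (radical-radical recombination in dense track cores). 65% of
#' deoxyribose reactions yield a strand break; 1% of strand breaks convert
#' to double-strand breaks. Defaults are calibrated so that sparsely
#' ionizing irradiation yields roughly 60 direct and 100 indirect strand
#' breaks per Gy per Gbp.
#'
#' @param f_dna DNA-hit probability for deposits in occupied voxels
#' @param p_oh radical yield per non-DNA deposit
#' @param p_deoxy deoxyribose reaction probability per visited chromatin voxel
#' @param oh_step radical walk step (um)
#' @param oh_steps maximum number of walk steps
#' @param k_max radical survival cap per voxel and track
#' @param p_conversion SB to DSB conversion probability
#' @return named list
#' @export
damageParams <- function(f_dna = 0.017, p_oh = 0.35, p_deoxy = 6.5e-4,
                         oh_step = 0.004, oh_steps = 120L, k_max = 12L,
                         p_conversion = 0.01) {
  list(f_dna = f_dna, p_oh = p_oh, p_deoxy = p_deoxy, oh_step = oh_step,
       oh_steps = as.integer(oh_steps), k_max = as.integer(k_max),
       p_conversion = p_conversion)
}

.OH_BREAK_PROB <- 0.65  # strand-break yield per OH-deoxyribose interaction

.emptyBreaks <- function() {
  data.frame(chromosome = integer(0), pos = numeric(0),
             strand = character(0), origin = character(0),
             track_id = integer(0))
}

#' Direct strand breaks from energy deposits
#'
#' Each deposit falling into an occupied chromatin voxel hits DNA with
#' probability `f_dna`; the hit is assigned a (bp, strand) sugar-phosphate
#' group by projecting the deposit position onto the chromatin walk (strand
#' chosen with equal probability). Energies are accumulated per group over
#' the whole exposure, and each group breaks with the 5-37.5 eV ramp
#' probability applied to its accumulated energy.
#'
#' @param deposits data.frame with x, y, z (um), energy (eV), track_id
#' @param model a [ChromatinModel-class]
#' @param params see [damageParams()]
#' @return break data.frame (chromosome, pos, strand, origin, track_id)
#'   with attribute `dnaHit`: logical per input deposit
#' @export
depositsToDirectBreaks <- function(deposits, model, params = damageParams()) {
  n <- nrow(deposits)
  if (n == 0L) { b <- .emptyBreaks(); attr(b, "dnaHit") <- logical(0); return(b) }
  widx <- .positionToVoxel(model, deposits$x, deposits$y, deposits$z)
  hit <- widx > 0L & stats::runif(n) < params$f_dna
  out <- .emptyBreaks()
  if (any(hit)) {
    loc <- .voxelBp(model, widx[hit], deposits$x[hit], deposits$y[hit],
                    deposits$z[hit])
    dt <- data.table::data.table(
      chromosome = loc$chromosome, pos = loc$pos,
      strand = loc$strand,
      energy = deposits$energy[hit],
      track_id = as.integer(deposits$track_id[hit]))
    grp <- dt[order(-energy),
              .(energy = sum(energy), track_id = track_id[1]),
              by = .(chromosome, pos, strand)]
    broke <- stats::runif(nrow(grp)) < directSbProbability(grp$energy)
    if (any(broke))
      out <- data.frame(chromosome = grp$chromosome[broke],
                        pos = grp$pos[broke], strand = grp$strand[broke],
                        origin = "direct", track_id = grp$track_id[broke])
  }
  attr(out, "dnaHit") <- hit
  out
}

#' Indirect strand breaks via the hydroxyl-radical surrogate
#'
#' Non-DNA deposits spawn hydroxyl radicals that perform isotropic random
#' walks; a radical entering a chromatin voxel reacts with the deoxyribose
#' moiety with probability `p_deoxy` per step, and 65% of those reactions
#' produce a strand break at the voxel's projected (bp, strand) group.
#' Radical density per voxel and track is capped at `k_max` to emulate
#' radical-radical recombination in dense track cores, which suppresses
#' indirect damage at high LET.
#'
#' @inheritParams depositsToDirectBreaks
#' @param dnaHit optional logical (from [depositsToDirectBreaks()]) marking
#'   deposits already consumed as direct DNA hits; these spawn no radicals
#' @return break data.frame with attributes `encounters` (number of
#'   OH-deoxyribose reactions) for diagnostic use
#' @export
indirectBreaks <- function(deposits, model, params = damageParams(),
                           dnaHit = NULL) {
  n <- nrow(deposits)
  out <- .emptyBreaks()
  attr(out, "encounters") <- 0L
  if (n == 0L || params$p_oh <= 0) return(out)
  use <- if (is.null(dnaHit)) rep(TRUE, n) else !dnaHit
  rn <- model@gridDim * model@voxelSize / 2
  inNuc <- deposits$x^2 + deposits$y^2 + deposits$z^2 <= rn^2
  use <- use & inNuc & stats::runif(n) < params$p_oh
  if (!any(use)) return(out)

  px <- deposits$x[use]; py <- deposits$y[use]; pz <- deposits$z[use]
  tid <- as.integer(deposits$track_id[use])
  # radical-density suppression per origin voxel and track
  G <- model@gridDim; v <- model@voxelSize
  lin <- (floor((pz + rn) / v)) * G * G + (floor((py + rn) / v)) * G +
    floor((px + rn) / v) + 1
  dt <- data.table::data.table(lin = lin, tid = tid, i = seq_along(lin))
  keep <- dt[, .(i = i[seq_len(min(.N, params$k_max))]), by = .(lin, tid)]$i
  px <- px[keep]; py <- py[keep]; pz <- pz[keep]; tid <- tid[keep]

  m <- length(px)
  active <- rep(TRUE, m)
  enc <- 0L
  bk <- list()
  for (step in seq_len(params$oh_steps)) {
    idx <- which(active)
    if (!length(idx)) break
    k <- length(idx)
    u <- matrix(stats::rnorm(3 * k), k, 3)
    u <- u / sqrt(rowSums(u^2))
    px[idx] <- px[idx] + params$oh_step * u[, 1]
    py[idx] <- py[idx] + params$oh_step * u[, 2]
    pz[idx] <- pz[idx] + params$oh_step * u[, 3]
    gone <- px[idx]^2 + py[idx]^2 + pz[idx]^2 > (rn + 0.25)^2
    active[idx[gone]] <- FALSE
    idx <- idx[!gone]
    if (!length(idx)) next
    widx <- .positionToVoxel(model, px[idx], py[idx], pz[idx])
    inDna <- widx > 0L
    react <- inDna & stats::runif(length(idx)) < params$p_deoxy
    if (any(react)) {
      ri <- idx[react]
      enc <- enc + length(ri)
      mk <- stats::runif(length(ri)) < .OH_BREAK_PROB
      if (any(mk)) {
        loc <- .voxelBp(model, widx[react][mk], px[ri][mk], py[ri][mk],
                        pz[ri][mk])
        bk[[length(bk) + 1L]] <- data.frame(
          chromosome = loc$chromosome, pos = loc$pos,
          strand = loc$strand,
          origin = "indirect", track_id = tid[ri][mk])
      }
      active[ri] <- FALSE                    # radical consumed
    }
  }
  if (length(bk)) out <- do.call(rbind, bk)
  attr(out, "encounters") <- enc
  out
}

#' Convert strand breaks to double-strand breaks
#'
#' Each break independently gains, with probability `p`, a partner break on
#' the opposite strand at the same position (origin \code{"converted"}),
#' accounting for radical transfer across the double helix. Input breaks
#' are preserved.
#'
#' @param breaks break data.frame
#' @param p conversion probability (default 1%)
#' @return break data.frame with converted partners appended
#' @export
convertSbToDsb <- function(breaks, p = 0.01) {
  if (nrow(breaks) == 0L || p <= 0) return(breaks)
  sel <- stats::runif(nrow(breaks)) < p
  if (!any(sel)) return(breaks)
  partner <- breaks[sel, ]
  partner$strand <- ifelse(partner$strand == "+", "-", "+")
  partner$origin <- "converted"
  rbind(breaks, partner)
}
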