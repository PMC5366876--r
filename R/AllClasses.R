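## Physical constants (CODATA); energies in MeV unless noted.
.const <- list(
  amu      = 931.49410242,   # atomic mass unit rest energy, MeV
  me       = 0.51099895,     # electron rest energy, MeV
  mp       = 938.27208816,   # proton rest energy, MeV
  I_water  = 75e-6,          # mean excitation energy of liquid water, MeV
  K_water  = 0.307075 * 0.55509, # 4 pi N_A re^2 me c^2 * (Z/A), MeV cm^2/g
  J_per_eV = 1.602176634e-19,
  kg_per_um3 = 1e-15,        # unit-density water
  # Gy produced by 1 keV/um crossing 1 um^-2 fluence at unit density
  gy_per_kev_um_fluence = 1.602176634e-16 / 1e-15
)

#' Hydrogen-in-water interaction baseline
#'
#' Tabulated electronic stopping power and total inverse mean free path (IMFP)
#' for hydrogen projectiles (a proton/neutral-atom mixture) in liquid water,
#' together with the parameters of the per-collision energy-transfer
#' distribution (a truncated inverse-square spectrum on \code{[tmin, tmax]}).
#' The table is the substrate that the generalized Barkas scaling multiplies
#' to obtain interaction data for heavier ions at the same velocity.
#'
#' @slot energy energy per nucleon grid (MeV/u), strictly increasing
#' @slot stopping electronic stopping power (keV/um) at each grid point
#' @slot imfp inverse mean free path for energy-depositing collisions (1/um)
#' @slot tmin lower cutoff of the energy-transfer spectrum (eV), per grid point
#' @slot tmax upper cutoff of the energy-transfer spectrum (eV), per grid point
#'
#' @seealso [defaultBaseline()], [loadBaseline()], [stoppingH()]
#' @export
setClass("BaselineTable",
  representation(energy = "numeric", stopping = "numeric",
                 imfp = "numeric", tmin = "numeric", tmax = "numeric"))

.truncInvSqMean <- function(tmin, tmax) {
  # mean of pdf ~ 1/t^2 on [tmin, tmax]
  ifelse(tmax - tmin < 1e-9 * tmax, tmin,
         tmin * tmax / (tmax - tmin) * log(tmax / tmin))
}

setValidity("BaselineTable", function(object) {
  n <- length(object@energy)
  if (any(lengths(list(object@stopping, object@imfp, object@tmin,
                       object@tmax)) != n))
    return("all slots must have equal length")
  if (n < 4) return("need at least 4 grid points")
  if (any(diff(object@energy) <= 0))
    return("energy grid must be strictly increasing")
  if (any(object@stopping <= 0) || any(object@imfp <= 0))
    return("stopping and imfp must be positive")
  if (any(object@tmin <= 0) || any(object@tmax <= object@tmin))
    return("transfer cutoffs must satisfy 0 < tmin < tmax")
  s <- object@stopping
  if (sum(diff(sign(diff(s))) != 0) != 1 ||
      which.max(s) %in% c(1L, n))
    return("stopping must have a single interior maximum")
  m <- .truncInvSqMean(object@tmin, object@tmax)
  if (any(m * object@imfp > 1000 * object@stopping * 1.01))
    return("mean transfer x imfp exceeds stopping (>1%): discrete collisions cannot outrun total stopping")
  TRUE
})

#' Ion species
#'
#' Static description of a supported projectile: H, He, C, N, O or Ne.
#'
#' @slot Z atomic number
#' @slot A mass number
#' @slot name element symbol
#' @seealso [ionSpec()], [supportedIons()]
#' @export
setClass("IonSpec",
  representation(Z = "integer", A = "integer", name = "character"))

setValidity("IonSpec", function(object) {
  if (length(object@Z) != 1L || length(object@A) != 1L) return("Z, A must be scalar")
  if (object@Z < 1L) return("Z must be >= 1")
  if (object@A < object@Z) return("A must be >= Z")
  if (!object@Z %in% c(1L, 2L, 6L, 7L, 8L, 10L))
    return("unsupported species: supported are H, He, C, N, O, Ne")
  TRUE
})

#' Irradiation geometry
#'
#' Spherical nucleus with a tangential circular ion source, the concentric
#' scoring sphere, and the slab stack used for depth-local LET.
#'
#' @slot nucleusDiameter diameter of the spherical nucleus (um)
#' @slot scoringDiameter diameter of the concentric scoring sphere (um)
#' @slot sourceArea area of the tangential source disc (um^2)
#' @slot primariesPerRun ions started per simulation run
#' @slot slabThickness slab thickness for depth-local scoring (um)
#' @slot nSlabs number of slabs (stack starts at the source plane)
#' @seealso [nucleusGeometry()], [fluence()]
#' @export
setClass("NucleusGeometry",
  representation(nucleusDiameter = "numeric", scoringDiameter = "numeric",
                 sourceArea = "numeric", primariesPerRun = "integer",
                 slabThickness = "numeric", nSlabs = "integer"))

setValidity("NucleusGeometry", function(object) {
  if (object@nucleusDiameter <= 0) return("nucleusDiameter must be positive")
  if (object@scoringDiameter <= object@nucleusDiameter)
    return("scoringDiameter must exceed nucleusDiameter")
  if (object@sourceArea <= 0) return("sourceArea must be positive")
  if (object@primariesPerRun < 1L) return("primariesPerRun must be >= 1")
  if (object@slabThickness <= 0 || object@nSlabs < 1L)
    return("slab stack must be non-empty with positive thickness")
  TRUE
})

#' Coarse voxelized chromatin model
#'
#' The genome is laid out as a randomized lattice walk on a cubic grid inside
#' the nucleus; each occupied voxel carries a contiguous genomic interval of
#' \code{bpPerVoxel} base pairs of one chromosome, so spatial proximity along
#' the walk mirrors genomic proximity. Loop (~100 kbp) and domain (1 Mbp)
#' boundaries are bookkept per chromosome.
#'
#' @slot voxelSize edge length of a voxel (um)
#' @slot gridDim grid dimension (voxels per axis)
#' @slot voxelKey linear grid index of each occupied voxel, in walk order
#' @slot chromosome chromosome id of each occupied voxel
#' @slot bpStart first genomic coordinate (bp, 1-based within chromosome)
#'   carried by each occupied voxel
#' @slot stepDir unit lattice direction towards the next voxel of the walk
#'   (rows match \code{voxelKey}); used for sub-voxel bp interpolation
#' @slot occupancy full-grid lookup: walk index of the voxel occupying each
#'   grid cell, 0 if free
#' @slot bpPerVoxel base pairs per voxel
#' @slot genomeLength total genome length (bp)
#' @slot chromLengths chromosome lengths (bp)
#' @slot loopStarts per-chromosome genomic start coordinates of chromatin loops
#' @slot domainStarts per-chromosome start coordinates of 1-Mbp domains
#' @seealso [buildNucleusModel()]
#' @export
setClass("ChromatinModel",
  representation(voxelSize = "numeric", gridDim = "integer",
                 voxelKey = "integer", chromosome = "integer",
                 bpStart = "numeric", stepDir = "matrix",
                 occupancy = "integer", bpPerVoxel = "numeric",
                 genomeLength = "numeric", chromLengths = "numeric",
                 loopStarts = "list", domainStarts = "list"))

setValidity("ChromatinModel", function(object) {
  n <- length(object@voxelKey)
  if (length(object@chromosome) != n || length(object@bpStart) != n ||
      nrow(object@stepDir) != n)
    return("per-voxel slots must have equal length")
  if (abs(n * object@bpPerVoxel - object@genomeLength) > object@bpPerVoxel)
    return("occupied voxels x bpPerVoxel must equal genomeLength within one voxel")
  if (abs(sum(object@chromLengths) - object@genomeLength) > 1)
    return("chromosome lengths must sum to genomeLength")
  TRUE
})

#' Single-track transport record
#'
#' @slot ion the transported [IonSpec-class]
#' @slot initialEnergy starting energy (MeV/u)
#' @slot deposits data.frame of point energy depositions: columns
#'   \code{x, y, z} (um), \code{energy} (eV), \code{kind}
#'   (\code{"ion_local"} or \code{"electron_kernel"}), \code{track_id}
#' @slot path matrix with columns \code{depth} (um) and \code{energy}
#'   (MeV/u) sampled along the trajectory
#' @slot stoppedInside TRUE if the ion slowed below the transport floor
#'   before leaving the scoring sphere
#' @slot exitEnergy residual energy (MeV/u) carried out of the scoring
#'   sphere (0 for stoppers)
#' @export
setClass("TrackRecord",
  representation(ion = "IonSpec", initialEnergy = "numeric",
                 deposits = "data.frame", path = "matrix",
                 stoppedInside = "logical", exitEnergy = "numeric"))

setValidity("TrackRecord", function(object) {
  p <- object@path
  if (nrow(p) > 1) {
    if (any(diff(p[, "depth"]) < 0)) return("path depth must be non-decreasing")
    if (any(diff(p[, "energy"]) > 1e-9)) return("path energy must be non-increasing")
  }
  if (nrow(object@deposits) && any(object@deposits$energy <= 0))
    return("deposit energies must be positive")
  TRUE
})

#' Damage tallies for one irradiation experiment
#'
#' @slot counts named mean per-run counts: \code{sb}, \code{ssb}, \code{dsb},
#'   \code{dsbIsolated}, \code{dsbClusters}, \code{dsbSites},
#'   \code{multiplicity} (mean DSB per cluster), \code{microFragments}
#'   (intra-cluster pieces of <= 25 bp)
#' @slot perGyPerGbp the same quantities normalized per Gy and per Gbp
#' @slot uncertainty twice the standard error of the mean over runs (NA for a
#'   single run)
#' @slot fragments data.frame of single-track fragment counts per size bin
#' @slot dose mean dose per run (Gy)
#' @slot genomeLength genome length used for normalization (bp)
#' @slot nRuns number of runs aggregated
#' @export
setClass("DamageSummary",
  representation(counts = "numeric", perGyPerGbp = "numeric",
                 uncertainty = "numeric", fragments = "data.frame",
                 dose = "numeric", genomeLength = "numeric",
                 nRuns = "integer"))

setValidity("DamageSummary", function(object) {
  cn <- object@counts
  need <- c("sb", "ssb", "dsb", "dsbIsolated", "dsbClusters", "dsbSites")
  if (!all(need %in% names(cn))) return("missing count fields")
  tol <- 1e-6 * max(1, cn["dsb"])
  if (abs(cn[["dsbSites"]] - cn[["dsbIsolated"]] - cn[["dsbClusters"]]) > tol)
    return("sites must equal isolated DSB + DSB clusters")
  TRUE
})

#' Simulation run configuration
#'
#' @slot ion projectile species
#' @slot energy initial energy (MeV/u)
#' @slot runs number of independent runs
#' @slot seed RNG seed for the whole experiment
#' @slot geometry irradiation geometry
#' @slot genomeLength genome length (bp) of the chromatin model
#' @slot params damage-model parameter list, see [damageParams()]
#' @slot slabProfile score depth-local LET per slab
#' @slot outputDir optional directory for TSV/JSON outputs (empty: none)
#' @seealso [runConfig()], [runExperiment()]
#' @export
setClass("RunConfig",
  representation(ion = "IonSpec", energy = "numeric", runs = "integer",
                 seed = "integer", geometry = "NucleusGeometry",
                 genomeLength = "numeric", params = "list",
                 slabProfile = "logical", outputDir = "character"))

setValidity("RunConfig", function(object) {
  if (object@energy <= 0) return("energy must be positive")
  if (object@runs < 1L) return("runs must be >= 1")
  TRUE
})
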