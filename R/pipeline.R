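#' Build a run configuration
#'
#' Validates the requested species and energy against the baseline span
#' before any computation. Default run counts at full scale follow the
#' study design (hundreds to thousands of runs); reduce `runs` for
#' desk-scale work — outputs always record the actual number.
#'
#' @param ion species symbol or atomic number
#' @param energy initial energy (MeV/u)
#' @param runs number of independent runs
#' @param seed experiment seed
#' @param geometry a [NucleusGeometry-class]
#' @param genomeLength genome size (bp)
#' @param params damage parameters, see [damageParams()]
#' @param slabProfile also score depth-local slab dose/LET
#' @param outputDir directory for TSV/JSON outputs ("" = none)
#' @param baseline baseline used for validation
#' @return a [RunConfig-class]
#' @export
runConfig <- function(ion, energy, runs = 256L, seed = 1L,
                      geometry = nucleusGeometry(), genomeLength = 6.4e9,
                      params = damageParams(), slabProfile = FALSE,
                      outputDir = "", baseline = defaultBaseline()) {
  spec <- .asIon(ion)
  if (energy < .applicabilityFloor)
    stop("energy below the 0.01 MeV/u applicability floor", call. = FALSE)
  .checkSpan(baseline, energy)
  methods::new("RunConfig", ion = spec, energy = energy,
               runs = as.integer(runs), seed = as.integer(seed),
               geometry = geometry, genomeLength = genomeLength,
               params = params, slabProfile = slabProfile,
               outputDir = outputDir)
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: %s at %g MeV/u, %d runs, seed %d, genome %.3g bp\n",
              object@ion@name, object@energy, object@runs, object@seed,
              object@genomeLength))
})

.twoSem <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  2 * stats::sd(x) / sqrt(length(x))
}

#' Run a multi-run irradiation experiment
#'
#' Builds the chromatin model once, then for each run rotates the source,
#' transports the primaries, scores dose and LET (over the full nucleus for
#' crossers; over the spherical cap of height equal to the ion range for
#' stoppers), induces direct and indirect strand breaks, applies the 1%
#' SB-to-DSB conversion and classifies the damage. Reported values are
#' means over runs with twice the standard error of the mean as
#' uncertainty; a single run reports NA uncertainty.
#'
#' All randomness derives from `config@seed`; identical configurations give
#' identical results.
#'
#' @param config a [RunConfig-class]
#' @param baseline a [BaselineTable-class]
#' @param model optional pre-built [ChromatinModel-class] (must match the
#'   configured genome length)
#' @param verbose log one line per run
#' @return list with `summary` (a [DamageSummary-class]), `perRun`
#'   (data.frame of per-run tallies), `fragments` (mean per-run spectrum),
#'   `slabs` (per-slab profile or NULL), `range` (um), `stopper` (logical),
#'   `meanLet` (keV/um), `config`
#' @export
runExperiment <- function(config, baseline = defaultBaseline(),
                          model = NULL, verbose = FALSE) {
  methods::validObject(config)
  set.seed(config@seed)
  geom <- config@geometry
  ion <- config@ion
  rn <- geom@nucleusDiameter / 2
  rs <- geom@scoringDiameter / 2
  phi <- fluence(geom)

  if (is.null(model))
    model <- buildNucleusModel(geom, genomeLength = config@genomeLength)
  else if (abs(model@genomeLength - config@genomeLength) > model@bpPerVoxel)
    stop("supplied model does not match the configured genome length",
         call. = FALSE)

  rng <- computeRange(ion, config@energy, baseline, "extrapolate10")
  stopper <- rng < geom@nucleusDiameter
  refVol <- if (stopper) capVolume(geom, rng)
            else 4 / 3 * pi * rn^3

  bins <- fragmentBins()
  perRun <- vector("list", config@runs)
  fragAcc <- matrix(0, config@runs, nrow(bins))
  slabEnergy <- numeric(geom@nSlabs)
  slabStops <- numeric(0)

  for (r in seq_len(config@runs)) {
    frame <- makeRun(geom)
    tracks <- lapply(seq_len(geom@primariesPerRun), function(i)
      simulateTrack(ion, config@energy, frame$starts[i, ], frame$direction,
                    baseline, scoringRadius = rs, trackId = i))
    deposits <- data.table::rbindlist(lapply(tracks, function(t) t@deposits))
    deposits <- as.data.frame(deposits)
    doseRun <- doseFromDeposits(deposits, refVol, radius = rn)
    letRun <- letFromDoseFluence(doseRun, phi)

    direct <- depositsToDirectBreaks(deposits, model, config@params)
    indirect <- indirectBreaks(deposits, model, config@params,
                               dnaHit = attr(direct, "dnaHit"))
    breaks <- convertSbToDsb(rbind(direct, indirect),
                             config@params$p_conversion)
    s <- classifyBreaks(breaks, dose = if (doseRun > 0) doseRun else NA_real_,
                        genomeLength = config@genomeLength, bins = bins)
    frag <- s@fragments$count
    fragAcc[r, ] <- frag
    cn <- s@counts
    perRun[[r]] <- data.frame(
      run = r, dose = doseRun, let = letRun,
      sb = cn[["sb"]], ssb = cn[["ssb"]], dsb = cn[["dsb"]],
      dsbIsolated = cn[["dsbIsolated"]], dsbClusters = cn[["dsbClusters"]],
      dsbSites = cn[["dsbSites"]], multiplicity = cn[["multiplicity"]],
      microFragments = cn[["microFragments"]],
      nDirect = sum(breaks$origin == "direct"),
      nIndirect = sum(breaks$origin == "indirect"))
    if (config@slabProfile) {
      sp <- slabProfile(deposits, geom, frame$rotation, phi,
                        stopDepths = vapply(tracks, function(t)
                          if (t@stoppedInside) max(t@path[, "depth"]) else Inf,
                          numeric(1)))
      slabEnergy <- slabEnergy + sp$energy_eV
    }
    if (verbose)
      message(sprintf("run %d: dose %.4g Gy, LET %.4g keV/um, %d SB, %g DSB",
                      r, doseRun, letRun, cn[["sb"]], cn[["dsb"]]))
  }

  perRun <- do.call(rbind, perRun)
  gbp <- config@genomeLength / 1e9
  fields <- c("sb", "ssb", "dsb", "dsbIsolated", "dsbClusters", "dsbSites",
              "multiplicity", "microFragments")
  counts <- vapply(fields, function(f) mean(perRun[[f]], na.rm = TRUE),
                   numeric(1))
  unc <- vapply(fields, function(f) .twoSem(perRun[[f]][!is.na(perRun[[f]])]),
                numeric(1))
  okDose <- perRun$dose > 0
  per <- vapply(fields, function(f)
    mean(perRun[[f]][okDose] / (perRun$dose[okDose] * gbp), na.rm = TRUE),
    numeric(1))
  per["multiplicity"] <- counts[["multiplicity"]]
  fragments <- bins
  fragments$count <- colMeans(fragAcc)
  fragments$perGyPerGbp <- colMeans(fragAcc / (perRun$dose * gbp),
                                    na.rm = TRUE)
  summary <- methods::new("DamageSummary", counts = counts,
                          perGyPerGbp = per, uncertainty = unc,
                          fragments = fragments, dose = mean(perRun$dose),
                          genomeLength = config@genomeLength,
                          nRuns = config@runs)
  slabs <- NULL
  if (config@slabProfile) {
    dna <- dnaMassPerSlab(model, geom, nRotations = 50L)
    edges <- seq(0, by = geom@slabThickness, length.out = geom@nSlabs + 1L)
    vol <- .sliceVolume(geom, edges[-length(edges)], edges[-1])
    meanE <- slabEnergy / config@runs
    doseSlab <- ifelse(vol > 0,
                       meanE * .const$J_per_eV / (vol * .const$kg_per_um3), 0)
    slabs <- data.frame(depth_mid = 0.5 * (edges[-1] + edges[-length(edges)]),
                        energy_eV = meanE, dose = doseSlab,
                        let = doseSlab / (.const$gy_per_kev_um_fluence * phi),
                        dna_bp = dna)
  }

  out <- list(summary = summary, perRun = perRun, fragments = fragments,
              slabs = slabs, range = rng, stopper = stopper,
              meanLet = mean(perRun$let), config = config)
  if (nzchar(config@outputDir)) .writeExperiment(out, config)
  out
}

.writeExperiment <- function(out, config) {
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(config@outputDir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(out$perRun, "per_run.tsv")
  w(out$fragments, "fragments.tsv")
  if (!is.null(out$slabs)) w(out$slabs, "slab_profile.tsv")
  cn <- out$summary@counts
  w(data.frame(quantity = names(cn), mean = as.numeric(cn),
               two_sem = as.numeric(out$summary@uncertainty),
               per_gy_per_gbp = as.numeric(out$summary@perGyPerGbp)),
    "summary.tsv")
  meta <- list(
    package = "IonTrackDamage",
    version = as.character(utils::packageVersion("IonTrackDamage")),
    ion = config@ion@name, energy_MeV_u = config@energy,
    runs = config@runs, seed = config@seed,
    genome_length_bp = config@genomeLength,
    fluence_per_um2 = fluence(config@geometry),
    nucleus_diameter_um = config@geometry@nucleusDiameter,
    scoring_diameter_um = config@geometry@scoringDiameter,
    params = config@params,
    range_um = out$range, stopper = out$stopper)
  jsonlite::write_json(meta, file.path(config@outputDir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Generate deterministic fixtures
#'
#' Produces synthetic classifier and scorer inputs, including the three
#' worked break patterns that illustrate DSB-site scoring: 7 isolated DSB
#' (7 sites), two clusters of 2 plus 3 isolated DSB (5 sites), and a chain
#' of 7 DSB within 25 bp steps (1 site of multiplicity 7).
#'
#' @param kind one of `worked_example_isolated7`, `worked_example_2clusters`,
#'   `worked_example_chain7`, `random_breaks`, `uniform_deposits`,
#'   `bragg_deposits`
#' @param seed RNG seed (stochastic kinds)
#' @param path optional TSV output path
#' @param n number of rows for the stochastic kinds
#' @return a break or deposit data.frame (written to `path` if given)
#' @export
generateFixture <- function(kind, seed = 1L, path = NULL, n = 200L) {
  dsbPair <- function(p, chrom = 1L, track = 1L)
    data.frame(chromosome = chrom, pos = c(p, p + 2),
               strand = c("+", "-"), origin = "direct",
               track_id = as.integer(track))
  set.seed(seed)
  out <- switch(kind,
    worked_example_isolated7 =
      do.call(rbind, lapply(1e6 * (1:7), dsbPair)),
    worked_example_2clusters =
      rbind(dsbPair(1000), dsbPair(1020),
            dsbPair(201000), dsbPair(201020),
            do.call(rbind, lapply(1e6 * (5:7), dsbPair))),
    worked_example_chain7 =
      do.call(rbind, lapply(1000 + 20 * (0:6), dsbPair)),
    random_breaks =
      data.frame(chromosome = sample(1:2, n, TRUE),
                 pos = sample.int(5e4, n, TRUE),
                 strand = sample(c("+", "-"), n, TRUE),
                 origin = "direct",
                 track_id = sample(1:3, n, TRUE)),
    uniform_deposits = {
      r <- 5 * stats::runif(n)^(1 / 3)
      u <- matrix(stats::rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2))
      data.frame(x = r * u[, 1], y = r * u[, 2], z = r * u[, 3],
                 energy = stats::runif(n, 10, 100), kind = "ion_local",
                 track_id = 1L)
    },
    bragg_deposits = {
      # deposit density along +z follows the deterministic carbon
      # slowing-down curve entering at the south pole with 0.5 MeV/u,
      # so the local stopping rises to the Bragg maximum and falls off
      bt <- defaultBaseline()
      Eg <- exp(seq(log(0.5), log(0.01), length.out = 2000))
      S <- .scaledStoppingQuiet(ionSpec("C"), Eg, bt)
      d <- c(0, cumsum(-diff(Eg) * 12 * 1000 * 0.5 * (1 / S[-1] + 1 / S[-2000])))
      w <- S[-1] * diff(d)                   # energy deposited per depth step
      depth <- stats::approx(c(0, cumsum(w) / sum(w)), d,
                             xout = stats::runif(n), rule = 2)$y
      # lateral positions uniform over the 80 um^2 source disc, so slab
      # doses carry the chord-length weighting of a parallel beam
      rr <- sqrt(80 / pi) * sqrt(stats::runif(n))
      ph <- stats::runif(n, 0, 2 * pi)
      data.frame(x = rr * cos(ph), y = rr * sin(ph), z = depth - 5,
                 energy = rep(5 * 12 * 0.49 * 1e6 / n, n),
                 kind = "ion_local", track_id = 1L)
    },
    stop("unknown fixture kind: ", kind, call. = FALSE))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
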