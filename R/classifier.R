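.emptyDsb <- function() {
  data.frame(chromosome = integer(0), pos = numeric(0),
             pos1 = numeric(0), pos2 = numeric(0),
             strand1 = character(0), strand2 = character(0),
             origin = character(0), track_id = integer(0))
}

#' Merge directly adjacent strand breaks
#'
#' Breaks on the same strand at directly adjacent nucleotides (consecutive
#' bp) are merged into a single break at the run's lowest position; breaks
#' are scored individually only if at least one unbroken sugar-phosphate
#' group separates them. Idempotent.
#'
#' @param breaks break data.frame (chromosome, pos, strand, origin, track_id)
#' @return merged break data.frame, sorted by (chromosome, strand, pos)
#' @export
#' @examples
#' b <- data.frame(chromosome = 1L, pos = c(100, 101, 103),
#'                 strand = "+", origin = "direct", track_id = 1L)
#' mergeAdjacent(b)$pos  # 100 103
mergeAdjacent <- function(breaks) {
  if (nrow(breaks) == 0L) return(breaks)
  o <- order(breaks$chromosome, breaks$strand, breaks$pos)
  b <- breaks[o, , drop = FALSE]
  dup <- duplicated(data.frame(b$chromosome, b$strand, b$pos))
  b <- b[!dup, , drop = FALSE]
  newRun <- c(TRUE, !(diff(b$pos) == 1 &
                      b$chromosome[-1] == b$chromosome[-nrow(b)] &
                      b$strand[-1] == b$strand[-nrow(b)]))
  out <- b[newRun, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call double-strand breaks
#'
#' Greedy pairing of breaks on opposite strands within 10 bp: breaks are
#' scanned in ascending position; each unpaired break pairs with the
#' nearest unpaired opposite-strand break not more than 10 bp away (ties:
#' lower position first, then the plus-strand partner). Paired breaks form
#' DSB records with representative position at the floor of the pair
#' midpoint; all remaining breaks are single-strand breaks, including
#' breaks in the vicinity of a DSB.
#'
#' @param breaks break data.frame, already passed through
#'   [mergeAdjacent()] (and conversion, if used)
#' @param maxGap maximum strand-to-strand distance of a DSB pair (bp)
#' @return list with `dsb` (chromosome, pos, pos1, pos2, strand1-origin
#'   bookkeeping, track_id) and `ssb` (the unpaired breaks)
#' @export
callDsb <- function(breaks, maxGap = 10) {
  if (nrow(breaks) == 0L)
    return(list(dsb = .emptyDsb(), ssb = breaks))
  o <- order(breaks$chromosome, breaks$pos, breaks$strand != "+")
  b <- breaks[o, , drop = FALSE]
  n <- nrow(b)
  paired <- integer(n)                      # index of partner, 0 = unpaired
  chrom <- b$chromosome; pos <- b$pos; strand <- b$strand
  for (i in seq_len(n)) {
    if (paired[i] > 0L) next
    # candidate window around i on the opposite strand
    lo <- i
    while (lo > 1L && chrom[lo - 1L] == chrom[i] &&
           pos[i] - pos[lo - 1L] <= maxGap) lo <- lo - 1L
    hi <- i
    while (hi < n && chrom[hi + 1L] == chrom[i] &&
           pos[hi + 1L] - pos[i] <= maxGap) hi <- hi + 1L
    cand <- setdiff(lo:hi, i)
    cand <- cand[paired[cand] == 0L & strand[cand] != strand[i]]
    if (!length(cand)) next
    d <- abs(pos[cand] - pos[i])
    cand <- cand[d == min(d)]
    if (length(cand) > 1L) cand <- cand[order(pos[cand], strand[cand] != "+")]
    j <- cand[1L]
    paired[i] <- j; paired[j] <- i
  }
  isFirst <- paired > seq_len(n)
  i1 <- which(isFirst); i2 <- paired[i1]
  if (!length(i1))
    return(list(dsb = .emptyDsb(), ssb = b))
  dsb <- data.frame(chromosome = chrom[i1],
                    pos = floor((pos[i1] + pos[i2]) / 2),
                    pos1 = pos[i1], pos2 = pos[i2],
                    strand1 = strand[i1], strand2 = strand[i2],
                    origin = paste0(b$origin[i1], "/", b$origin[i2]),
                    track_id = pmin(b$track_id[i1], b$track_id[i2]))
  dsb <- dsb[order(dsb$chromosome, dsb$pos), , drop = FALSE]
  rownames(dsb) <- NULL
  ssb <- b[paired == 0L, , drop = FALSE]
  rownames(ssb) <- NULL
  list(dsb = dsb, ssb = ssb)
}

#' Cluster double-strand breaks
#'
#' Single-linkage chaining of DSB representative positions: consecutive DSB
#' of the same chromosome not separated by more than 25 bp join one chain.
#' Maximal chains with two or more DSB are DSB clusters; singletons are
#' isolated DSB. Each isolated DSB and each whole cluster counts as one DSB
#' site.
#'
#' @param dsb DSB data.frame from [callDsb()]
#' @param maxGap chaining threshold (bp)
#' @return data.frame with one row per site: chromosome, pos (mean of member
#'   representative positions), multiplicity, isCluster, track_id, and
#'   `microFragments` (the multiplicity - 1 internal pieces of <= 25 bp)
#' @export
clusterDsb <- function(dsb, maxGap = 25) {
  if (nrow(dsb) == 0L)
    return(data.frame(chromosome = integer(0), pos = numeric(0),
                      multiplicity = integer(0), isCluster = logical(0),
                      track_id = integer(0), microFragments = integer(0)))
  o <- order(dsb$chromosome, dsb$pos)
  d <- dsb[o, , drop = FALSE]
  newChain <- c(TRUE, !(d$chromosome[-1] == d$chromosome[-nrow(d)] &
                        diff(d$pos) <= maxGap))
  g <- cumsum(newChain)
  dt <- data.table::data.table(chromosome = d$chromosome, pos = d$pos,
                               track_id = d$track_id, g = g)
  cl <- dt[, .(chromosome = chromosome[1], pos = mean(pos),
               multiplicity = .N, track_id = min(track_id)), by = g]
  data.frame(chromosome = cl$chromosome, pos = cl$pos,
             multiplicity = cl$multiplicity,
             isCluster = cl$multiplicity >= 2L,
             track_id = cl$track_id,
             microFragments = pmax(cl$multiplicity - 1L, 0L))
}

#' Default fragment-size bins
#'
#' Single-track fragment scoring intervals corresponding to DSB-site pairs
#' within a nucleosome (60-100 bp), a chromatin fiber (0.3-3 kbp), a fiber
#' loop (10-100 kbp) and a chromatin domain or giant loop (0.3-3 Mbp), plus
#' the PFGE-detectable window (5 kbp-6 Mbp).
#'
#' @return data.frame with columns name, lower, upper (bp, inclusive)
#' @export
fragmentBins <- function() {
  data.frame(name = c("60-100 bp", "0.3-3 kbp", "10-100 kbp",
                      "0.3-3 Mbp", "PFGE 5 kbp-6 Mbp"),
             lower = c(60, 300, 1e4, 3e5, 5e3),
             upper = c(100, 3000, 1e5, 3e6, 6e6))
}

#' Single-track DNA fragment-size spectrum
#'
#' Fragment lengths are the gaps between consecutive DSB sites of the same
#' track on the same chromosome (a pair of DSB sites cuts out one
#' fragment); terminal chromosome pieces are not counted. Counts are
#' accumulated into the configured (possibly overlapping) size bins.
#' Intra-cluster micro-fragments (<= 25 bp) never enter these bins; they are
#' tallied by [clusterDsb()].
#'
#' @param sites site data.frame from [clusterDsb()] (needs chromosome, pos,
#'   track_id)
#' @param bins data.frame as in [fragmentBins()]
#' @return `bins` with a `count` column added; attribute `lengths` carries
#'   the individual fragment lengths
#' @export
fragmentSpectrum <- function(sites, bins = fragmentBins()) {
  lens <- numeric(0)
  if (nrow(sites) > 0L) {
    dt <- data.table::data.table(chromosome = sites$chromosome,
                                 pos = sites$pos,
                                 track_id = sites$track_id)
    data.table::setorder(dt, track_id, chromosome, pos)
    gaps <- dt[, if (.N > 1L) .(len = diff(pos)) else NULL,
               by = .(track_id, chromosome)]
    if (nrow(gaps)) lens <- gaps$len
  }
  bins$count <- vapply(seq_len(nrow(bins)), function(i)
    sum(lens >= bins$lower[i] & lens <= bins$upper[i]), numeric(1))
  attr(bins, "lengths") <- lens
  bins
}

#' Summarize classified damage
#'
#' Collects the invariant-checked tallies of one exposure: SB (all breaks
#' after adjacent-merging), SSB (breaks not consumed in DSB), DSB, isolated
#' DSB, DSB clusters, DSB sites (isolated + clusters), mean DSB multiplicity
#' per cluster, micro-fragments, and per-Gy-per-Gbp normalizations.
#'
#' @param sites site data.frame from [clusterDsb()]
#' @param ssb SSB data.frame from [callDsb()]
#' @param dose absorbed dose (Gy); required positive for per-Gy yields
#' @param genomeLength genome length (bp)
#' @param nRuns number of runs the tallies average over
#' @param uncertainty optional named vector of 2 x SEM values
#' @param fragments optional fragment spectrum from [fragmentSpectrum()]
#' @return a [DamageSummary-class]
#' @export
summarizeDamage <- function(sites, ssb, dose = NA_real_,
                            genomeLength = 6.4e9, nRuns = 1L,
                            uncertainty = NULL, fragments = NULL) {
  nDsb <- sum(sites$multiplicity)
  nIso <- sum(!sites$isCluster)
  nClu <- sum(sites$isCluster)
  counts <- c(sb = as.numeric(nrow(ssb) + 2 * nDsb),
              ssb = as.numeric(nrow(ssb)),
              dsb = as.numeric(nDsb),
              dsbIsolated = as.numeric(nIso),
              dsbClusters = as.numeric(nClu),
              dsbSites = as.numeric(nIso + nClu),
              multiplicity = if (nClu > 0)
                sum(sites$multiplicity[sites$isCluster]) / nClu else NA_real_,
              microFragments = as.numeric(sum(sites$microFragments)))
  per <- rep(NA_real_, length(counts)); names(per) <- names(counts)
  if (!is.na(dose)) {
    if (dose <= 0) stop("per-Gy normalization requires positive dose",
                        call. = FALSE)
    gbp <- genomeLength / 1e9
    per <- counts / (dose * gbp)
    per["multiplicity"] <- counts[["multiplicity"]]
  }
  if (is.null(fragments)) {
    fragments <- fragmentBins(); fragments$count <- 0
  }
  if (is.null(uncertainty)) {
    uncertainty <- rep(NA_real_, length(counts))
    names(uncertainty) <- names(counts)
  }
  methods::new("DamageSummary", counts = counts, perGyPerGbp = per,
               uncertainty = uncertainty, fragments = fragments,
               dose = dose, genomeLength = genomeLength,
               nRuns = as.integer(nRuns))
}

#' Classify a break list end to end
#'
#' Runs adjacent-break merging, DSB calling, cluster/site scoring and
#' fragment scoring on a break list (for example one read with
#' [readBreaks()]), returning a [DamageSummary-class]. SB to DSB conversion
#' is not applied here; apply [convertSbToDsb()] beforehand if the list
#' holds raw breaks.
#'
#' @param breaks break data.frame
#' @param dose optional dose (Gy) for per-Gy yields
#' @param genomeLength genome length (bp)
#' @param bins fragment bins, see [fragmentBins()]
#' @return a [DamageSummary-class]; the intermediate tables are attached as
#'   attributes `dsb`, `sites`, `ssb`
#' @export
classifyBreaks <- function(breaks, dose = NA_real_, genomeLength = 6.4e9,
                           bins = fragmentBins()) {
  m <- mergeAdjacent(breaks)
  cd <- callDsb(m)
  sites <- clusterDsb(cd$dsb)
  frags <- fragmentSpectrum(sites, bins)
  s <- summarizeDamage(sites, cd$ssb, dose, genomeLength, fragments = frags)
  attr(s, "dsb") <- cd$dsb
  attr(s, "sites") <- sites
  attr(s, "ssb") <- cd$ssb
  s
}

#' Read and write break lists
#'
#' TSV exchange format with header columns chromosome, pos, strand, origin,
#' track_id.
#'
#' @param path file path
#' @param breaks break data.frame
#' @return `readBreaks`: break data.frame; `writeBreaks`: `path`, invisibly
#' @export
readBreaks <- function(path) {
  b <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chromosome", "pos", "strand", "origin", "track_id")
  if (!all(need %in% names(b)))
    stop("break list must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(b$strand %in% c("+", "-"))) stop("strand must be '+' or '-'",
                                            call. = FALSE)
  if (any(b$pos < 1)) stop("positions must be >= 1", call. = FALSE)
  b[, need]
}

#' @rdname readBreaks
#' @export
writeBreaks <- function(breaks, path) {
  utils::write.table(breaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

setMethod("show", "DamageSummary", function(object) {
  cn <- object@counts
  cat(sprintf("DamageSummary (%d run%s):\n", object@nRuns,
              if (object@nRuns == 1L) "" else "s"))
  cat(sprintf("  SB %.4g | SSB %.4g | DSB %.4g (isolated %.4g, in clusters %.4g)\n",
              cn[["sb"]], cn[["ssb"]], cn[["dsb"]], cn[["dsbIsolated"]],
              cn[["dsb"]] - cn[["dsbIsolated"]]))
  cat(sprintf("  DSB clusters %.4g | DSB sites %.4g | multiplicity %.3g\n",
              cn[["dsbClusters"]], cn[["dsbSites"]], cn[["multiplicity"]]))
  if (!is.na(object@dose))
    cat(sprintf("  dose %.4g Gy; DSB yield %.4g /Gy/Gbp\n", object@dose,
                object@perGyPerGbp[["dsb"]]))
})
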