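# Independent oracles, written from first principles and kept free of the
# package's implementation internals.

# Textbook Bethe formula for protons in water, I = 75 eV, unit density.
oracleBethe <- function(E_MeV) {
  me <- 0.510998950      # MeV
  mp <- 938.2720882      # MeV
  I  <- 75e-6            # MeV
  gamma <- E_MeV / mp + 1
  beta2 <- 1 - gamma^-2
  ratio <- me / mp
  Tmax <- 2 * me * beta2 * gamma^2 / (1 + 2 * gamma * ratio + ratio^2)
  # 0.307075 MeV mol^-1 cm^2 * Z/A(water) = 0.1704
  dEdx <- 0.307075 * 0.55509 / beta2 *
    (log(sqrt(2 * me * beta2 * gamma^2 * Tmax) / I) - beta2)  # MeV cm^2/g
  dEdx / 10                                                   # keV/um
}

# Brute-force run-length merging of same-strand breaks at adjacent bp.
oracleMergeAdjacent <- function(breaks) {
  out <- NULL
  for (ch in unique(breaks$chromosome)) for (st in c("+", "-")) {
    p <- sort(unique(breaks$pos[breaks$chromosome == ch &
                                breaks$strand == st]))
    if (!length(p)) next
    keep <- p[1]
    for (i in seq_along(p)[-1]) if (p[i] - p[i - 1] > 1) keep <- c(keep, p[i])
    out <- rbind(out, data.frame(chromosome = ch, pos = keep, strand = st))
  }
  out[order(out$chromosome, out$strand, out$pos), ]
}

# Brute-force single-linkage chaining of sorted positions with gap <= maxGap.
oracleChains <- function(pos, maxGap = 25) {
  p <- sort(pos)
  sizes <- integer(0); cur <- 1L
  for (i in seq_along(p)[-1]) {
    if (p[i] - p[i - 1] <= maxGap) cur <- cur + 1L
    else { sizes <- c(sizes, cur); cur <- 1L }
  }
  c(sizes, cur)
}

# Brute-force fragment lengths: consecutive gaps per (track, chromosome).
oracleFragments <- function(sites) {
  lens <- numeric(0)
  for (tr in unique(sites$track_id)) for (ch in unique(sites$chromosome)) {
    p <- sort(sites$pos[sites$track_id == tr & sites$chromosome == ch])
    if (length(p) > 1) lens <- c(lens, diff(p))
  }
  lens
}

# Maximum-cardinality matching of opposite-strand breaks within maxGap.
oracleMaxMatching <- function(breaks, maxGap = 10) {
  plus <- which(breaks$strand == "+")
  minus <- which(breaks$strand == "-")
  if (!length(plus) || !length(minus)) return(0L)
  edges <- NULL
  for (i in plus) for (j in minus)
    if (breaks$chromosome[i] == breaks$chromosome[j] &&
        abs(breaks$pos[i] - breaks$pos[j]) <= maxGap)
      edges <- rbind(edges, c(i, j))
  if (is.null(edges)) return(0L)
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  igraph::V(g)$type <- igraph::V(g)$name %in% as.character(plus)
  igraph::max_bipartite_match(g)$matching_size
}

randomBreakSet <- function(n, span = 2000, chromosomes = 1L) {
  data.frame(chromosome = sample(seq_len(chromosomes), n, TRUE),
             pos = sample.int(span, n, TRUE),
             strand = sample(c("+", "-"), n, TRUE),
             origin = "direct",
             track_id = sample(1:3, n, TRUE))
}

# Unit conversion done by hand: eV -> J, um^3 of water -> kg.
oracleDose <- function(eV, volume_um3) {
  (eV * 1.602176634e-19) / (volume_um3 * 1e-15)
}

# Small reusable geometry/model for damage tests (built once per session).
testModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(424242)
      cache <<- buildNucleusModel(nucleusGeometry(), genomeLength = 2e8)
    }
    cache
  }
})
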