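# Shared fixtures. Everything is generated in code under fixed seeds.

# O(N^2) discrete Fourier transform, the independent oracle for the FFT path.
bruteDFT <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * k / n)), complex(1))
}

# A small but complete protocol dataset (all groups present), cached.
.fixture_cache <- new.env(parent = emptyenv())

smallDataset <- function() {
  if (is.null(.fixture_cache$small)) {
    spec <- ProtocolSpec(incisionsPerMode = 2L, packetsPerIncision = 3L,
                         airPacketsPerState = 10L, seed = 42L)
    .fixture_cache$small <- simulateProtocolDataset(spec)
  }
  .fixture_cache$small
}

smallFeatures <- function() {
  if (is.null(.fixture_cache$smallFx))
    .fixture_cache$smallFx <- extractFeatures(smallDataset())
  .fixture_cache$smallFx
}

# The full scaled-down protocol experiment (seed 1): 12 incisions/mode,
# 10 packets/incision, 120 air packets/state/pool. Computed once per test run.
acceptanceSummary <- function() {
  if (is.null(.fixture_cache$acc)) {
    spec <- ProtocolSpec(seed = 1L)
    ps <- simulateProtocolDataset(spec)
    res <- runExperiment(ps, seed = 1L)
    .fixture_cache$acc <- summarizeResults(res)
  }
  .fixture_cache$acc
}

# Hand-built PacketFeatures around an explicit peak-feature table; the banded
# spectra default to noise so the pc5 path stays well-defined.
featuresFromTable <- function(tab, bands = NULL, nBands = 20L) {
  if (is.null(bands)) {
    bands <- matrix(stats::rnorm(nrow(tab) * nBands, sd = 1e-3),
                    nrow(tab), nBands)
  }
  for (col in c("tissue", "pool"))
    if (is.null(tab[[col]])) tab[[col]] <- NA_character_
  esusense:::makePacketFeatures(tab, bands,
                                seq_len(ncol(bands)) * 100 - 50)
}

# Two well-separated Gaussian blobs in peak-feature space.
blobFeatures <- function(n = 200L, delta = 10, sigma = 1, seed = 7L) {
  set.seed(seed)
  tab <- data.frame(
    packet_id = sprintf("blob%04d", seq_len(2L * n)),
    device = "dev_X", power_w = 30,
    state = rep(c(0L, 1L), each = n),
    max_intensity = c(rnorm(n, 0, sigma), rnorm(n, delta * sigma, sigma)),
    peak_freq_hz = c(rnorm(n, 0, sigma), rnorm(n, delta * sigma, sigma)),
    stringsAsFactors = FALSE)
  featuresFromTable(tab)
}
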