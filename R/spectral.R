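# Spectral feature pipeline: FFT magnitude spectrum, equal-width band
# downsampling, peak features, and per-fold PCA.

#' Magnitude spectrum of one packet
#'
#' Magnitude of the discrete Fourier transform of a packet's voltage samples,
#' with no window function and no detrending; bin k (0-based) is centered at
#' `k * samplingRate / N`. Only the non-negative frequencies are returned
#' (`floor(N/2) + 1` bins, 1951 for the default 3900-sample packet).
#'
#' @param x numeric vector of packet samples (length must match `config`).
#' @param config an [AcquisitionConfig].
#' @return a data.frame with columns `freq_hz` and `magnitude`.
#' @examples
#' cfg <- AcquisitionConfig()
#' sp <- computeSpectrum(simulatePacket(defaultProfiles()[[1]], cfg,
#'                                      "cut_air", 30, seed = 1), cfg)
#' sp$freq_hz[which.max(sp$magnitude)]  # 6000 Hz carrier
#' @export
computeSpectrum <- function(x, config = AcquisitionConfig()) {
  n <- samplesPerPacket(config)
  if (length(x) != n)
    stop("packet has ", length(x), " samples but config expects ", n)
  nb <- n %/% 2L + 1L
  mag <- Mod(stats::fft(as.numeric(x)))[seq_len(nb)]
  data.frame(freq_hz = (seq_len(nb) - 1L) * samplingRateHz(config) / n,
             magnitude = mag)
}

# magnitude spectra for all packets of a PacketSet (bins x packets), chunked
# to bound the complex workspace.
packetSpectra <- function(pset, chunk = 512L) {
  n <- nrow(pset)
  nb <- n %/% 2L + 1L
  out <- matrix(0, nb, ncol(pset))
  i <- 1L
  while (i <= ncol(pset)) {
    j <- min(i + chunk - 1L, ncol(pset))
    out[, i:j] <- Mod(stats::mvfft(packetSamples(pset)[, i:j, drop = FALSE]))[seq_len(nb), , drop = FALSE]
    i <- j + 1L
  }
  out
}

# Band membership of each spectrum bin: equal-width half-open intervals over
# [0, Nyquist], last interval closed so the Nyquist bin belongs to band
# nBands - 1 (0-based).
bandIndex <- function(freqs, nyquist, nBands) {
  idx <- floor(freqs / (nyquist / nBands))
  pmin(as.integer(idx), nBands - 1L) + 1L
}

#' Downsample a spectrum to equal-width frequency bands
#'
#' Partitions `[0, Nyquist]` into `nBands` equal-width intervals (half-open,
#' the last closed) and averages the member-bin magnitudes of each; the band
#' center is the interval midpoint. With the 1951-bin default spectrum and
#' 200 bands every band aggregates 9 or 10 bins; the DC bin is kept inside
#' band 1. The mean (rather than sum) keeps band values comparable despite
#' the unequal member counts.
#'
#' @param spectrum a data.frame as returned by [computeSpectrum()].
#' @param nBands number of bands (default 200; must not exceed the number of
#'   spectrum bins).
#' @return a data.frame with columns `band_center_hz` and `magnitude`.
#' @examples
#' cfg <- AcquisitionConfig()
#' sp <- computeSpectrum(rnorm(3900), cfg)
#' nrow(bandDownsample(sp))  # 200
#' @export
bandDownsample <- function(spectrum, nBands = 200L) {
  nBands <- as.integer(nBands)
  nb <- nrow(spectrum)
  if (nBands < 1L || nBands > nb)
    stop("nBands must be between 1 and the number of spectrum bins (", nb, ")")
  nyquist <- spectrum$freq_hz[nb]
  idx <- bandIndex(spectrum$freq_hz, nyquist, nBands)
  mag <- as.numeric(tapply(spectrum$magnitude, factor(idx, levels = seq_len(nBands)), mean))
  width <- nyquist / nBands
  data.frame(band_center_hz = (seq_len(nBands) - 0.5) * width, magnitude = mag)
}

# banded spectra for a whole magnitude matrix (bins x packets) -> bands x packets
bandMatrix <- function(mag, freqs, nBands) {
  idx <- bandIndex(freqs, freqs[length(freqs)], nBands)
  counts <- tabulate(idx, nbins = nBands)
  rowsum(mag, idx, reorder = TRUE) / counts
}

#' Peak features of a banded spectrum
#'
#' The classifier's 2-D feature pair: the maximal band magnitude and the
#' center frequency of the band attaining it. Ties are broken toward the
#' lowest frequency.
#'
#' @param banded a data.frame as returned by [bandDownsample()].
#' @return a named list with `max_intensity` and `peak_freq_hz`.
#' @examples
#' b <- data.frame(band_center_hz = c(100, 300, 500), magnitude = c(0, 5, 0))
#' extractPeakFeatures(b)
#' @export
extractPeakFeatures <- function(banded) {
  k <- which.max(banded$magnitude)  # which.max takes the first maximum
  list(max_intensity = banded$magnitude[k],
       peak_freq_hz = banded$band_center_hz[k])
}

#' Spectral features for every packet of a PacketSet
#'
#' Runs the full per-packet feature pipeline (FFT magnitude spectrum,
#' `nBands`-band downsampling, peak extraction) over a [PacketSet] and keeps
#' the banded spectra so principal components can later be fitted per
#' cross-validation fold. The result is the input to the classifier and
#' evaluation modules.
#'
#' @param pset a [PacketSet].
#' @param nBands number of frequency bands (default 200).
#' @return a `PacketFeatures` object: `featureTable(x)` is a data.frame of
#'   packet metadata plus `max_intensity` and `peak_freq_hz`;
#'   `bandedSpectra(x)` is the packets x bands matrix.
#' @examples
#' spec <- ProtocolSpec(incisionsPerMode = 1, packetsPerIncision = 2,
#'                      airPacketsPerState = 2, seed = 1)
#' fx <- extractFeatures(simulateProtocolDataset(spec))
#' head(featureTable(fx))
#' @aliases PacketFeatures-class featureTable bandedSpectra
#' @export
extractFeatures <- function(pset, nBands = 200L) {
  stopifnot(is(pset, "PacketSet"))
  cfg <- acquisitionConfig(pset)
  n <- samplesPerPacket(cfg)
  nb <- n %/% 2L + 1L
  freqs <- (seq_len(nb) - 1L) * samplingRateHz(cfg) / n
  mag <- packetSpectra(pset)
  bands <- bandMatrix(mag, freqs, nBands)           # nBands x packets
  width <- freqs[nb] / nBands
  centers <- (seq_len(nBands) - 0.5) * width
  peakIdx <- apply(bands, 2L, which.max)
  tab <- as.data.frame(packetInfo(pset))
  tab$max_intensity <- bands[cbind(peakIdx, seq_len(ncol(bands)))]
  tab$peak_freq_hz <- centers[peakIdx]
  rownames(tab) <- NULL
  new("PacketFeatures", table = tab, bands = t(bands),
      bandCenters = centers)
}

setClass("PacketFeatures",
  representation(table = "data.frame", bands = "matrix",
                 bandCenters = "numeric"))

setValidity("PacketFeatures", function(object) {
  if (nrow(object@table) != nrow(object@bands))
    return("feature table and banded-spectrum matrix disagree on packet count")
  if (ncol(object@bands) != length(object@bandCenters))
    return("band count and band centers disagree")
  need <- c("packet_id", "device", "power_w", "state", "tissue",
            "max_intensity", "peak_freq_hz")
  miss <- setdiff(need, colnames(object@table))
  if (length(miss))
    return(paste("missing feature column(s):", paste(miss, collapse = ", ")))
  TRUE
})

#' @rdname extractFeatures
#' @param x,object a `PacketFeatures` object.
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' @rdname extractFeatures
#' @export
setMethod("featureTable", "PacketFeatures", function(x) x@table)

#' @rdname extractFeatures
#' @export
setGeneric("bandedSpectra", function(x) standardGeneric("bandedSpectra"))

#' @rdname extractFeatures
#' @export
setMethod("bandedSpectra", "PacketFeatures", function(x) x@bands)

setMethod("show", "PacketFeatures", function(object) {
  cat("PacketFeatures:", nrow(object@table), "packets,",
      ncol(object@bands), "frequency bands\n")
})

# assemble a PacketFeatures from parts (also used by test fixtures)
makePacketFeatures <- function(table, bands, bandCenters) {
  new("PacketFeatures", table = table, bands = as.matrix(bands),
      bandCenters = bandCenters)
}

# subset a PacketFeatures by row index
featureSubset <- function(fx, idx) {
  new("PacketFeatures", table = fx@table[idx, , drop = FALSE],
      bands = fx@bands[idx, , drop = FALSE], bandCenters = fx@bandCenters)
}

#' Principal component model of banded spectra
#'
#' Fits a PCA on the banded spectra of the *training* packets of one fold:
#' mean-centering only (no variance scaling), components are the leading
#' eigenvectors of the sample covariance. The model is frozen after fitting;
#' [applyPCA()] projects new spectra without updating it, which is what keeps
#' validation data out of the fit.
#'
#' @param bands numeric matrix of banded spectra, packets x bands.
#' @param nComponents number of components to keep (default 5).
#' @return a `PCAModel` with slots `center`, `rotation` (bands x components,
#'   orthonormal) and `explainedVariance` (non-increasing).
#' @examples
#' m <- fitPCA(matrix(rnorm(200 * 20), 20), nComponents = 3)
#' dim(applyPCA(m, matrix(rnorm(200 * 4), 4)))
#' @aliases PCAModel-class applyPCA
#' @export
fitPCA <- function(bands, nComponents = 5L) {
  bands <- as.matrix(bands)
  nComponents <- as.integer(nComponents)
  if (nrow(bands) <= nComponents)
    stop("need more than ", nComponents, " training rows to fit ",
         nComponents, " components (got ", nrow(bands), ")")
  ctr <- colMeans(bands)
  xc <- sweep(bands, 2L, ctr)
  sv <- svd(xc, nu = 0L, nv = nComponents)
  new("PCAModel", center = ctr,
      rotation = sv$v,
      explainedVariance = sv$d[seq_len(nComponents)]^2 / (nrow(bands) - 1L))
}

setClass("PCAModel",
  representation(center = "numeric", rotation = "matrix",
                 explainedVariance = "numeric"))

setValidity("PCAModel", function(object) {
  if (nrow(object@rotation) != length(object@center))
    return("rotation and center disagree on dimension")
  if (ncol(object@rotation) != length(object@explainedVariance))
    return("component count and explainedVariance disagree")
  g <- crossprod(object@rotation)
  if (max(abs(g - diag(ncol(g)))) > 1e-8)
    return("components must be orthonormal")
  ev <- object@explainedVariance
  if (any(ev < 0) || is.unsorted(rev(ev)))
    return("explainedVariance must be non-negative and non-increasing")
  TRUE
})

#' @rdname fitPCA
#' @param model a `PCAModel`.
#' @param newBands matrix (packets x bands) or vector of banded magnitudes.
#' @export
applyPCA <- function(model, newBands) {
  stopifnot(is(model, "PCAModel"))
  if (is.null(dim(newBands))) newBands <- matrix(newBands, nrow = 1L)
  if (ncol(newBands) != length(model@center))
    stop("input has ", ncol(newBands), " bands but the model expects ",
         length(model@center))
  scores <- sweep(as.matrix(newBands), 2L, model@center) %*% model@rotation
  colnames(scores) <- paste0("pc", seq_len(ncol(scores)))
  scores
}

setMethod("show", "PCAModel", function(object) {
  ev <- object@explainedVariance
  share <- if (sum(ev) > 0) ev / sum(ev) else ev
  cat("PCAModel:", length(object@center), "bands ->", ncol(object@rotation),
      "components; variance share",
      paste(sprintf("%.3f", share), collapse = " "), "\n")
})
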