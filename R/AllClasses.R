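#' Acquisition configuration
#'
#' Describes how the current sensor is sampled: `samplesPerPacket` voltage
#' samples are delivered in one packet every `1/packetRateHz` seconds, so the
#' effective sampling rate is `samplesPerPacket * packetRateHz`. The defaults
#' (3900 samples at 20 packets/s) give the 78 kHz effective rate of the
#' oscilloscope set-up the package models.
#'
#' @param samplesPerPacket number of voltage samples per packet.
#' @param packetRateHz packets per second.
#' @return an `AcquisitionConfig` object.
#' @examples
#' cfg <- AcquisitionConfig()
#' samplingRateHz(cfg)  # 78000
#' @aliases AcquisitionConfig-class
#' @export AcquisitionConfig
#' @exportClass AcquisitionConfig
AcquisitionConfig <- setClass("AcquisitionConfig",
  slots = c(samplesPerPacket = "integer", packetRateHz = "numeric"))

setValidity("AcquisitionConfig", function(object) {
  if (length(object@samplesPerPacket) != 1L || object@samplesPerPacket < 2L)
    return("samplesPerPacket must be a single integer >= 2")
  if (length(object@packetRateHz) != 1L || object@packetRateHz <= 0)
    return("packetRateHz must be a single positive number")
  TRUE
})

#' @rdname AcquisitionConfig
#' @usage NULL
setMethod("initialize", "AcquisitionConfig",
  function(.Object, samplesPerPacket = 3900L, packetRateHz = 20, ...) {
    .Object <- callNextMethod(.Object,
      samplesPerPacket = as.integer(samplesPerPacket),
      packetRateHz = as.numeric(packetRateHz), ...)
    validObject(.Object)
    .Object
  })

#' @rdname AcquisitionConfig
#' @param object,x an `AcquisitionConfig`.
#' @export
setGeneric("samplingRateHz", function(x) standardGeneric("samplingRateHz"))

#' @rdname AcquisitionConfig
#' @export
setMethod("samplingRateHz", "AcquisitionConfig", function(x) {
  x@samplesPerPacket * x@packetRateHz
})

#' @rdname AcquisitionConfig
#' @export
setGeneric("samplesPerPacket", function(x) standardGeneric("samplesPerPacket"))

#' @rdname AcquisitionConfig
#' @export
setMethod("samplesPerPacket", "AcquisitionConfig", function(x) x@samplesPerPacket)

#' @rdname AcquisitionConfig
#' @export
setGeneric("packetRateHz", function(x) standardGeneric("packetRateHz"))

#' @rdname AcquisitionConfig
#' @export
setMethod("packetRateHz", "AcquisitionConfig", function(x) x@packetRateHz)

setMethod("show", "AcquisitionConfig", function(object) {
  cat("AcquisitionConfig:", object@samplesPerPacket, "samples/packet at",
      object@packetRateHz, "packets/s =>", samplingRateHz(object), "Hz\n")
})

#' Parametric waveform profile of one electrosurgical generator
#'
#' A `DeviceProfile` describes the current waveform one ESU induces in the
#' live-electrode sensor for each activated state: a continuous sinusoid at
#' `cutCarrierHz` in cut mode, and a burst-gated sinusoid at `coagCarrierHz`
#' (duty cycle `coagDuty`, burst repetition `coagBurstRateHz`) in coagulate
#' mode. Tissue contact multiplies the amplitude by the mode's contact gain
#' and adds a second-harmonic component scaled by `contactHarmonicGain`.
#' `cutContactGain < coagContactGain` is enforced: the amplitude step from
#' cut-in-air to cut-on-tissue is the smallest contrast in the whole state
#' geometry, which makes that pair the hardest to classify.
#'
#' All constants are package-defined surrogates for real generators (see
#' [defaultProfiles()]); real ESU fundamentals (~400 kHz) lie far above the
#' 39 kHz Nyquist limit of the modeled digitizer, so carriers are placed
#' below it.
#'
#' @param deviceId short device identifier.
#' @param cutCarrierHz,coagCarrierHz carrier frequencies (Hz), below Nyquist.
#' @param baseAmplitude sinusoid amplitude (V) at the 30 W reference power.
#' @param coagBurstRateHz burst repetition rate (Hz) in coagulate mode.
#' @param coagDuty fraction of each burst period the carrier is on, in (0,1).
#' @param cutContactGain,coagContactGain amplitude multipliers (>1) applied on
#'   tissue contact in cut / coagulate mode; cut must be the smaller.
#' @param contactHarmonicGain scale (>=0) of the tissue-dependent
#'   second-harmonic component added on contact.
#' @param noiseSigma standard deviation (V) of the additive Gaussian sensor
#'   noise.
#' @return a `DeviceProfile` object.
#' @examples
#' defaultProfiles()[[1]]
#' @aliases DeviceProfile-class
#' @export DeviceProfile
#' @exportClass DeviceProfile
DeviceProfile <- setClass("DeviceProfile",
  slots = c(deviceId = "character",
            cutCarrierHz = "numeric", coagCarrierHz = "numeric",
            baseAmplitude = "numeric", coagBurstRateHz = "numeric",
            coagDuty = "numeric",
            cutContactGain = "numeric", coagContactGain = "numeric",
            contactHarmonicGain = "numeric", noiseSigma = "numeric"))

setValidity("DeviceProfile", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (length(object@deviceId) != 1L || !nzchar(object@deviceId))
    msg <- c(msg, "deviceId must be a non-empty string")
  for (s in c("cutCarrierHz", "coagCarrierHz", "baseAmplitude",
              "coagBurstRateHz", "noiseSigma")) {
    v <- slot(object, s)
    if (!one(v) || v < 0) msg <- c(msg, paste(s, "must be a single non-negative number"))
  }
  if (!one(object@coagDuty) || object@coagDuty <= 0 || object@coagDuty >= 1)
    msg <- c(msg, "coagDuty must lie strictly in (0,1)")
  if (!one(object@cutContactGain) || object@cutContactGain <= 1)
    msg <- c(msg, "cutContactGain must be > 1")
  if (!one(object@coagContactGain) || object@coagContactGain <= 1)
    msg <- c(msg, "coagContactGain must be > 1")
  if (one(object@cutContactGain) && one(object@coagContactGain) &&
      !(object@cutContactGain < object@coagContactGain))
    msg <- c(msg, "cutContactGain must be smaller than coagContactGain")
  if (!one(object@contactHarmonicGain) || object@contactHarmonicGain < 0)
    msg <- c(msg, "contactHarmonicGain must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname DeviceProfile
#' @param x a `DeviceProfile`.
#' @export
setGeneric("deviceId", function(x) standardGeneric("deviceId"))

#' @rdname DeviceProfile
#' @export
setMethod("deviceId", "DeviceProfile", function(x) x@deviceId)

setMethod("show", "DeviceProfile", function(object) {
  cat("DeviceProfile '", object@deviceId, "': cut ", object@cutCarrierHz,
      " Hz, coag ", object@coagCarrierHz, " Hz (burst ", object@coagBurstRateHz,
      " Hz, duty ", object@coagDuty, "), amplitude ", object@baseAmplitude,
      " V, contact gains ", object@cutContactGain, "/", object@coagContactGain,
      ", noise sd ", object@noiseSigma, " V\n", sep = "")
})

#' Simulation protocol specification
#'
#' Describes one full bench protocol: every device is run at every power with
#' every tissue (the default two devices, three powers and three tissues give
#' the 18 tissue set-ups), performing `incisionsPerMode` incisions per mode in
#' each set-up, each incision `packetsPerIncision` packets (10 packets = 0.5 s)
#' long. Off/air states do not depend on the tissue sample, so off, cut-air
#' and coag-air packets are generated per device and power only, as two
#' disjoint pools ("train" and "validation") of `airPacketsPerState` packets
#' each, with independent sub-seeds; grouped cross-validation folds can then
#' keep air packets disjoint between roles.
#'
#' @param devices list of [DeviceProfile] objects.
#' @param powersW generator power settings in watts.
#' @param tissues tissue specimen names.
#' @param incisionsPerMode incisions per mode per set-up.
#' @param packetsPerIncision packets per incision (20 packets/s).
#' @param airPacketsPerState packets per off/air state in each pool.
#' @param seed top-level integer seed; all sub-seeds derive from it.
#' @return a `ProtocolSpec` object.
#' @examples
#' ProtocolSpec(seed = 1)
#' @aliases ProtocolSpec-class
#' @export ProtocolSpec
#' @exportClass ProtocolSpec
ProtocolSpec <- setClass("ProtocolSpec",
  slots = c(devices = "list", powersW = "numeric", tissues = "character",
            incisionsPerMode = "integer", packetsPerIncision = "integer",
            airPacketsPerState = "integer", seed = "integer"))

setValidity("ProtocolSpec", function(object) {
  msg <- character()
  if (!length(object@devices) ||
      !all(vapply(object@devices, is, logical(1), "DeviceProfile")))
    msg <- c(msg, "devices must be a non-empty list of DeviceProfile objects")
  ids <- vapply(object@devices, deviceId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "device ids must be unique")
  if (!length(object@powersW) || any(object@powersW <= 0))
    msg <- c(msg, "powersW must be positive")
  if (!length(object@tissues) || anyDuplicated(object@tissues))
    msg <- c(msg, "tissues must be non-empty and unique")
  for (s in c("incisionsPerMode", "packetsPerIncision", "airPacketsPerState")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 1L)
      msg <- c(msg, paste(s, "must be a single positive integer"))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ProtocolSpec
#' @usage NULL
setMethod("initialize", "ProtocolSpec",
  function(.Object, devices = defaultProfiles(), powersW = c(30, 35, 40),
           tissues = c("chicken", "porcine", "bovine"),
           incisionsPerMode = 12L, packetsPerIncision = 10L,
           airPacketsPerState = 120L, seed = 1L, ...) {
    .Object <- callNextMethod(.Object, devices = devices,
      powersW = as.numeric(powersW), tissues = as.character(tissues),
      incisionsPerMode = as.integer(incisionsPerMode),
      packetsPerIncision = as.integer(packetsPerIncision),
      airPacketsPerState = as.integer(airPacketsPerState),
      seed = as.integer(seed), ...)
    validObject(.Object)
    .Object
  })

setMethod("show", "ProtocolSpec", function(object) {
  cat("ProtocolSpec:", length(object@devices), "devices x",
      length(object@powersW), "powers x", length(object@tissues), "tissues (",
      length(object@devices) * length(object@powersW) * length(object@tissues),
      "set-ups);", object@incisionsPerMode, "incisions/mode x",
      object@packetsPerIncision, "packets;", object@airPacketsPerState,
      "air packets/state/pool; seed", object@seed, "\n")
})

#' Container for packet streams
#'
#' `PacketSet` extends [SummarizedExperiment::SummarizedExperiment]: the
#' `"samples"` assay holds one packet per column (3900 voltage samples per
#' 50 ms window by default) and `colData` carries the per-packet metadata
#' (`packet_id`, `timestamp_s`, `device`, `power_w`, `state`, `tissue`,
#' `channel`, `pool`). The [AcquisitionConfig] and provenance live in
#' `metadata()`. Tissue must be `NA` for off/air packets, and state codes may
#' be `NA` only in prediction-mode streams.
#'
#' @param samples numeric matrix, one packet per column.
#' @param info data.frame or DataFrame of per-packet metadata.
#' @param config an [AcquisitionConfig].
#' @param provenance free-form provenance record (e.g. a [ProtocolSpec]).
#' @return a `PacketSet`.
#' @seealso [simulateProtocolDataset()], [readPackets()]
#' @aliases PacketSet-class
#' @export PacketSet
#' @exportClass PacketSet
PacketSet <- function(samples, info, config = AcquisitionConfig(),
                      provenance = "constructed in memory") {
  samples <- as.matrix(samples)
  info <- S4Vectors::DataFrame(info)
  if (is.null(info$channel)) info$channel <- "live"
  if (is.null(info$pool)) info$pool <- NA_character_
  if (is.null(info$tissue)) info$tissue <- NA_character_
  se <- SummarizedExperiment(assays = list(samples = samples), colData = info)
  colnames(se) <- info$packet_id
  metadata(se)$config <- config
  metadata(se)$provenance <- provenance
  new("PacketSet", se)
}

setClass("PacketSet", contains = "SummarizedExperiment")

setValidity("PacketSet", function(object) {
  msg <- character()
  cfg <- metadata(object)$config
  if (!is(cfg, "AcquisitionConfig"))
    return("metadata()$config must be an AcquisitionConfig")
  if (!"samples" %in% assayNames(object))
    return("assay 'samples' is required")
  if (nrow(object) != cfg@samplesPerPacket)
    msg <- c(msg, sprintf("assay has %d rows but config expects %d samples/packet",
                          nrow(object), cfg@samplesPerPacket))
  cd <- colData(object)
  need <- c("packet_id", "timestamp_s", "device", "power_w", "state",
            "tissue", "channel", "pool")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing colData column(s):", paste(miss, collapse = ", ")))
  if (ncol(object)) {
    if (anyDuplicated(cd$packet_id))
      msg <- c(msg, "packet_id values must be unique")
    st <- cd$state
    known <- !is.na(st)
    if (any(known & !(st %in% stateLevels())))
      msg <- c(msg, "state codes must be in 0..4 or NA")
    airoff <- known & !isTissueStateSafe(st)
    if (any(airoff & !is.na(cd$tissue)))
      msg <- c(msg, "tissue must be NA for off/air packets")
    if (any(known & isTissueStateSafe(st) & is.na(cd$tissue)))
      msg <- c(msg, "tissue-contact packets must carry a tissue name")
    if (!all(cd$channel %in% c("live", "return")))
      msg <- c(msg, "channel must be 'live' or 'return'")
  }
  if (length(msg)) msg else TRUE
})

# isTissueState over possibly-NA codes (NA -> FALSE).
isTissueStateSafe <- function(code) {
  out <- logical(length(code))
  ok <- !is.na(code)
  out[ok] <- isTissueState(code[ok])
  out
}

#' @rdname PacketSet
#' @param x,object a `PacketSet`.
#' @export
setGeneric("acquisitionConfig", function(x) standardGeneric("acquisitionConfig"))

#' @rdname PacketSet
#' @export
setMethod("acquisitionConfig", "PacketSet", function(x) metadata(x)$config)

#' @rdname PacketSet
#' @export
setGeneric("packetInfo", function(x) standardGeneric("packetInfo"))

#' @rdname PacketSet
#' @export
setMethod("packetInfo", "PacketSet", function(x) colData(x))

#' @rdname PacketSet
#' @export
setGeneric("packetSamples", function(x) standardGeneric("packetSamples"))

#' @rdname PacketSet
#' @export
setMethod("packetSamples", "PacketSet", function(x) assay(x, "samples"))

#' @rdname PacketSet
#' @export
setGeneric("packetStates", function(x) standardGeneric("packetStates"))

#' @rdname PacketSet
#' @export
setMethod("packetStates", "PacketSet", function(x) colData(x)$state)

setMethod("show", "PacketSet", function(object) {
  cfg <- acquisitionConfig(object)
  st <- packetStates(object)
  cat("PacketSet with", ncol(object), "packets of", nrow(object),
      "samples (", samplingRateHz(cfg), "Hz effective )\n")
  if (ncol(object)) {
    tab <- table(factor(stateName(st[!is.na(st)]), levels = names(stateLevels())))
    cat("  states:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        if (anyNA(st)) sprintf("unknown=%d", sum(is.na(st))) else "", "\n")
    cat("  devices:", paste(unique(colData(object)$device), collapse = ", "), "\n")
  }
})
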