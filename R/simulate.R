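# Seeded simulator of ESU current-sensor packets.
#
# All waveform constants live here. They are package-defined surrogates for
# two real generator models, chosen once so that the documented class geometry
# holds: the two devices occupy disjoint carrier-frequency ranges and clearly
# different amplitudes; the cut-contact amplitude gain (1.35) exceeds the
# amplitude span between 30 W and 40 W (sqrt(40/30) ~ 1.155) so power-grouped
# folds remain separable, yet it is by far the smallest contrast in the state
# geometry, making (cut_air, cut_tissue) the hardest pair; all carriers and
# their tissue-contact second harmonics stay below the 39 kHz Nyquist limit
# and are multiples of the 20 Hz packet resolution so sinusoids fall on exact
# FFT bins.

# Per-tissue contact factors: a small amplitude gain (tissue as a nuisance
# variable) and the relative magnitude of the contact second harmonic.
.tissueAmpGain <- c(chicken = 1.00, porcine = 1.02, bovine = 1.04)
.tissueHarmonic <- c(chicken = 0.05, porcine = 0.10, bovine = 0.15)

#' Default device profiles
#'
#' The two generator profiles shipped with the package, `dev_A` and `dev_B`.
#' Their carrier frequencies are disjoint (6/10 kHz vs 15/18 kHz) and their
#' base amplitudes clearly different (1 V vs 2.5 V), so features measured on
#' one device do not transfer to the other — the basis of the cross-device
#' generalization failure the evaluation harness demonstrates. All values are
#' package-defined surrogates, not measurements of any physical generator.
#'
#' @return a list of two [DeviceProfile] objects.
#' @examples
#' defaultProfiles()
#' @export
defaultProfiles <- function() {
  list(
    DeviceProfile(deviceId = "dev_A",
                  cutCarrierHz = 6000, coagCarrierHz = 10000,
                  baseAmplitude = 1.0, coagBurstRateHz = 100, coagDuty = 0.35,
                  cutContactGain = 1.35, coagContactGain = 3.5,
                  contactHarmonicGain = 1.0, noiseSigma = 0.02),
    DeviceProfile(deviceId = "dev_B",
                  cutCarrierHz = 15000, coagCarrierHz = 18000,
                  baseAmplitude = 2.5, coagBurstRateHz = 120, coagDuty = 0.40,
                  cutContactGain = 1.35, coagContactGain = 3.5,
                  contactHarmonicGain = 1.0, noiseSigma = 0.03))
}

checkNyquist <- function(profile, config) {
  nyq <- samplingRateHz(config) / 2
  if (profile@cutCarrierHz >= nyq || profile@coagCarrierHz >= nyq)
    stop("carrier frequencies of '", profile@deviceId,
         "' must lie strictly below the Nyquist frequency (", nyq, " Hz)")
}

#' Simulate one current-sensor packet
#'
#' Generates one 50 ms window of sensor voltage for a given device, state,
#' power and (for tissue-contact states) tissue. Off packets are pure
#' Gaussian noise; cut states are a continuous sinusoid at the device's cut
#' carrier; coagulate states are a burst-gated sinusoid at the coagulate
#' carrier. Amplitude scales with `sqrt(powerW/30)` (power proportional to
#' current squared); tissue contact applies the mode's contact gain, a small
#' tissue-specific amplitude factor, and a second-harmonic component whose
#' relative magnitude depends on the tissue. Gaussian noise with the
#' profile's `noiseSigma` is added everywhere. Given the same `seed` the
#' samples are reproduced exactly.
#'
#' @param profile a [DeviceProfile].
#' @param config an [AcquisitionConfig].
#' @param state state code or name; tissue-contact states require `tissue`,
#'   off/air states forbid it.
#' @param powerW generator power in watts (> 0).
#' @param tissue tissue name for contact states, else `NULL`.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return numeric vector of `samplesPerPacket(config)` voltages.
#' @examples
#' cfg <- AcquisitionConfig()
#' x <- simulatePacket(defaultProfiles()[[1]], cfg, "cut_air", 30, seed = 1)
#' length(x)
#' @export
simulatePacket <- function(profile, config, state, powerW, tissue = NULL,
                           seed = NULL) {
  stopifnot(is(profile, "DeviceProfile"), is(config, "AcquisitionConfig"))
  checkNyquist(profile, config)
  code <- asStateCode(state)
  stopifnot(length(code) == 1L)
  if (length(powerW) != 1L || !is.finite(powerW) || powerW <= 0)
    stop("powerW must be a single positive wattage")
  contact <- isTissueState(code)
  if (contact && (is.null(tissue) || is.na(tissue)))
    stop("tissue-contact state '", stateName(code), "' requires a tissue name")
  if (!contact && !is.null(tissue) && !is.na(tissue))
    stop("tissue must not be supplied for off/air state '", stateName(code), "'")
  withSeed(seed, {
    n <- samplesPerPacket(config)
    fs <- samplingRateHz(config)
    noise <- rnorm(n, 0, profile@noiseSigma)
    if (code == stateCode("off")) return(noise)
    mode <- stateMode(code)
    carrier <- if (mode == "cut") profile@cutCarrierHz else profile@coagCarrierHz
    amp <- profile@baseAmplitude * sqrt(powerW / 30)
    tt <- (seq_len(n) - 1L) / fs
    phase <- runif(1, 0, 2 * pi)
    x <- sin(2 * pi * carrier * tt + phase)
    if (mode == "coag") {
      gatePhase <- runif(1)
      gate <- ((tt * profile@coagBurstRateHz + gatePhase) %% 1) < profile@coagDuty
      x <- x * gate
    }
    if (contact) {
      gain <- if (mode == "cut") profile@cutContactGain else profile@coagContactGain
      tAmp <- .tissueAmpGain[[tissue]] %||% 1.0
      tHarm <- .tissueHarmonic[[tissue]] %||% 0.1
      amp <- amp * gain * tAmp
      h <- profile@contactHarmonicGain * tHarm
      if (h > 0) {
        phase2 <- runif(1, 0, 2 * pi)
        x <- x + h * sin(2 * pi * 2 * carrier * tt + phase2)
      }
    }
    amp * x + noise
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorized batch: n packets of one (state, power, tissue) condition under a
# single seed; column i is packet i. Used by the pool and stream generators.
simulatePacketBatch <- function(profile, config, state, powerW, tissue, n, seed) {
  withSeed(seed, {
    vapply(seq_len(n), function(i)
      simulatePacket(profile, config, state, powerW, tissue),
      numeric(samplesPerPacket(config)))
  })
}

#' Simulate a labeled incision stream
#'
#' Produces a time-ordered packet stream for one set-up and mode: runs of the
#' mode's air state (length `airGapPackets`) alternate with tissue-contact
#' runs (length `packetsPerIncision`, 10 packets = 0.5 s at the default
#' 20 Hz), beginning and ending in air. Every packet carries its true state
#' and a timestamp on the 50 ms grid — the ground truth used to score the
#' event detector.
#'
#' @param profile a [DeviceProfile].
#' @param config an [AcquisitionConfig].
#' @param mode `"cut"` or `"coag"`.
#' @param powerW power in watts.
#' @param tissue tissue name.
#' @param nIncisions number of incisions (>= 1).
#' @param packetsPerIncision packets per tissue-contact run.
#' @param airGapPackets packets per air run.
#' @param seed integer seed.
#' @return a [PacketSet] ordered in time.
#' @examples
#' ps <- simulateIncisionStream(defaultProfiles()[[1]], AcquisitionConfig(),
#'                              "cut", 30, "chicken", nIncisions = 2,
#'                              packetsPerIncision = 4, airGapPackets = 2,
#'                              seed = 1)
#' table(stateName(packetStates(ps)))
#' @export
simulateIncisionStream <- function(profile, config, mode = c("cut", "coag"),
                                   powerW, tissue, nIncisions,
                                   packetsPerIncision = 10L,
                                   airGapPackets = 4L, seed = 1L) {
  mode <- match.arg(mode)
  nIncisions <- as.integer(nIncisions)
  packetsPerIncision <- as.integer(packetsPerIncision)
  airGapPackets <- as.integer(airGapPackets)
  if (nIncisions < 1L) stop("nIncisions must be >= 1")
  if (packetsPerIncision < 1L || airGapPackets < 1L)
    stop("run lengths must be positive")
  airState <- stateCode(paste0(mode, "_air"))
  tisState <- stateCode(paste0(mode, "_tissue"))
  runs <- rep(c(airState, tisState), nIncisions)
  runs <- c(runs, airState)
  lens <- rep(c(airGapPackets, packetsPerIncision), nIncisions)
  lens <- c(lens, airGapPackets)
  states <- rep(runs, lens)
  nTot <- length(states)
  samples <- withSeed(seed, {
    vapply(states, function(s)
      simulatePacket(profile, config, s, powerW,
                     if (isTissueState(s)) tissue else NULL),
      numeric(samplesPerPacket(config)))
  })
  info <- data.frame(
    packet_id = sprintf("%s_%s_%gW_%s_p%05d", profile@deviceId, mode, powerW,
                        tissue, seq_len(nTot)),
    timestamp_s = (seq_len(nTot) - 1L) / packetRateHz(config),
    device = profile@deviceId,
    power_w = powerW,
    state = as.integer(states),
    tissue = ifelse(isTissueState(states), tissue, NA_character_),
    channel = "live",
    pool = NA_character_,
    stringsAsFactors = FALSE)
  PacketSet(samples, info, config,
            provenance = sprintf("incision stream: %s %s %g W %s, %d incisions",
                                 profile@deviceId, mode, powerW, tissue,
                                 nIncisions))
}

#' Simulate the full acquisition protocol
#'
#' Runs the whole bench protocol of a [ProtocolSpec]: for each device x power
#' x tissue set-up, incision streams in both modes (only the tissue-contact
#' packets enter the dataset); and for each device x power, two disjoint
#' pools ("train" and "validation") of off, cut-air and coag-air packets with
#' independent sub-seeds, so grouped folds never share an air packet between
#' training and validation. Sub-seeds are derived by hashing the set-up
#' coordinates with the top-level seed, so any subset regenerates
#' identically.
#'
#' @param spec a [ProtocolSpec].
#' @param config an [AcquisitionConfig].
#' @return a [PacketSet] containing the full dataset.
#' @examples
#' spec <- ProtocolSpec(incisionsPerMode = 1, packetsPerIncision = 2,
#'                      airPacketsPerState = 2, seed = 1)
#' ps <- simulateProtocolDataset(spec)
#' table(stateName(packetStates(ps)))
#' @export
simulateProtocolDataset <- function(spec, config = AcquisitionConfig()) {
  stopifnot(is(spec, "ProtocolSpec"), is(config, "AcquisitionConfig"))
  airStates <- c("off", "cut_air", "coag_air")
  blocksS <- list()
  blocksI <- list()
  push <- function(samples, info) {
    k <- length(blocksS) + 1L
    blocksS[[k]] <<- samples
    blocksI[[k]] <<- info
  }
  for (profile in spec@devices) {
    dev <- deviceId(profile)
    for (powerW in spec@powersW) {
      # contact packets, per tissue and mode, extracted from incision streams
      for (tissue in spec@tissues) {
        for (mode in c("cut", "coag")) {
          sd <- deriveSeed(spec@seed, dev, powerW, tissue, mode, "stream")
          st <- simulateIncisionStream(profile, config, mode, powerW, tissue,
                                       nIncisions = spec@incisionsPerMode,
                                       packetsPerIncision = spec@packetsPerIncision,
                                       airGapPackets = 1L, seed = sd)
          keep <- isTissueStateSafe(packetStates(st))
          info <- as.data.frame(packetInfo(st)[keep, ])
          info$packet_id <- sprintf("%s_%gW_%s_%s_pkt%03d",
                                    dev, powerW, tissue, mode,
                                    seq_len(sum(keep)))
          push(packetSamples(st)[, keep, drop = FALSE], info)
        }
      }
      # off/air pools: no tissue attribute, one train + one validation pool
      for (pool in c("train", "validation")) {
        for (stName in airStates) {
          sd <- deriveSeed(spec@seed, dev, powerW, stName, pool, "pool")
          n <- spec@airPacketsPerState
          samples <- simulatePacketBatch(profile, config, stName, powerW,
                                         NULL, n, sd)
          info <- data.frame(
            packet_id = sprintf("%s_%gW_%s_%s_%03d", dev, powerW, stName,
                                pool, seq_len(n)),
            timestamp_s = (seq_len(n) - 1L) / packetRateHz(config),
            device = dev, power_w = powerW,
            state = stateCode(stName), tissue = NA_character_,
            channel = "live", pool = pool, stringsAsFactors = FALSE)
          push(samples, info)
        }
      }
    }
  }
  samples <- do.call(cbind, blocksS)
  info <- do.call(rbind, blocksI)
  rownames(info) <- NULL
  PacketSet(samples, info, config, provenance = spec)
}
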