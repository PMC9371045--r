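cfg <- AcquisitionConfig()

test_that("default acquisition gives 78 kHz and shipped profiles keep their geometry", {
  expect_identical(samplesPerPacket(cfg), 3900L)
  expect_equal(samplingRateHz(cfg), 78000)
  profs <- defaultProfiles()
  expect_length(profs, 2L)
  a <- profs[[1]]; b <- profs[[2]]
  # disjoint carriers and distinct amplitudes across the two devices
  expect_false(a@cutCarrierHz == b@cutCarrierHz)
  expect_false(a@baseAmplitude == b@baseAmplitude)
  carriers <- c(a@cutCarrierHz, a@coagCarrierHz, b@cutCarrierHz, b@coagCarrierHz)
  expect_true(all(carriers < samplingRateHz(cfg) / 2))
  expect_true(a@cutContactGain < a@coagContactGain)
  expect_true(b@cutContactGain < b@coagContactGain)
})

test_that("off packets are pure sensor noise at the configured level", {
  p <- defaultProfiles()[[1]]
  x <- simulatePacket(p, cfg, "off", 30, seed = 11)
  n <- length(x)
  rms <- sqrt(mean(x^2))
  se <- p@noiseSigma / sqrt(2 * n)  # standard error of the RMS of Gaussian noise
  expect_lt(abs(rms - p@noiseSigma), 4 * se)
})

test_that("noise-free cut packets peak at the FFT bin nearest the carrier", {
  p <- defaultProfiles()[[1]]
  p@noiseSigma <- 0
  x <- simulatePacket(p, cfg, "cut_air", 30, seed = 3)
  sp <- computeSpectrum(x, cfg)
  expect_equal(sp$freq_hz[which.max(sp$magnitude)], p@cutCarrierHz)
  # coagulate: argmax within the carrier's immediate neighborhood (sidebands)
  y <- simulatePacket(p, cfg, "coag_air", 30, seed = 3)
  spc <- computeSpectrum(y, cfg)
  fpk <- spc$freq_hz[which.max(spc$magnitude)]
  expect_lt(abs(fpk - p@coagCarrierHz), p@coagBurstRateHz + 1)
})

test_that("spectral placement agrees with a brute-force DFT oracle at small N", {
  small <- AcquisitionConfig(samplesPerPacket = 60L, packetRateHz = 20)
  p <- DeviceProfile(deviceId = "t", cutCarrierHz = 140, coagCarrierHz = 300,
                     baseAmplitude = 1, coagBurstRateHz = 20, coagDuty = 0.5,
                     cutContactGain = 1.2, coagContactGain = 2,
                     contactHarmonicGain = 0, noiseSigma = 0)
  x <- simulatePacket(p, small, "cut_air", 30, seed = 5)
  oracle <- Mod(bruteDFT(x))[1:31]
  expect_equal(which.max(oracle), which.max(computeSpectrum(x, small)$magnitude))
  expect_equal(computeSpectrum(x, small)$magnitude, oracle, tolerance = 1e-9)
})

test_that("packet simulation is deterministic and validates its inputs", {
  p <- defaultProfiles()[[2]]
  expect_identical(simulatePacket(p, cfg, "coag_tissue", 35, "porcine", seed = 9),
                   simulatePacket(p, cfg, "coag_tissue", 35, "porcine", seed = 9))
  expect_error(simulatePacket(p, cfg, "cut_air", 30, tissue = "bovine"),
               "must not be supplied")
  expect_error(simulatePacket(p, cfg, "cut_tissue", 30), "requires a tissue")
  expect_error(simulatePacket(p, cfg, "cut_air", -5), "positive wattage")
})

test_that("incision streams alternate air and contact runs on the 50 ms grid", {
  p <- defaultProfiles()[[1]]
  ps <- simulateIncisionStream(p, cfg, "cut", 30, "chicken", nIncisions = 3,
                               packetsPerIncision = 4, airGapPackets = 2,
                               seed = 1)
  st <- packetStates(ps)
  expect_identical(ncol(ps), (3L + 1L) * 2L + 3L * 4L)
  r <- rle(as.vector(isTissueState(st)))
  expect_identical(sum(r$values), 3L)             # exactly 3 contact runs
  expect_true(all(r$lengths[r$values] == 4L))
  ts <- packetInfo(ps)$timestamp_s
  expect_equal(diff(ts), rep(0.05, ncol(ps) - 1))
  expect_error(simulateIncisionStream(p, cfg, "cut", 30, "chicken",
                                      nIncisions = 0), "nIncisions")
  expect_error(simulateIncisionStream(p, cfg, "cut", 30, "chicken",
                                      nIncisions = 1, packetsPerIncision = 0),
               "run lengths")
})

test_that("protocol datasets have the declared composition and are reproducible", {
  ps <- smallDataset()
  info <- as.data.frame(packetInfo(ps))
  contact <- isTissueState(ifelse(is.na(info$state), 0L, info$state)) &
             !is.na(info$state)
  # 2 devices x 3 powers x 3 tissues x 2 modes x 2 incisions x 3 packets
  expect_identical(sum(contact), 2L * 3L * 3L * 2L * 2L * 3L)
  expect_true(all(is.na(info$tissue[!contact])))
  expect_true(all(!is.na(info$tissue[contact])))
  expect_true(all(info$pool[!contact] %in% c("train", "validation")))
  expect_false(anyDuplicated(info$packet_id) > 0)
  # byte-identical regeneration under the same seed
  spec <- ProtocolSpec(incisionsPerMode = 2L, packetsPerIncision = 3L,
                       airPacketsPerState = 10L, seed = 42L)
  again <- simulateProtocolDataset(spec)
  expect_identical(packetSamples(ps), packetSamples(again))
  expect_identical(as.data.frame(packetInfo(ps)), as.data.frame(packetInfo(again)))
})

test_that("mean packet RMS increases with power for fixed device, state and tissue", {
  p <- defaultProfiles()[[1]]
  rmsAt <- function(powerW, state, tissue = NULL) {
    mean(vapply(1:5, function(i)
      sqrt(mean(simulatePacket(p, cfg, state, powerW, tissue,
                               seed = 100 + i)^2)), numeric(1)))
  }
  for (cond in list(list("cut_air", NULL), list("coag_air", NULL),
                    list("cut_tissue", "bovine"))) {
    r <- vapply(c(30, 35, 40), function(w) rmsAt(w, cond[[1]], cond[[2]]),
                numeric(1))
    expect_true(all(diff(r) > 0))
  }
})

test_that("the two devices occupy disjoint peak-frequency ranges when active", {
  fx <- smallFeatures()
  tab <- featureTable(fx)
  on <- !is.na(tab$state) & tab$state != stateCode("off")
  fa <- range(tab$peak_freq_hz[on & tab$device == "dev_A"])
  fb <- range(tab$peak_freq_hz[on & tab$device == "dev_B"])
  expect_true(fa[2] < fb[1] || fb[2] < fa[1])
})

test_that("cut-air vs cut-on-tissue is the closest class pair on both devices", {
  fx <- smallFeatures()
  for (dev in c("dev_A", "dev_B")) {
    sep <- classSeparability(fx, dev)
    expect_setequal(c(sep$state_a[1], sep$state_b[1]),
                    c("cut_air", "cut_tissue"))
    expect_lt(sep$distance[1], min(sep$distance[-1]))
  }
})
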