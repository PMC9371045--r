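# File formats: JSON-lines packet streams and CSV feature tables.
#
# Packet dialect (format 1): line 1 is a header object with the acquisition
# config, the state-code legend and a provenance string; every further line
# is one packet with keys exactly {id, t, device, power_w, tissue, state,
# channel, samples}. Sample values are written with 9 significant digits
# (below sensor noise, keeps files diff-able); timestamps are written
# round-trip exact. ".gz" paths are compressed transparently.

openConn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write and read packet streams
#'
#' `writePackets()` serializes a [PacketSet] to a JSON-lines file (one header
#' line, then one packet per line, order preserved); `readPackets()` parses
#' it back, validating every line and reporting the line number of any
#' malformed record. Metadata round-trips exactly and samples to 9
#' significant digits; writing what was read reproduces the file byte for
#' byte.
#'
#' @param pset a [PacketSet].
#' @param path file path; a `.gz` suffix enables gzip compression.
#' @return `readPackets()` returns a [PacketSet]; `writePackets()` returns
#'   `path` invisibly.
#' @examples
#' spec <- ProtocolSpec(incisionsPerMode = 1, packetsPerIncision = 2,
#'                      airPacketsPerState = 1, seed = 1)
#' ps <- simulateProtocolDataset(spec)
#' f <- tempfile(fileext = ".jsonl")
#' writePackets(ps, f)
#' ps2 <- readPackets(f)
#' all.equal(packetSamples(ps), packetSamples(ps2), tolerance = 1e-6)
#' @export
writePackets <- function(pset, path) {
  stopifnot(is(pset, "PacketSet"))
  validObject(pset)
  cfg <- acquisitionConfig(pset)
  prov <- metadata(pset)$provenance
  info <- packetInfo(pset)
  hdr <- list(
    format = 1L, type = "esusense-packets",
    samples_per_packet = samplesPerPacket(cfg),
    packet_rate_hz = packetRateHz(cfg),
    state_legend = as.list(names(sort(stateLevels()))),
    provenance = if (is.character(prov)) prov else "protocol simulation")
  # pool membership (train/validation air pools) is protocol metadata, not a
  # per-packet key; it rides in the header so folds survive a round trip
  if (any(!is.na(info$pool))) {
    hdr$pools <- lapply(
      split(info$packet_id[!is.na(info$pool)], info$pool[!is.na(info$pool)]),
      as.list)
  }
  header <- jsonlite::toJSON(hdr, auto_unbox = TRUE)
  samp <- packetSamples(pset)
  jstr <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE)
  lines <- character(ncol(pset))
  for (i in seq_len(ncol(pset))) {
    tissue <- info$tissue[i]
    lines[i] <- paste0(
      '{"id":', jstr(info$packet_id[i]),
      ',"t":', sprintf("%.17g", info$timestamp_s[i]),
      ',"device":', jstr(info$device[i]),
      ',"power_w":', fmtNum(info$power_w[i]),
      ',"tissue":', if (is.na(tissue)) "null" else jstr(tissue),
      ',"state":', if (is.na(info$state[i])) "null" else info$state[i],
      ',"channel":', jstr(info$channel[i]),
      ',"samples":[', paste(fmtNum(samp[, i]), collapse = ","), "]}")
  }
  con <- openConn(path, "wb")
  on.exit(close(con))
  writeLines(c(as.character(header), lines), con)
  invisible(path)
}

#' @rdname writePackets
#' @export
readPackets <- function(path) {
  con <- openConn(path, "rb")
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines)) stop("empty file: no header line")
  header <- tryCatch(jsonlite::fromJSON(lines[1]),
                     error = function(e) stop("malformed header at line 1: ",
                                              conditionMessage(e)))
  if (is.null(header$format) || header$format != 1L ||
      is.null(header$samples_per_packet))
    stop("line 1 is not a format-1 packet-stream header")
  cfg <- AcquisitionConfig(samplesPerPacket = header$samples_per_packet,
                           packetRateHz = header$packet_rate_hz)
  n <- samplesPerPacket(cfg)
  body <- lines[-1]
  m <- length(body)
  samples <- matrix(0, n, m)
  info <- data.frame(packet_id = character(m), timestamp_s = numeric(m),
                     device = character(m), power_w = numeric(m),
                     state = rep(NA_integer_, m),
                     tissue = rep(NA_character_, m),
                     channel = character(m), pool = rep(NA_character_, m),
                     stringsAsFactors = FALSE)
  need <- c("id", "t", "device", "power_w", "tissue", "state", "channel",
            "samples")
  for (i in seq_len(m)) {
    lineNo <- i + 1L
    rec <- tryCatch(jsonlite::fromJSON(body[i]),
                    error = function(e) stop("malformed packet at line ",
                                             lineNo, ": ",
                                             conditionMessage(e)))
    if (!is.null(rec$format))
      stop("unexpected header object mid-file at line ", lineNo)
    miss <- setdiff(need, names(rec))
    if (length(miss))
      stop("line ", lineNo, " is missing key(s): ",
           paste(miss, collapse = ", "))
    if (length(rec$samples) != n)
      stop("line ", lineNo, " has ", length(rec$samples),
           " samples; header declares ", n)
    samples[, i] <- rec$samples
    info$packet_id[i] <- rec$id
    info$timestamp_s[i] <- rec$t
    info$device[i] <- rec$device
    info$power_w[i] <- rec$power_w
    info$state[i] <- if (is.null(rec$state)) NA_integer_ else as.integer(rec$state)
    info$tissue[i] <- if (is.null(rec$tissue)) NA_character_ else rec$tissue
    info$channel[i] <- rec$channel
  }
  if (!is.null(header$pools)) {
    for (pool in names(header$pools))
      info$pool[info$packet_id %in% unlist(header$pools[[pool]])] <- pool
  }
  PacketSet(samples, info, cfg,
            provenance = if (is.null(header$provenance)) basename(path)
                         else header$provenance)
}

#' Write and read feature tables
#'
#' Feature tables are RFC-4180 CSV (header row, UTF-8, '.' decimal). Numeric
#' columns are written with 9 significant digits; the `pc1`..`pc5` columns
#' are present only when principal-component scores were attached. Reading
#' validates the mandatory columns and that the file is valid UTF-8,
#' reporting the byte offset of the first offending byte otherwise.
#'
#' @param tab a data.frame of feature records (e.g. `featureTable(fx)`).
#' @param path CSV file path.
#' @return `readFeatures()` returns a data.frame; `writeFeatures()` returns
#'   `path` invisibly.
#' @export
writeFeatures <- function(tab, path) {
  stopifnot(is.data.frame(tab))
  out <- tab
  for (cn in colnames(out)) {
    x <- out[[cn]]
    # format fractional double columns to 9 significant digits; leave
    # whole-number columns alone so a write/read/write cycle is a fixed point
    if (is.double(x) && !all(is.na(x) | x == round(x)))
      out[[cn]] <- ifelse(is.na(x), NA, fmtNum(x))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  off <- utf8InvalidOffset(raw)
  if (off > 0L)
    stop("file is not valid UTF-8: first invalid byte at offset ", off)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("packet_id", "device", "power_w", "state", "max_intensity",
            "peak_freq_hz")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (!"tissue" %in% colnames(tab)) tab$tissue <- NA_character_
  tab$tissue[!is.na(tab$tissue) & tab$tissue == ""] <- NA_character_
  tab
}

#' Serialize simulation configurations
#'
#' [ProtocolSpec] and [DeviceProfile] objects serialize to a flat, versioned
#' JSON config (`"format": 1`), so a simulation can be described in a file
#' and rerun exactly.
#'
#' @param spec a [ProtocolSpec].
#' @param path JSON file path.
#' @return `readProtocolConfig()` returns a [ProtocolSpec];
#'   `writeProtocolConfig()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeProtocolConfig(ProtocolSpec(seed = 7), f)
#' readProtocolConfig(f)
#' @export
writeProtocolConfig <- function(spec, path) {
  stopifnot(is(spec, "ProtocolSpec"))
  devs <- lapply(spec@devices, function(p) list(
    device_id = p@deviceId, cut_carrier_hz = p@cutCarrierHz,
    coag_carrier_hz = p@coagCarrierHz, base_amplitude = p@baseAmplitude,
    coag_burst_rate_hz = p@coagBurstRateHz, coag_duty = p@coagDuty,
    cut_contact_gain = p@cutContactGain, coag_contact_gain = p@coagContactGain,
    contact_harmonic_gain = p@contactHarmonicGain, noise_sigma = p@noiseSigma))
  obj <- list(format = 1L, type = "esusense-protocol", devices = devs,
              powers_w = spec@powersW, tissues = spec@tissues,
              incisions_per_mode = spec@incisionsPerMode,
              packets_per_incision = spec@packetsPerIncision,
              air_packets_per_state = spec@airPacketsPerState,
              seed = spec@seed)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeProtocolConfig
#' @export
readProtocolConfig <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(obj$format) || obj$format != 1L)
    stop("not a format-1 protocol config")
  dv <- obj$devices
  devices <- lapply(seq_len(nrow(dv)), function(i) DeviceProfile(
    deviceId = dv$device_id[i], cutCarrierHz = dv$cut_carrier_hz[i],
    coagCarrierHz = dv$coag_carrier_hz[i], baseAmplitude = dv$base_amplitude[i],
    coagBurstRateHz = dv$coag_burst_rate_hz[i], coagDuty = dv$coag_duty[i],
    cutContactGain = dv$cut_contact_gain[i],
    coagContactGain = dv$coag_contact_gain[i],
    contactHarmonicGain = dv$contact_harmonic_gain[i],
    noiseSigma = dv$noise_sigma[i]))
  ProtocolSpec(devices = devices, powersW = obj$powers_w,
               tissues = obj$tissues,
               incisionsPerMode = obj$incisions_per_mode,
               packetsPerIncision = obj$packets_per_incision,
               airPacketsPerState = obj$air_packets_per_state,
               seed = obj$seed)
}
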