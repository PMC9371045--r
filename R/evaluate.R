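# Leave-one-group-out cross-validation harness, energy-level evaluation,
# summary tables and confusion matrices.

#' Leave-one-group-out fold specification
#'
#' One grouped fold: all packets of the held-out group (one tissue, one power
#' or one device) form the validation set; the complement trains. The default
#' protocol yields exactly eight folds: three tissue, three power, two
#' device.
#'
#' @param axis `"tissue"`, `"power"` or `"device"`.
#' @param heldOut the held-out group value.
#' @param trainGroups the remaining group values.
#' @return a `FoldSpec`.
#' @aliases FoldSpec-class
#' @export FoldSpec
#' @exportClass FoldSpec
FoldSpec <- setClass("FoldSpec",
  slots = c(axis = "character", heldOut = "character",
            trainGroups = "character"))

setValidity("FoldSpec", function(object) {
  if (!object@axis %in% c("tissue", "power", "device"))
    return("axis must be 'tissue', 'power' or 'device'")
  if (object@heldOut %in% object@trainGroups)
    return("held-out group must not appear among the training groups")
  TRUE
})

setMethod("show", "FoldSpec", function(object) {
  cat("FoldSpec: leave-out", object@axis, object@heldOut,
      "(train on", paste(object@trainGroups, collapse = ", "), ")\n")
})

#' Build the eight leave-one-group-out folds
#'
#' Constructs one fold per tissue, per power and per device found in the
#' dataset (8 with the default three tissues, three powers, two devices).
#'
#' @param x a [PacketSet] or a feature table (data.frame) carrying `device`,
#'   `power_w` and `tissue` columns.
#' @return a list of [FoldSpec] objects.
#' @export
buildFolds <- function(x) {
  info <- if (is(x, "PacketSet")) as.data.frame(packetInfo(x)) else x
  tissues <- sort(unique(info$tissue[!is.na(info$tissue)]))
  powers <- sort(unique(info$power_w))
  devices <- sort(unique(info$device))
  if (!length(tissues)) stop("dataset has no tissue groups")
  if (length(powers) < 2L) stop("dataset has fewer than two power groups")
  if (length(devices) < 2L) stop("dataset has fewer than two device groups")
  c(lapply(tissues, function(g)
      FoldSpec(axis = "tissue", heldOut = g,
               trainGroups = setdiff(tissues, g))),
    lapply(powers, function(g)
      FoldSpec(axis = "power", heldOut = as.character(g),
               trainGroups = as.character(setdiff(powers, g)))),
    lapply(devices, function(g)
      FoldSpec(axis = "device", heldOut = g,
               trainGroups = setdiff(devices, g))))
}

#' Training/validation row indices of a fold
#'
#' Tissue folds validate on the held-out tissue's contact packets plus the
#' "validation" off/air pool and train on the other tissues' contact packets
#' plus the "train" pool — off/air packets carry no tissue attribute, so the
#' two disjoint pools are what keeps them from appearing on both sides.
#' Power and device folds validate on every packet of the held-out group.
#'
#' @param fold a [FoldSpec].
#' @param info per-packet metadata (data.frame with `device`, `power_w`,
#'   `tissue`, `pool`).
#' @return a list with integer vectors `train` and `validation`.
#' @export
foldIndices <- function(fold, info) {
  stopifnot(is(fold, "FoldSpec"))
  info <- as.data.frame(info)
  all <- seq_len(nrow(info))
  if (fold@axis == "tissue") {
    if (!fold@heldOut %in% info$tissue)
      stop("missing tissue group '", fold@heldOut, "'")
    contact <- !is.na(info$tissue)
    val <- contact & info$tissue == fold@heldOut
    val <- val | (!contact & !is.na(info$pool) & info$pool == "validation")
    trn <- (contact & info$tissue %in% fold@trainGroups) |
           (!contact & !is.na(info$pool) & info$pool == "train")
  } else if (fold@axis == "power") {
    if (!fold@heldOut %in% as.character(info$power_w))
      stop("missing power group '", fold@heldOut, "'")
    val <- as.character(info$power_w) == fold@heldOut
    trn <- !val
  } else {
    if (!fold@heldOut %in% info$device)
      stop("missing device group '", fold@heldOut, "'")
    val <- info$device == fold@heldOut
    trn <- !val
  }
  list(train = all[trn], validation = all[val])
}

# 5x5 confusion matrix in fixed class order 0..4 (rows = true)
stateConfusion <- function(truth, pred) {
  lv <- stateLevels()
  t(vapply(lv, function(a)
    vapply(lv, function(b) sum(truth == a & pred == b), integer(1)),
    integer(length(lv))))
}

#' Run one cross-validation fold
#'
#' Trains the requested state classifier on the fold's training rows (the
#' PCA for the `pc5` feature set is fitted on those rows only) and scores it
#' on the validation rows. Fully seeded: the fold, algorithm and feature set
#' derive a sub-seed from `seed`.
#'
#' @param fold a [FoldSpec].
#' @param algorithm `"svm"` or `"rfc"`.
#' @param featureSet `"peak"` or `"pc5"`.
#' @param fx a `PacketFeatures` object for the whole dataset.
#' @param seed top-level integer seed.
#' @return a list (`FoldResult`): `fold`, `algorithm`, `featureSet`,
#'   `accuracy` (fraction), `confusion` (5x5, rows = true class 0..4),
#'   `nValidation`.
#' @export
runFold <- function(fold, algorithm, featureSet, fx, seed = 1L) {
  idx <- foldIndices(fold, featureTable(fx))
  sub <- deriveSeed(seed, "fold", fold@axis, fold@heldOut, algorithm,
                    featureSet)
  model <- trainModel(
    ModelSpec(algorithm = algorithm, featureSet = featureSet, task = "state",
              seed = sub),
    featureSubset(fx, idx$train))
  valFx <- featureSubset(fx, idx$validation)
  truth <- featureTable(valFx)$state
  pred <- predictStates(model, valFx)
  conf <- stateConfusion(truth, pred)
  list(fold = fold, algorithm = algorithm, featureSet = featureSet,
       accuracy = mean(pred == truth), confusion = conf,
       nValidation = length(truth))
}

#' Evaluate per-device energy-level detection
#'
#' Trains the per-device three-class (30/35/40 W) energy model on the
#' device's "train" off/air pool restricted to air states (cut-air and
#' coag-air at all powers) and reports accuracy on the disjoint "validation"
#' air pool. A single accuracy per device is reported — no fold axis.
#'
#' @param fx a `PacketFeatures` object for the whole dataset.
#' @param device device id.
#' @param algorithm `"svm"` or `"rfc"`.
#' @param featureSet `"peak"` or `"pc5"`.
#' @param seed top-level integer seed.
#' @return a list with `device`, `algorithm`, `featureSet`, `accuracy`,
#'   `confusion` (powers x powers) and `nValidation`.
#' @export
runEnergyEval <- function(fx, device, algorithm = "rfc", featureSet = "peak",
                          seed = 1L) {
  tab <- featureTable(fx)
  air <- !is.na(tab$state) & isAirState(tab$state) & tab$device == device
  trn <- which(air & tab$pool == "train")
  val <- which(air & tab$pool == "validation")
  if (!length(trn) || !length(val))
    stop("device '", device, "' lacks train/validation air pools")
  powers <- sort(unique(tab$power_w[trn]))
  if (length(powers) < 3L)
    stop("device '", device, "' is missing air packets for power level(s): ",
         paste(setdiff(c(30, 35, 40), powers), collapse = ", "))
  sub <- deriveSeed(seed, "energy", device, algorithm, featureSet)
  model <- trainModel(
    ModelSpec(algorithm = algorithm, featureSet = featureSet,
              task = "energy", deviceScope = device, seed = sub),
    featureSubset(fx, trn))
  valFx <- featureSubset(fx, val)
  truth <- featureTable(valFx)$power_w
  pred <- predictEnergy(model, valFx)
  conf <- t(vapply(powers, function(a)
    vapply(powers, function(b) sum(truth == a & pred == b), integer(1)),
    integer(length(powers))))
  dimnames(conf) <- list(true = powers, predicted = powers)
  list(device = device, algorithm = algorithm, featureSet = featureSet,
       accuracy = mean(pred == truth), confusion = conf,
       nValidation = length(truth))
}

#' Run the full validation experiment
#'
#' Executes every leave-one-group-out fold for each algorithm x feature-set
#' combination, plus the per-device energy-level evaluation, on one dataset.
#' This is the package's top-level experiment driver; [summarizeResults()]
#' turns its output into accuracy tables.
#'
#' @param pset a [PacketSet] (typically from [simulateProtocolDataset()]).
#' @param algorithms classifier algorithms to run.
#' @param featureSets feature families to run.
#' @param seed top-level integer seed.
#' @return a list with `stateResults` (one fold result per fold x algorithm x
#'   feature set) and `energyResults` (one energy evaluation per device x
#'   algorithm x feature set).
#' @export
runExperiment <- function(pset, algorithms = c("svm", "rfc"),
                          featureSets = c("peak", "pc5"), seed = 1L) {
  fx <- extractFeatures(pset)
  folds <- buildFolds(pset)
  stateResults <- list()
  for (algorithm in algorithms)
    for (featureSet in featureSets)
      for (fold in folds)
        stateResults[[length(stateResults) + 1L]] <-
          runFold(fold, algorithm, featureSet, fx, seed)
  devices <- sort(unique(featureTable(fx)$device))
  energyResults <- list()
  for (algorithm in algorithms)
    for (featureSet in featureSets)
      for (device in devices)
        energyResults[[length(energyResults) + 1L]] <-
          runEnergyEval(fx, device, algorithm, featureSet, seed)
  list(stateResults = stateResults, energyResults = energyResults)
}

#' Summarize an experiment into accuracy tables
#'
#' Produces the per-fold accuracy table with per-axis unweighted averages for
#' each algorithm x feature set, the per-device energy accuracies, and the
#' grand mean over the eight axis-average cells ({SVM, RFC} x {peak, pc5} x
#' {tissue axis, power axis}) — the experiment's headline statistic. All
#' accuracies are percentages.
#'
#' @param results output of [runExperiment()].
#' @return a list with `stateTable` (columns `algorithm`, `featureSet`,
#'   `axis`, `heldOut`, `accuracy_pct`), `axisAverages`, `energyTable`,
#'   `grandMean_pct`, and `confusions` (named list of 5x5 matrices).
#' @export
summarizeResults <- function(results) {
  sr <- results$stateResults
  if (!length(sr)) stop("no fold results to summarize")
  stateTable <- do.call(rbind, lapply(sr, function(r)
    data.frame(algorithm = r$algorithm, featureSet = r$featureSet,
               axis = r$fold@axis, heldOut = r$fold@heldOut,
               accuracy_pct = 100 * r$accuracy)))
  combos <- unique(stateTable[c("algorithm", "featureSet")])
  axes <- c("tissue", "power", "device")
  axisAverages <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- stateTable[stateTable$algorithm == combos$algorithm[i] &
                      stateTable$featureSet == combos$featureSet[i], ]
    miss <- setdiff(axes, sub$axis)
    if (length(miss))
      stop("incomplete result grid: ", combos$algorithm[i], "/",
           combos$featureSet[i], " lacks axis ", paste(miss, collapse = ", "))
    data.frame(algorithm = combos$algorithm[i],
               featureSet = combos$featureSet[i], axis = axes,
               average_pct = vapply(axes, function(a)
                 mean(sub$accuracy_pct[sub$axis == a]), numeric(1)))
  }))
  rownames(axisAverages) <- NULL
  energyTable <- if (length(results$energyResults)) {
    do.call(rbind, lapply(results$energyResults, function(r)
      data.frame(device = r$device, algorithm = r$algorithm,
                 featureSet = r$featureSet, accuracy_pct = 100 * r$accuracy)))
  } else {
    data.frame(device = character(0), algorithm = character(0),
               featureSet = character(0), accuracy_pct = numeric(0))
  }
  confusions <- stats::setNames(
    lapply(sr, `[[`, "confusion"),
    vapply(sr, function(r) paste(r$algorithm, r$featureSet, r$fold@axis,
                                 r$fold@heldOut, sep = "_"), character(1)))
  cells <- axisAverages$average_pct[axisAverages$axis %in% c("tissue", "power")]
  list(stateTable = stateTable, axisAverages = axisAverages,
       energyTable = energyTable, grandMean_pct = grandMeanAccuracy(cells),
       confusions = confusions)
}

#' Grand mean of axis-average accuracies
#'
#' Unweighted mean of the tissue-axis and power-axis average accuracies over
#' all classifier x feature-set combinations (eight cells with the default
#' grid). The device axis is excluded: cross-device transfer is reported
#' separately as a failure mode, not folded into the headline number.
#'
#' @param cells numeric vector of axis-average accuracies (percent).
#' @return the grand mean (percent).
#' @examples
#' grandMeanAccuracy(c(98.82, 98.93, 95.06, 97.22,
#'                     90.77, 98.52, 87.21, 97.98))
#' @export
grandMeanAccuracy <- function(cells) {
  mean(as.numeric(cells))
}

#' Scaled between-class distances of the peak features
#'
#' For every pair of cautery states of one device, the Euclidean distance
#' between the class means of (max intensity, peak frequency), each feature
#' scaled by the pair's pooled within-class standard deviation. A feature
#' whose pooled SD is zero contributes nothing when the class means agree and
#' an infinite separation otherwise (the classes live at distinct constant
#' frequencies). On the default simulator geometry the smallest distance is
#' always the (cut_air, cut_tissue) pair — the hardest pair for the
#' classifiers.
#'
#' @param fx a `PacketFeatures` object.
#' @param device device id to restrict to.
#' @return a data.frame of state-name pairs and their scaled distances,
#'   sorted ascending.
#' @export
classSeparability <- function(fx, device) {
  tab <- featureTable(fx)
  tab <- tab[!is.na(tab$state) & tab$device == device, ]
  feats <- c("max_intensity", "peak_freq_hz")
  codes <- sort(unique(tab$state))
  pairs <- utils::combn(codes, 2L)
  res <- data.frame(state_a = stateName(pairs[1L, ]),
                    state_b = stateName(pairs[2L, ]),
                    distance = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    a <- tab[tab$state == pairs[1L, k], feats]
    b <- tab[tab$state == pairs[2L, k], feats]
    d2 <- 0
    for (f in feats) {
      va <- var(a[[f]]); vb <- var(b[[f]])
      pooled <- sqrt(((nrow(a) - 1L) * va + (nrow(b) - 1L) * vb) /
                     (nrow(a) + nrow(b) - 2L))
      dm <- mean(a[[f]]) - mean(b[[f]])
      if (pooled == 0) {
        if (dm != 0) d2 <- Inf
      } else {
        d2 <- d2 + (dm / pooled)^2
      }
    }
    res$distance[k] <- sqrt(d2)
  }
  res[order(res$distance), ]
}
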