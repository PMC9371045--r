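# Cautery-state and energy-level classifiers.
#
# "Library-default" models throughout: an RBF-kernel SVM (e1071 defaults) and
# a 100-tree random forest. Features are z-scored with training statistics
# before the SVM because peak frequencies (~10^4 Hz) would otherwise dwarf
# intensities under the RBF kernel; forests are scale-invariant, so the same
# standardization is harmless there and is applied uniformly.

RF_NTREE <- 100L

#' Classifier specification
#'
#' Declares which model to train: the algorithm (`"svm"` or `"rfc"`), the
#' feature family (`"peak"` = the 2-D max-intensity/peak-frequency pair,
#' `"pc5"` = the first five principal components of the banded spectrum),
#' and the task (`"state"` = the five cautery states, `"energy"` = the three
#' power levels). Energy-level models are per-device — each generator has its
#' own waveform, so `deviceScope` must name a single device for that task.
#'
#' @param algorithm `"svm"` or `"rfc"`.
#' @param featureSet `"peak"` or `"pc5"`.
#' @param task `"state"` or `"energy"`.
#' @param deviceScope `"all"` or one device id (required for energy task).
#' @param seed integer seed for any stochastic component of training.
#' @return a `ModelSpec`.
#' @examples
#' ModelSpec("rfc", "peak", "state")
#' ModelSpec("rfc", "peak", "energy", deviceScope = "dev_A")
#' @aliases ModelSpec-class
#' @export ModelSpec
#' @exportClass ModelSpec
ModelSpec <- setClass("ModelSpec",
  slots = c(algorithm = "character", featureSet = "character",
            task = "character", deviceScope = "character", seed = "integer"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("svm", "rfc"))
    msg <- c(msg, "algorithm must be 'svm' or 'rfc'")
  if (!object@featureSet %in% c("peak", "pc5"))
    msg <- c(msg, "featureSet must be 'peak' or 'pc5'")
  if (!object@task %in% c("state", "energy"))
    msg <- c(msg, "task must be 'state' or 'energy'")
  if (object@task == "energy" && object@deviceScope == "all")
    msg <- c(msg, "energy-level models are per-device: deviceScope must name one device")
  if (length(msg)) msg else TRUE
})

#' @rdname ModelSpec
#' @usage NULL
setMethod("initialize", "ModelSpec",
  function(.Object, algorithm = "rfc", featureSet = "peak", task = "state",
           deviceScope = "all", seed = 1L, ...) {
    .Object <- callNextMethod(.Object, algorithm = algorithm,
      featureSet = featureSet, task = task, deviceScope = deviceScope,
      seed = as.integer(seed), ...)
    validObject(.Object)
    .Object
  })

setClass("TrainedModel",
  representation(spec = "ModelSpec", center = "numeric", scale = "numeric",
                 classes = "character", fit = "ANY", pca = "ANY"))

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel:", object@spec@algorithm, "on", object@spec@featureSet,
      "features, task", object@spec@task,
      if (object@spec@deviceScope != "all") paste0("(", object@spec@deviceScope, ")"),
      "- classes:", paste(object@classes, collapse = ", "), "\n")
})

# design matrix for a feature set; fits the PCA when asked to (training only)
modelMatrixFor <- function(model, fx, fitPca = FALSE) {
  tab <- featureTable(fx)
  if (model@spec@featureSet == "peak") {
    X <- cbind(max_intensity = tab$max_intensity,
               peak_freq_hz = tab$peak_freq_hz)
  } else {
    if (fitPca) model@pca <- fitPCA(bandedSpectra(fx), 5L)
    X <- applyPCA(model@pca, bandedSpectra(fx))
  }
  list(model = model, X = X)
}

#' Train a cautery-state or energy-level classifier
#'
#' Trains the classifier declared by a [ModelSpec] on the given (training)
#' features. Features are z-scored with training-set statistics; for the
#' `pc5` feature set a PCA is fitted on the training banded spectra and
#' frozen into the model. The state task uses the five state codes as labels;
#' the energy task uses the wattage, and accepts only air-state packets of
#' the model's device — energy levels are read off while the blade is in air,
#' before tissue is ever touched.
#'
#' @param spec a [ModelSpec].
#' @param fx a `PacketFeatures` object (training rows only, labels known).
#' @return a `TrainedModel`.
#' @examples
#' spec <- ProtocolSpec(incisionsPerMode = 2, packetsPerIncision = 3,
#'                      airPacketsPerState = 6, seed = 1)
#' fx <- extractFeatures(simulateProtocolDataset(spec))
#' m <- trainModel(ModelSpec("rfc", "peak", "state"), fx)
#' table(predictStates(m, fx) == featureTable(fx)$state)
#' @aliases TrainedModel-class
#' @export
trainModel <- function(spec, fx) {
  stopifnot(is(spec, "ModelSpec"), is(fx, "PacketFeatures"))
  tab <- featureTable(fx)
  if (!nrow(tab)) stop("no training rows")
  if (spec@task == "state") {
    if (anyNA(tab$state)) stop("training rows with unknown state labels")
    y <- factor(tab$state, levels = sort(unique(tab$state)))
  } else {
    if (anyNA(tab$state)) stop("training rows with unknown state labels")
    if (any(isTissueStateSafe(tab$state)))
      stop("energy-level training accepts air-state packets only; ",
           "tissue-contact rows supplied")
    if (!all(isAirState(tab$state)))
      stop("energy-level training accepts air-state packets only; ",
           "off rows supplied")
    if (!all(tab$device == spec@deviceScope))
      stop("energy-level training rows must all come from device '",
           spec@deviceScope, "'")
    y <- factor(tab$power_w, levels = sort(unique(tab$power_w)))
  }
  if (nlevels(y) < 2L)
    stop("training requires at least two classes; got ", nlevels(y))
  model <- new("TrainedModel", spec = spec, center = numeric(),
               scale = numeric(), classes = levels(y), fit = NULL, pca = NULL)
  mm <- modelMatrixFor(model, fx, fitPca = TRUE)
  model <- mm$model
  X <- mm$X
  model@center <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  model@scale <- sdv
  Xs <- scale(X, center = model@center, scale = model@scale)
  model@fit <- withSeed(spec@seed, {
    if (spec@algorithm == "svm") {
      e1071::svm(Xs, y, kernel = "radial", scale = FALSE)
    } else {
      randomForest::randomForest(Xs, y, ntree = RF_NTREE)
    }
  })
  model
}

predictRaw <- function(model, fx) {
  if (!nrow(featureTable(fx))) return(character(0))
  X <- modelMatrixFor(model, fx)$X
  if (ncol(X) != length(model@center))
    stop("feature dimension mismatch: got ", ncol(X), ", model expects ",
         length(model@center))
  Xs <- scale(X, center = model@center, scale = model@scale)
  as.character(withSeed(model@spec@seed, predict(model@fit, Xs)))
}

#' Predict cautery states
#'
#' Applies a trained state classifier to packet features; one state code per
#' row, deterministic given the model. Only codes seen in training can be
#' predicted.
#'
#' @param model a `TrainedModel` with task `"state"`.
#' @param fx a `PacketFeatures` object.
#' @return integer vector of state codes.
#' @export
predictStates <- function(model, fx) {
  stopifnot(is(model, "TrainedModel"))
  if (model@spec@task != "state") stop("model task is not 'state'")
  as.integer(predictRaw(model, fx))
}

#' Predict generator energy levels
#'
#' Applies a trained per-device energy-level classifier to air-state packet
#' features; one wattage per row, restricted to the wattages seen in
#' training. Rows whose metadata names a different device are rejected.
#'
#' @param model a `TrainedModel` with task `"energy"`.
#' @param fx a `PacketFeatures` object of air-state packets from the model's
#'   device.
#' @return numeric vector of wattages.
#' @export
predictEnergy <- function(model, fx) {
  stopifnot(is(model, "TrainedModel"))
  if (model@spec@task != "energy") stop("model task is not 'energy'")
  tab <- featureTable(fx)
  if (nrow(tab) && !all(is.na(tab$device) | tab$device == model@spec@deviceScope))
    stop("features contain packets from a device other than '",
         model@spec@deviceScope, "'")
  as.numeric(predictRaw(model, fx))
}
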