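test_that("the default protocol yields exactly eight grouped folds", {
  folds <- buildFolds(smallDataset())
  expect_length(folds, 8L)
  axes <- vapply(folds, function(f) f@axis, character(1))
  expect_identical(sum(axes == "tissue"), 3L)
  expect_identical(sum(axes == "power"), 3L)
  expect_identical(sum(axes == "device"), 2L)
  for (f in folds) expect_false(f@heldOut %in% f@trainGroups)
  # missing group is named
  info <- as.data.frame(packetInfo(smallDataset()))
  expect_error(buildFolds(info[info$device == "dev_A", ]), "device")
})

test_that("fold membership honours the leave-one-group-out contract", {
  info <- as.data.frame(packetInfo(smallDataset()))
  folds <- buildFolds(smallDataset())

  p30 <- Filter(function(f) f@axis == "power" && f@heldOut == "30", folds)[[1]]
  idx <- foldIndices(p30, info)
  expect_true(all(info$power_w[idx$train] != 30))
  expect_true(all(info$power_w[idx$validation] == 30))
  expect_length(intersect(idx$train, idx$validation), 0L)

  # tissue folds: air/off packets never serve both roles
  tf <- Filter(function(f) f@axis == "tissue", folds)[[1]]
  idx <- foldIndices(tf, info)
  airTrain <- idx$train[is.na(info$tissue[idx$train])]
  airVal <- idx$validation[is.na(info$tissue[idx$validation])]
  expect_true(all(info$pool[airTrain] == "train"))
  expect_true(all(info$pool[airVal] == "validation"))
  expect_length(intersect(airTrain, airVal), 0L)
  # the held-out tissue's contact packets never train
  expect_false(any(info$tissue[idx$train] %in% tf@heldOut))
})

test_that("fold runs are seeded, conserve counts, and are duplication-invariant", {
  fx <- smallFeatures()
  fold <- buildFolds(smallDataset())[[1]]
  r1 <- runFold(fold, "rfc", "peak", fx, seed = 3L)
  r2 <- runFold(fold, "rfc", "peak", fx, seed = 3L)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$confusion, r2$confusion)

  # confusion conservation: row sums = per-class validation counts
  idx <- foldIndices(fold, featureTable(fx))
  truth <- featureTable(fx)$state[idx$validation]
  expect_identical(unname(rowSums(r1$confusion)),
                   vapply(0:4, function(s) sum(truth == s), numeric(1)))
  expect_identical(sum(r1$confusion), r1$nValidation)
  expect_equal(r1$accuracy, sum(diag(r1$confusion)) / sum(r1$confusion))

  # duplicating every validation row leaves accuracy unchanged
  model <- trainModel(ModelSpec("rfc", "peak", "state",
                                seed = esusense:::deriveSeed(3L, "fold",
                                  fold@axis, fold@heldOut, "rfc", "peak")),
                      esusense:::featureSubset(fx, idx$train))
  dup <- esusense:::featureSubset(fx, rep(idx$validation, 2L))
  accDup <- mean(predictStates(model, dup) == featureTable(dup)$state)
  expect_equal(accDup, r1$accuracy)
})

test_that("a transferable-device toy dataset scores perfectly in every fold", {
  profs <- defaultProfiles()
  twin <- profs[[1]]
  twin@deviceId <- "dev_A2"   # second device with identical waveform physics
  spec <- ProtocolSpec(devices = list(profs[[1]], twin),
                       incisionsPerMode = 2L, packetsPerIncision = 3L,
                       airPacketsPerState = 8L, seed = 2L)
  fx <- extractFeatures(simulateProtocolDataset(spec))
  for (fold in buildFolds(featureTable(fx))) {
    r <- runFold(fold, "rfc", "peak", fx, seed = 2L)
    expect_equal(r$accuracy, 1.0)
  }
})

test_that("energy evaluation uses the disjoint air pools and demands all powers", {
  fx <- smallFeatures()
  r <- runEnergyEval(fx, "dev_A", "rfc", "peak", seed = 1L)
  expect_gte(r$accuracy, 0.99)
  expect_identical(sum(r$confusion), r$nValidation)

  spec <- ProtocolSpec(powersW = c(30, 40), incisionsPerMode = 1L,
                       packetsPerIncision = 2L, airPacketsPerState = 4L,
                       seed = 3L)
  fx2 <- extractFeatures(simulateProtocolDataset(spec))
  expect_error(runEnergyEval(fx2, "dev_A", "rfc", "peak"), "power")
  expect_error(runEnergyEval(fx, "dev_Z", "rfc", "peak"), "dev_Z")
})

test_that("summaries average folds unweighted and keep confusion totals", {
  spec <- ProtocolSpec(incisionsPerMode = 1L, packetsPerIncision = 2L,
                       airPacketsPerState = 4L, seed = 9L)
  ps <- simulateProtocolDataset(spec)
  res <- runExperiment(ps, algorithms = "rfc", featureSets = "peak", seed = 9L)
  s <- summarizeResults(res)

  for (ax in c("tissue", "power", "device")) {
    cells <- s$stateTable$accuracy_pct[s$stateTable$axis == ax]
    avg <- s$axisAverages$average_pct[s$axisAverages$axis == ax]
    expect_equal(avg, mean(cells), tolerance = 1e-12)
  }
  nVal <- vapply(res$stateResults, `[[`, integer(1), "nValidation")
  totals <- vapply(s$confusions, sum, integer(1))
  expect_identical(unname(totals), nVal)

  # incomplete grids are refused with the missing cells named
  res2 <- res
  keep <- vapply(res2$stateResults, function(r) r$fold@axis != "power",
                 logical(1))
  res2$stateResults <- res2$stateResults[keep]
  expect_error(summarizeResults(res2), "power")
})

test_that("the grand mean reproduces the published averaging rule", {
  cells <- c(98.82, 98.93, 95.06, 97.22, 90.77, 98.52, 87.21, 97.98)
  expect_equal(round(grandMeanAccuracy(cells), 2), 95.56)
})
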