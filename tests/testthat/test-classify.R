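test_that("model specs enforce their task constraints", {
  expect_error(ModelSpec("rfc", "peak", "energy"), "per-device")
  expect_error(ModelSpec("lda", "peak", "state"), "algorithm")
  expect_s4_class(ModelSpec("svm", "pc5", "state"), "ModelSpec")
})

test_that("both algorithms separate two distant Gaussian blobs perfectly", {
  fx <- blobFeatures(n = 200L, delta = 10, seed = 7L)
  truth <- featureTable(fx)$state
  for (algo in c("svm", "rfc")) {
    m <- trainModel(ModelSpec(algo, "peak", "state", seed = 7L), fx)
    expect_identical(predictStates(m, fx), truth)
  }
})

test_that("training is deterministic given spec, data and seed", {
  fx <- blobFeatures(n = 80L, delta = 4, seed = 3L)
  probe <- blobFeatures(n = 40L, delta = 4, seed = 21L)
  for (algo in c("svm", "rfc")) {
    m1 <- trainModel(ModelSpec(algo, "peak", "state", seed = 5L), fx)
    m2 <- trainModel(ModelSpec(algo, "peak", "state", seed = 5L), fx)
    expect_identical(predictStates(m1, probe), predictStates(m2, probe))
  }
})

test_that("conflicting labels on identical rows cap accuracy at the majority share", {
  # 90 byte-identical rows labelled 2:1 (classes 0 vs 1) plus a separable
  # third class far away; on the conflicted point no model can beat 2/3
  tab <- data.frame(packet_id = sprintf("p%03d", 1:120),
                    device = "dev_X", power_w = 30,
                    state = c(rep(c(0L, 0L, 1L), 30), rep(2L, 30)),
                    max_intensity = c(rep(1, 90), rep(50, 30)),
                    peak_freq_hz = c(rep(500, 90), rep(9000, 30)),
                    stringsAsFactors = FALSE)
  fx <- featuresFromTable(tab, bands = matrix(1, 120, 10))
  m <- trainModel(ModelSpec("rfc", "peak", "state", seed = 1L), fx)
  pred <- predictStates(m, fx)
  conflicted <- seq_len(90)
  expect_lte(mean(pred[conflicted] == tab$state[conflicted]), 2 / 3 + 1e-9)
})

test_that("degenerate training inputs are rejected", {
  fx <- blobFeatures(n = 20L)
  one <- esusense:::featureSubset(fx, which(featureTable(fx)$state == 0L))
  expect_error(trainModel(ModelSpec("rfc", "peak", "state"), one),
               "at least two classes")
  tab <- featureTable(fx)
  tab$state <- NA_integer_
  expect_error(trainModel(ModelSpec("rfc", "peak", "state"),
                          featuresFromTable(tab)), "unknown state")
})

test_that("prediction handles empty tables and checks dimensions", {
  fx <- blobFeatures(n = 30L)
  m <- trainModel(ModelSpec("svm", "peak", "state", seed = 2L), fx)
  empty <- esusense:::featureSubset(fx, integer(0))
  expect_identical(predictStates(m, empty), integer(0))
  expect_error(predictEnergy(m, fx), "not 'energy'")
})

test_that("energy models train on air packets only and stay class-closed", {
  fx <- smallFeatures()
  tab <- featureTable(fx)
  airA <- which(!is.na(tab$state) & isAirState(tab$state) &
                tab$device == "dev_A")
  spec <- ModelSpec("rfc", "peak", "energy", deviceScope = "dev_A", seed = 1L)

  # tissue-contact rows are rejected outright
  contact <- which(isTissueState(ifelse(is.na(tab$state), 0L, tab$state)))
  expect_error(trainModel(spec, esusense:::featureSubset(fx, contact[1:30])),
               "air-state packets only")
  off <- which(!is.na(tab$state) & tab$state == 0L & tab$device == "dev_A")
  expect_error(trainModel(spec, esusense:::featureSubset(fx, c(airA, off))),
               "off rows")

  # leave 35 W out of training: predictions are restricted to {30, 40}
  no35 <- airA[tab$power_w[airA] != 35]
  m <- trainModel(spec, esusense:::featureSubset(fx, no35))
  pred <- predictEnergy(m, esusense:::featureSubset(fx, airA))
  expect_true(all(pred %in% c(30, 40)))

  # device mismatch is rejected
  airB <- which(!is.na(tab$state) & isAirState(tab$state) &
                tab$device == "dev_B")
  expect_error(predictEnergy(m, esusense:::featureSubset(fx, airB)),
               "other than 'dev_A'")

  # high-SNR air packets at 40 W classify as 40 W
  mfull <- trainModel(spec, esusense:::featureSubset(fx, no35))
  at40 <- airA[tab$power_w[airA] == 40]
  expect_true(all(predictEnergy(mfull, esusense:::featureSubset(fx, at40)) == 40))

  # permuting row order permutes predictions identically
  perm <- sample(seq_along(airA))
  p1 <- predictEnergy(m, esusense:::featureSubset(fx, airA))
  p2 <- predictEnergy(m, esusense:::featureSubset(fx, airA[perm]))
  expect_identical(p2, p1[perm])
})

test_that("random within-set-up splits reach near-perfect accuracy with RFC/peak", {
  fx <- smallFeatures()
  tab <- featureTable(fx)
  rows <- which(tab$device == "dev_A" & tab$power_w == 30 &
                (is.na(tab$tissue) | tab$tissue == "chicken"))
  set.seed(12)
  trn <- unlist(lapply(split(rows, tab$state[rows]), function(r)
    sample(r, length(r) %/% 2)))   # stratified so every class trains
  val <- setdiff(rows, trn)
  m <- trainModel(ModelSpec("rfc", "peak", "state", seed = 12L),
                  esusense:::featureSubset(fx, trn))
  acc <- mean(predictStates(m, esusense:::featureSubset(fx, val)) ==
              tab$state[val])
  expect_gte(acc, 0.99)
})

test_that("label permutation drives validation accuracy to chance", {
  fx <- smallFeatures()
  tab <- featureTable(fx)
  set.seed(77)
  idx <- seq_len(nrow(tab))
  trn <- sample(idx, length(idx) %/% 2)
  val <- setdiff(idx, trn)
  shuffled <- tab
  shuffled$state[trn] <- sample(shuffled$state[trn])
  fxs <- featuresFromTable(shuffled, bands = bandedSpectra(fx))
  m <- trainModel(ModelSpec("rfc", "peak", "state", seed = 77L),
                  esusense:::featureSubset(fxs, trn))
  acc <- mean(predictStates(m, esusense:::featureSubset(fx, val)) ==
              tab$state[val])
  chance <- max(table(tab$state[val])) / length(val)
  expect_lt(abs(acc - chance), 0.10)
})

test_that("a state model trained on one device collapses on the other", {
  fx <- smallFeatures()
  tab <- featureTable(fx)
  a <- which(tab$device == "dev_A")
  b <- which(tab$device == "dev_B")
  m <- trainModel(ModelSpec("svm", "peak", "state", seed = 9L),
                  esusense:::featureSubset(fx, a))
  acc <- mean(predictStates(m, esusense:::featureSubset(fx, b)) ==
              tab$state[b])
  expect_lt(acc, 0.60)
})
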