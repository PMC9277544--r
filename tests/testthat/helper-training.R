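# Shared desk-scale training fixture for the acceptance checks: 200
# synthetic 96x96 scenes drawn from the mixture of the three challenge
# regimes (low contrast / small / large), full and baseline variants
# trained identically (15 epochs, batch 4, Adam 1e-3, augmentation on), and
# a 100-scene held-out test set scored with the binarized mean Dice.
# Trained once per test run and memoized; two acceptance blocks consume it.

training_fixture_env <- new.env(parent = emptyenv())

acceptance_training <- function() {
  if (!is.null(training_fixture_env$result)) return(training_fixture_env$result)
  t0 <- proc.time()[["elapsed"]]
  dir <- file.path(tempdir(), "acceptance-synth")
  test_dir_ <- file.path(tempdir(), "acceptance-synth-test")
  if (!dir.exists(dir))
    generateDataset(synthConfig(nImages = 200L, size = 96L, seed = 101L,
                                regime = "mixed"), dir)
  if (!dir.exists(test_dir_))
    generateDataset(synthConfig(nImages = 100L, size = 96L, seed = 907L,
                                regime = "mixed"), test_dir_)
  tcfg <- trainConfig(epochs = 15L, inputSize = 96L, batchSize = 4L, seed = 101L)
  full <- trainFRCNet(modelConfig(variant = "full", seed = 101L), tcfg, dir,
                      quiet = TRUE)
  base <- trainFRCNet(modelConfig(variant = "baseline", seed = 101L), tcfg, dir,
                      quiet = TRUE)
  test_mdice <- function(run) {
    pred <- tempfile()
    predictFRCNet(run$checkpointPath, file.path(test_dir_, "images"), pred)
    preds <- lapply(sort(list.files(file.path(pred, "probs"), full.names = TRUE)),
                    function(f) png::readPNG(f))
    gts <- lapply(sort(list.files(file.path(test_dir_, "masks"),
                                  full.names = TRUE)),
                  function(f) (png::readPNG(f) > 0.5) * 1)
    mean(mapply(function(p, g) diceCoef((p >= 0.5) * 1, g), preds, gts))
  }
  training_fixture_env$result <- list(
    full = full, base = base,
    fullTestDice = test_mdice(full), baseTestDice = test_mdice(base),
    elapsed = proc.time()[["elapsed"]] - t0)
  training_fixture_env$result
}
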