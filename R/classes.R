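# S4 configuration and report classes. Constructors are the camelCase
# functions below; slots are validated on construction.

is_pow2 <- function(x) x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L

#' @title Configuration of the enhanced calibration convolution (ECC) block
#' @description The ECC block splits its input into two channel halves with a
#'   1x1 convolution, keeps one half through an identity-preserving 1x1
#'   conv-BN-ReLU branch, and gates the other half with a sigmoid attention
#'   map built from a downsample-convolve-upsample calibration path before
#'   re-fusing and adding the block input.
#' @slot inChannels even positive integer, channels of the block input.
#' @slot calibrationRate spatial pool/upsample factor of the calibration
#'   path; a power of two, at least 2.
#' @slot useDepthwise logical; use depthwise-separable 3x3 convolutions
#'   (the default) instead of dense ones.
#' @exportClass ECCConfig
setClass("ECCConfig", representation(
  inChannels = "integer", calibrationRate = "integer", useDepthwise = "logical"
), validity = function(object) {
  if (object@inChannels < 2L || object@inChannels %% 2L != 0L)
    return("inChannels must be even and >= 2")
  if (object@calibrationRate < 2L || !is_pow2(object@calibrationRate))
    return("calibrationRate must be a power of two >= 2")
  TRUE
})

#' Create an ECC block configuration
#' @param inChannels even number of input channels.
#' @param calibrationRate spatial down/up factor of the calibration path
#'   (power of two, default 4).
#' @param useDepthwise use depthwise-separable 3x3 convolutions.
#' @return an [ECCConfig-class] object.
#' @export
eccConfig <- function(inChannels, calibrationRate = 4L, useDepthwise = TRUE) {
  new("ECCConfig", inChannels = as.integer(inChannels),
      calibrationRate = as.integer(calibrationRate),
      useDepthwise = isTRUE(useDepthwise))
}

#' @title Configuration of the progressive context-aware fusion (PCF) block
#' @description The PCF block compresses its input to half the channels,
#'   extracts a local (3x3) and a surrounding (3x3, dilation-5) branch,
#'   concatenates them, adds a softmax global-attention-pooled context vector
#'   passed through a channel bottleneck, and closes with a residual skip
#'   from the block input.
#' @slot inChannels even positive integer.
#' @slot dilation dilation rate of the surrounding extractor (default 5).
#' @slot bottleneckRatio channel reduction of the context bottleneck;
#'   must divide inChannels.
#' @exportClass PCFConfig
setClass("PCFConfig", representation(
  inChannels = "integer", dilation = "integer", bottleneckRatio = "integer"
), validity = function(object) {
  if (object@inChannels < 2L || object@inChannels %% 2L != 0L)
    return("inChannels must be even and >= 2")
  if (object@dilation < 1L) return("dilation must be >= 1")
  if (object@bottleneckRatio < 1L ||
      object@inChannels %% object@bottleneckRatio != 0L)
    return("bottleneckRatio must be >= 1 and divide inChannels")
  TRUE
})

#' Create a PCF block configuration
#' @param inChannels even number of input channels.
#' @param dilation dilation rate of the surrounding branch (default 5).
#' @param bottleneckRatio context bottleneck reduction (default 4).
#' @return a [PCFConfig-class] object.
#' @export
pcfConfig <- function(inChannels, dilation = 5L, bottleneckRatio = 4L) {
  new("PCFConfig", inChannels = as.integer(inChannels),
      dilation = as.integer(dilation),
      bottleneckRatio = as.integer(bottleneckRatio))
}

#' @title Configuration of the multi-scale pyramid aggregation (MPA) head
#' @description The MPA head bilinearly upsamples five decoder levels to the
#'   finest resolution, concatenates them, projects to a common width, and
#'   re-weights the channels with a squeeze-and-excitation gate.
#' @slot levelChannels integer vector of length 5: channels of the five
#'   decoder levels, finest first.
#' @slot fusedChannels output width of the 1x1 projection.
#' @slot seRatio squeeze-and-excitation reduction; must divide fusedChannels.
#' @exportClass MPAConfig
setClass("MPAConfig", representation(
  levelChannels = "integer", fusedChannels = "integer", seRatio = "integer"
), validity = function(object) {
  if (length(object@levelChannels) != 5L || any(object@levelChannels < 1L))
    return("levelChannels must be 5 positive integers")
  if (object@fusedChannels < 1L ||
      object@fusedChannels %% object@seRatio != 0L)
    return("fusedChannels must be positive and divisible by seRatio")
  TRUE
})

#' Create an MPA head configuration
#' @param levelChannels channels of the five pyramid levels, finest first.
#' @param fusedChannels width after the fusing 1x1 projection (default 32).
#' @param seRatio squeeze-and-excitation reduction (default 4).
#' @return an [MPAConfig-class] object.
#' @export
mpaConfig <- function(levelChannels, fusedChannels = 32L, seRatio = 4L) {
  new("MPAConfig", levelChannels = as.integer(levelChannels),
      fusedChannels = as.integer(fusedChannels), seRatio = as.integer(seRatio))
}

#' @title Network architecture configuration
#' @slot encoderWidths strictly increasing even channel widths of the five
#'   encoder levels.
#' @slot variant one of "baseline", "ecc", "pcf", "mpa", "full"; which
#'   context modules are enabled.
#' @slot ecc,pcf,mpa block configurations (channel fields are taken per
#'   level from encoderWidths; the stored inChannels act as templates).
#' @slot seed integer seed for weight initialization.
#' @exportClass ModelConfig
setClass("ModelConfig", representation(
  encoderWidths = "integer", variant = "character", ecc = "ECCConfig",
  pcf = "PCFConfig", mpa = "MPAConfig", seed = "integer"
), validity = function(object) {
  if (length(object@encoderWidths) != 5L)
    return("encoderWidths must have length 5")
  if (any(diff(object@encoderWidths) <= 0L))
    return("encoderWidths must be strictly increasing")
  if (any(object@encoderWidths %% 2L != 0L))
    return("encoderWidths must all be even")
  if (!object@variant %in% c("baseline", "ecc", "pcf", "mpa", "full"))
    return("variant must be one of baseline, ecc, pcf, mpa, full")
  TRUE
})

#' Create a network configuration
#'
#' Defaults reproduce the published lightweight design: five encoder levels
#' of widths 16-160, depthwise-separable convolutions inside the context
#' blocks, and a 32-channel fused head, which together stay under the 0.78 M
#' parameter budget (see [auditParams()]).
#'
#' @param encoderWidths five strictly increasing even widths.
#' @param variant "baseline" (plain convolutional units), "ecc", "pcf",
#'   "mpa" (one module added), or "full" (all three).
#' @param calibrationRate ECC calibration factor.
#' @param dilation PCF surrounding-branch dilation.
#' @param bottleneckRatio PCF context bottleneck reduction.
#' @param fusedChannels MPA fused width.
#' @param seRatio MPA squeeze-and-excitation reduction.
#' @param useDepthwise depthwise-separable 3x3 convolutions in ECC.
#' @param seed weight initialization seed.
#' @return a [ModelConfig-class] object.
#' @export
modelConfig <- function(encoderWidths = c(16L, 32L, 64L, 128L, 160L),
                        variant = "full", calibrationRate = 4L,
                        dilation = 5L, bottleneckRatio = 4L,
                        fusedChannels = 32L, seRatio = 4L,
                        useDepthwise = TRUE, seed = 1L) {
  encoderWidths <- as.integer(encoderWidths)
  new("ModelConfig", encoderWidths = encoderWidths, variant = variant,
      ecc = eccConfig(encoderWidths[1], calibrationRate, useDepthwise),
      pcf = pcfConfig(encoderWidths[5], dilation, bottleneckRatio),
      mpa = mpaConfig(encoderWidths, fusedChannels, seRatio),
      seed = as.integer(seed))
}

setMethod("show", "ModelConfig", function(object) {
  cat("FRCNet model configuration\n")
  cat("  variant        :", object@variant, "\n")
  cat("  encoder widths :", paste(object@encoderWidths, collapse = ", "), "\n")
  cat("  ECC rate", object@ecc@calibrationRate,
      "| PCF dilation", object@pcf@dilation,
      "| MPA fused", object@mpa@fusedChannels, "\n")
  cat("  seed           :", object@seed, "\n")
})

#' @title Loss weighting
#' @slot lambda1 weight of the binary cross-entropy term (default 0.6).
#' @slot lambda2 weight of the Dice term (default 0.4).
#' @slot xi Laplace smoothing constant of the Dice term (default 1e-8).
#' @exportClass LossWeights
setClass("LossWeights", representation(
  lambda1 = "numeric", lambda2 = "numeric", xi = "numeric"
), validity = function(object) {
  if (object@lambda1 < 0 || object@lambda2 < 0)
    return("loss weights must be non-negative")
  if (object@xi <= 0) return("xi must be positive")
  TRUE
})

#' Create loss weights for the compound BCE + Dice objective
#' @param lambda1 BCE weight (default 0.6).
#' @param lambda2 Dice weight (default 0.4).
#' @param xi Dice smoothing constant (default 1e-8).
#' @return a [LossWeights-class] object.
#' @export
lossWeights <- function(lambda1 = 0.6, lambda2 = 0.4, xi = 1e-8) {
  new("LossWeights", lambda1 = lambda1, lambda2 = lambda2, xi = xi)
}

#' @title Metric computation configuration
#' @slot binThreshold binarization threshold for the region metrics
#'   (Dice/IoU), default 0.5.
#' @slot fbwBeta2 beta squared of the weighted F-measure (default 1).
#' @slot sAlpha object/region mixing weight of the S-measure (default 0.5).
#' @slot eThresholds number of equally spaced binarization thresholds of the
#'   E-measure sweep (default 256).
#' @exportClass MetricConfig
setClass("MetricConfig", representation(
  binThreshold = "numeric", fbwBeta2 = "numeric", sAlpha = "numeric",
  eThresholds = "integer"
), validity = function(object) {
  if (object@binThreshold <= 0 || object@binThreshold >= 1)
    return("binThreshold must be in (0, 1)")
  if (object@eThresholds < 1L) return("eThresholds must be >= 1")
  TRUE
})

#' Create a metric configuration
#' @param binThreshold binarization threshold for Dice/IoU (default 0.5).
#' @param fbwBeta2 weighted F-measure beta^2 (default 1).
#' @param sAlpha S-measure mixing weight (default 0.5).
#' @param eThresholds number of E-measure thresholds (default 256).
#' @return a [MetricConfig-class] object.
#' @export
metricConfig <- function(binThreshold = 0.5, fbwBeta2 = 1, sAlpha = 0.5,
                         eThresholds = 256L) {
  new("MetricConfig", binThreshold = binThreshold, fbwBeta2 = fbwBeta2,
      sAlpha = sAlpha, eThresholds = as.integer(eThresholds))
}

#' @title Seven-statistic evaluation report
#' @description Mean over the evaluated images of Dice, IoU, weighted
#'   F-measure, S-measure, mean and max E-measure, and mean absolute error,
#'   with the per-image values kept alongside.
#' @slot mDice,mIoU,wFb,sAlpha,meanE,maxE,mae means over images, all in
#'   [0, 1].
#' @slot perImage data.frame of the per-image metrics.
#' @exportClass MetricReport
setClass("MetricReport", representation(
  mDice = "numeric", mIoU = "numeric", wFb = "numeric", sAlpha = "numeric",
  meanE = "numeric", maxE = "numeric", mae = "numeric", perImage = "data.frame"
), validity = function(object) {
  vals <- c(object@mDice, object@mIoU, object@wFb, object@sAlpha,
            object@meanE, object@maxE, object@mae)
  if (any(!is.finite(vals)) || any(vals < -1e-12) || any(vals > 1 + 1e-12))
    return("all summary metrics must lie in [0, 1]")
  if (object@mDice < object@mIoU - 1e-12)
    return("mDice must dominate mIoU (Dice-Jaccard inequality)")
  TRUE
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf(
    "Segmentation metrics over %d image(s)\n", nrow(object@perImage)))
  cat(sprintf(
    "  mDice %.4f | mIoU %.4f | wFb %.4f | S %.4f | mE %.4f | maxE %.4f | MAE %.4f\n",
    object@mDice, object@mIoU, object@wFb, object@sAlpha, object@meanE,
    object@maxE, object@mae))
})

#' @title Synthetic scene generator configuration
#' @description Controls the seeded renderer of colonoscopy-like scenes:
#'   smooth reddish mucosa background with fold-like ridge distractors, one
#'   or more star-convex polyp blobs with a configurable
#'   foreground-background intensity gap, and additive Gaussian pixel noise.
#' @slot nImages number of image/mask pairs a dataset run produces.
#' @slot size square image side in pixels, a multiple of 32.
#' @slot polypsPerImage integer range c(lo, hi) of polyps per scene.
#' @slot radiusFrac range of polyp base radius as a fraction of the side.
#' @slot contrastDelta range of the foreground-background intensity gap,
#'   in [0, 1] units.
#' @slot boundaryIrregularity radial perturbation amplitude (0 = disks).
#' @slot noiseSigma standard deviation of additive Gaussian pixel noise.
#' @slot polarity "bright" (polyps lighter than mucosa, the default) or
#'   "mixed" (sign of the intensity offset drawn at random per polyp, as in
#'   low-contrast frames where flat lesions can be slightly darker).
#' @slot regime "custom" (use the configured ranges as-is) or "mixed"
#'   (per sample, draw one of the three challenge regimes - low contrast,
#'   small, large - and apply its parameter ranges).
#' @slot seed master seed; sample index is mixed in deterministically.
#' @exportClass SynthConfig
setClass("SynthConfig", representation(
  nImages = "integer", size = "integer", polypsPerImage = "integer",
  radiusFrac = "numeric", contrastDelta = "numeric",
  boundaryIrregularity = "numeric", noiseSigma = "numeric",
  polarity = "character", regime = "character", seed = "integer"
), validity = function(object) {
  if (!object@polarity %in% c("bright", "mixed"))
    return("polarity must be 'bright' or 'mixed'")
  if (!object@regime %in% c("custom", "mixed"))
    return("regime slot must be 'custom' or 'mixed'")
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  if (object@nImages < 1L) return("nImages must be positive")
  if (object@size < 32L || object@size %% 32L != 0L)
    return("size must be a positive multiple of 32")
  if (!rng_ok(object@polypsPerImage) || object@polypsPerImage[1] < 0L)
    return("polypsPerImage must be an ordered non-negative range")
  if (!rng_ok(object@radiusFrac) || object@radiusFrac[1] <= 0 ||
      object@radiusFrac[2] >= 0.5)
    return("radiusFrac must be an ordered range within (0, 0.5)")
  if (!rng_ok(object@contrastDelta) || object@contrastDelta[1] < 0 ||
      object@contrastDelta[2] > 1)
    return("contrastDelta must be an ordered range within [0, 1]")
  if (object@boundaryIrregularity < 0) return("boundaryIrregularity must be >= 0")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

#' Create a synthetic generator configuration
#'
#' The defaults emulate a mixed regime of moderately sized, moderately
#' contrasted polyps. `regime` applies a preset for the three published
#' challenge regimes: `"low_contrast"` (intensity gap at most 0.1),
#' `"small"` (base radius 4-8% of the side), `"large"` (25-40%).
#'
#' @param nImages number of samples (default 200).
#' @param size square side, multiple of 32 (default 96).
#' @param polypsPerImage range of polyp counts (default c(1, 2)).
#' @param radiusFrac base radius range as side fraction (default c(0.08, 0.22)).
#' @param contrastDelta intensity-gap range (default c(0.15, 0.45)).
#' @param boundaryIrregularity radial perturbation amplitude (default 0.15).
#' @param noiseSigma Gaussian pixel noise sd (default 0.02).
#' @param polarity "bright" or "mixed" polyp intensity offsets.
#' @param seed master seed (default 1).
#' @param regime optional preset: "low_contrast", "small", or "large" fix
#'   one challenge regime's ranges; "mixed" draws one of the three regimes
#'   per sample (the benchmark composition used by the package's own
#'   training checks).
#' @return a [SynthConfig-class] object.
#' @export
synthConfig <- function(nImages = 200L, size = 96L,
                        polypsPerImage = c(1L, 2L),
                        radiusFrac = c(0.08, 0.22),
                        contrastDelta = c(0.15, 0.45),
                        boundaryIrregularity = 0.15,
                        noiseSigma = 0.02, polarity = "bright",
                        seed = 1L, regime = NULL) {
  regime_slot <- "custom"
  if (!is.null(regime)) {
    regime <- match.arg(regime, c("low_contrast", "small", "large", "mixed"))
    if (regime == "low_contrast") { contrastDelta <- c(0.04, 0.10); polarity <- "mixed" }
    if (regime == "small") radiusFrac <- c(0.04, 0.08)
    if (regime == "large") { radiusFrac <- c(0.25, 0.40); polypsPerImage <- c(1L, 1L) }
    if (regime == "mixed") regime_slot <- "mixed"
  }
  if (length(polypsPerImage) == 1L) polypsPerImage <- rep(polypsPerImage, 2L)
  if (length(radiusFrac) == 1L) radiusFrac <- rep(radiusFrac, 2L)
  if (length(contrastDelta) == 1L) contrastDelta <- rep(contrastDelta, 2L)
  new("SynthConfig", nImages = as.integer(nImages), size = as.integer(size),
      polypsPerImage = as.integer(polypsPerImage), radiusFrac = radiusFrac,
      contrastDelta = contrastDelta,
      boundaryIrregularity = boundaryIrregularity,
      noiseSigma = noiseSigma, polarity = polarity, regime = regime_slot,
      seed = as.integer(seed))
}

#' @title Training configuration
#' @slot lr Adam learning rate (default 1e-3).
#' @slot batchSize minibatch size (default 4).
#' @slot epochs training epochs; the published protocol trains at least 80,
#'   desk-scale runs override this downwards.
#' @slot inputSize square side images are resized to; the published protocol
#'   uses 512.
#' @slot optimizer optimizer name; only "adam" is implemented.
#' @slot augment apply flip / right-angle rotation / brightness-contrast
#'   augmentation during training.
#' @slot valFrac fraction of the training images held out for validation by
#'   a seeded shuffle (default 0.1).
#' @slot seed seed for shuffling, augmentation draws, and batching.
#' @slot device placement hint; only "cpu" is available.
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  lr = "numeric", batchSize = "integer", epochs = "integer",
  inputSize = "integer", optimizer = "character", augment = "logical",
  valFrac = "numeric", seed = "integer", device = "character"
), validity = function(object) {
  if (object@lr <= 0) return("lr must be positive")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@inputSize < 32L || object@inputSize %% 32L != 0L)
    return("inputSize must be a multiple of 32")
  if (object@optimizer != "adam") return("only the adam optimizer is available")
  if (object@valFrac < 0 || object@valFrac >= 1)
    return("valFrac must be in [0, 1)")
  if (object@device != "cpu") return("only cpu execution is available")
  TRUE
})

#' Create a training configuration
#' @param lr learning rate (default 1e-3).
#' @param batchSize minibatch size (default 4).
#' @param epochs number of epochs (default 80, the full published protocol;
#'   use far fewer for desk-scale synthetic runs).
#' @param inputSize square training resolution, multiple of 32 (default 512;
#'   desk-scale synthetic runs use 96).
#' @param optimizer only "adam".
#' @param augment enable training-time augmentation (default TRUE).
#' @param valFrac validation fraction (default 0.1).
#' @param seed run seed (default 1).
#' @param device only "cpu".
#' @return a [TrainConfig-class] object.
#' @export
trainConfig <- function(lr = 1e-3, batchSize = 4L, epochs = 80L,
                        inputSize = 512L, optimizer = "adam", augment = TRUE,
                        valFrac = 0.1, seed = 1L, device = "cpu") {
  new("TrainConfig", lr = lr, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), inputSize = as.integer(inputSize),
      optimizer = optimizer, augment = isTRUE(augment), valFrac = valFrac,
      seed = as.integer(seed), device = device)
}
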