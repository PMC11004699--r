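test_that("feature clusters are reproducible with controllable separation", {
  d1 <- generateFeatureDataset(100, 5, classSeparation = 4, seed = 3)
  d2 <- generateFeatureDataset(100, 5, classSeparation = 4, seed = 3)
  expect_identical(d1$inputs, d2$inputs)
  expect_identical(d1$labels, d2$labels)
  expect_equal(sum(d1$labels), 50)
  expect_equal(dim(d1$inputs), c(100, 5))
  # class balance is respected
  d3 <- generateFeatureDataset(100, 3, classBalance = 0.3, seed = 1)
  expect_equal(sum(d3$labels), 30)
  expect_error(generateFeatureDataset(2), "nSamples")
  expect_error(generateFeatureDataset(10, classSeparation = -1),
               "nonnegative")
  expect_error(generateFeatureDataset(10, classBalance = 1), "classBalance")
})

test_that("separation 6 is nearly perfectly separable; separation 0 is chance", {
  # oracle classifier: sign of the projection on the true separation axis
  ds <- generateFeatureDataset(200, 5, classSeparation = 6, seed = 9)
  proj <- as.numeric(ds$inputs %*% ds$direction)
  acc <- mean(as.integer(proj > 0) == ds$labels)
  expect_gte(acc, 0.99)
  d0 <- generateFeatureDataset(2000, 5, classSeparation = 0, seed = 10)
  proj0 <- as.numeric(d0$inputs %*% d0$direction)
  acc0 <- mean(as.integer(proj0 > 0) == d0$labels)
  expect_lt(abs(acc0 - 0.5), 0.05)
})

test_that("image sets match their manifest, label counts, and seed", {
  dir <- withr::local_tempdir()
  gen <- generateSyntheticImages(file.path(dir, "a"), nImages = 20,
                                 imageSize = 64, tumorFraction = 0.5,
                                 blobRadiusRange = c(6, 10), seed = 4)
  expect_equal(sum(gen$manifest$label), 10)
  expect_true(all(file.exists(file.path(dir, "a", gen$manifest$filepath))))
  man <- read.csv(file.path(dir, "a", "manifest.csv"))
  expect_equal(man$label, gen$manifest$label)
  expect_true(file.exists(file.path(dir, "a", "spec.yaml")))
  # bit-identical regeneration under the same seed
  gen2 <- generateSyntheticImages(file.path(dir, "b"), nImages = 20,
                                  imageSize = 64, tumorFraction = 0.5,
                                  blobRadiusRange = c(6, 10), seed = 4)
  expect_identical(gen$manifest$label, gen2$manifest$label)
  same <- vapply(gen$manifest$filepath, function(f)
    identical(unname(tools::md5sum(file.path(dir, "a", f))),
              unname(tools::md5sum(file.path(dir, "b", f)))), logical(1))
  expect_true(all(same))
  expect_error(generateSyntheticImages(dir, 10, tumorFraction = 0),
               "tumorFraction")
  expect_error(generateSyntheticImages(dir, 10, imageSize = 64,
                                       blobRadiusRange = c(10, 30)),
               "fit inside")
})

test_that("noiseless blob images have the exact analytic mean lift", {
  dir <- withr::local_tempdir()
  lift <- 0.3
  s <- 64
  gen <- generateSyntheticImages(dir, nImages = 10, imageSize = s,
                                 tumorFraction = 0.5,
                                 blobRadiusRange = c(6, 10),
                                 blobIntensityLift = lift, noiseSd = 0,
                                 seed = 6)
  # negative images are all identical to the head template
  neg <- gen$manifest$filepath[gen$manifest$label == 0][1]
  template <- as.array(EBImage::readImage(file.path(dir, neg)))
  grid <- expand.grid(x = seq_len(s) - 0.5, y = seq_len(s) - 0.5)
  for (i in which(gen$manifest$label == 1)) {
    img <- as.array(EBImage::readImage(file.path(dir,
                                                 gen$details$filepath[i])))
    # independent pixel recount of the blob ellipse
    det <- gen$details[i, ]
    inBlob <- ((grid$x - det$blobX) / det$blobRx)^2 +
              ((grid$y - det$blobY) / det$blobRy)^2 <= 1
    # 8-bit PNG quantization perturbs each lifted pixel by < 1/255
    expect_equal(mean(img) - mean(template),
                 lift * sum(inBlob) / s^2, tolerance = 0.02)
  }
})

test_that("stratified splits are disjoint, exhaustive, and proportional", {
  m <- data.frame(filepath = sprintf("i%03d.png", 1:100),
                  label = rep(c(0, 1), c(60, 40)))
  sp <- splitManifest(m, trainFraction = 0.8, seed = 2)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_length(intersect(sp$train$filepath, sp$test$filepath), 0)
  expect_setequal(c(sp$train$filepath, sp$test$filepath), m$filepath)
  # stratification within one sample of the ideal per class
  expect_lte(abs(sum(sp$train$label == 1) - 0.8 * 40), 1)
  expect_lte(abs(sum(sp$train$label == 0) - 0.8 * 60), 1)
  # determinism
  sp2 <- splitManifest(m, trainFraction = 0.8, seed = 2)
  expect_identical(sp$train$filepath, sp2$train$filepath)
  expect_error(splitManifest(m, trainFraction = 1), "trainFraction")
  expect_error(splitManifest(data.frame(label = c(0, 1, 1)), 0.8),
               "fewer than 2")
})

test_that("stronger blob contrast never degrades end-to-end accuracy", {
  dir <- withr::local_tempdir()
  lifts <- c(0.03, 0.2, 0.45)
  accs <- vapply(seq_along(lifts), function(k) {
    cfg <- loadExperimentConfig(NULL)
    cfg$seed <- 31L
    cfg$synth$nImages <- 60L
    cfg$synth$blobIntensityLift <- lifts[k]
    cfg$synth$noiseSd <- 0.05
    cfg$elm$hiddenCount <- 10L
    cfg$optimizer$populationSize <- 8L
    cfg$optimizer$maxIterations <- 8L
    out <- runDiagnosisExperiment(cfg,
                                  imageDir = file.path(dir, paste0("l", k)))
    out$report$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})
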