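# brute-force per-element confusion counter, independent of confusionCounts
bruteForceCounts <- function(truth, predicted, positive) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    t_pos <- identical(as.character(truth[i]), as.character(positive))
    p_pos <- identical(as.character(predicted[i]), as.character(positive))
    if (t_pos && p_pos) tp <- tp + 1L
    else if (!t_pos && !p_pos) tn <- tn + 1L
    else if (!t_pos && p_pos) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# small optimizer settings for fast functional tests
tinyGoa <- function(..., seed = 1L)
  goaControl(populationSize = 10, maxIterations = 15, seed = seed, ...)
tinyAgoa <- function(..., seed = 1L)
  agoaControl(populationSize = 10, maxIterations = 15, seed = seed, ...)

# separable two-cluster toy set for classifier tests
toyClusters <- function(n = 100, d = 5, sep = 6, seed = 7L)
  generateFeatureDataset(nSamples = n, nFeatures = d, classSeparation = sep,
                         seed = seed)
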