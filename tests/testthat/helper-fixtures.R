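# Shared fixtures, memoised across test files within one run. Everything is
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small CNN patch classifier trained on generator patches; used by the
# classifier tests and the end-to-end acceptance runs.
fixture_classifier <- function() {
  fixture("classifier", function() {
    tr <- generate_patch_training_set(150, seed = 101)
    va <- generate_patch_training_set(60, seed = 202)
    clf <- train_patch_classifier(tr$patches, tr$labels, va$patches, va$labels,
                                  epochs = 40, seed = 11)
    attr(clf, "val") <- va
    clf
  })
}

fixture_canopies <- function() {
  fixture("canopies", function() {
    lapply(c(11L, 22L, 33L), function(s) generate_canopy(canopy_spec(seed = s)))
  })
}

# A cheap canopy whose lesions the colour-rule oracle detects exactly.
small_canopy <- function(seed = 5L, n_lesions = 2L) {
  generate_canopy(canopy_spec(rows = 96L, cols = 144L, margin = 16L,
                              seed = seed), n_lesions = n_lesions)
}

# Independent scalar JSD used as the oracle against package internals.
jsd_oracle <- function(a, b, eps = 1e-12) {
  a <- (a + eps) / sum(a + eps)
  b <- (b + eps) / sum(b + eps)
  m <- (a + b) / 2
  s <- 0
  for (k in seq_along(a)) {
    s <- s + 0.5 * a[k] * log(a[k] / m[k]) + 0.5 * b[k] * log(b[k] / m[k])
  }
  s
}

# Positive node set of a single-tile segmentation result.
segmentation_nodes <- function(seg) {
  sort(unique(unlist(lapply(seg$tiles, function(t) t$positive_nodes))))
}
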