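# Shared fixtures, all generated in code.  Expensive objects are built
# once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A handful of small molecules with known chemistry.
tinyMoleculeSet <- function() cached("tinyMols", {
  tf <- tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol",
               "c1ccccc1 benzene",
               "CC(=O)Nc1ccc(O)cc1 acetaminophen",
               "CCN(CC)CC triethylamine"), tf)
  readMolecules(tf)
})

# Small labeled training table with 4 informative + 6 noise descriptors.
smallTable <- function() cached("smallTable",
  genDescriptorDataset(syntheticSpec(nActives = 60, nInactives = 300,
                                     nInformative = 4, nNoise = 6,
                                     shift = 3, seed = 5)))

smallModel <- function() cached("smallModel",
  buildModel(smallTable(), iseConfig(filtersPerIteration = 150, seed = 3)))

# Random confusion tables with both classes present.
randomCounts <- function(n, maxCount = 1000) {
  lapply(seq_len(n), function(i) {
    nA <- sample(2:maxCount, 1); nI <- sample(2:maxCount, 1)
    tp <- sample(0:nA, 1); fp <- sample(0:nI, 1)
    ConfusionCounts(tp = tp, fp = fp, tn = nI - fp, fn = nA - tp)
  })
}

# Valid random SMILES assembled from fragments (deterministic given the
# current RNG state).
randomSmiles <- function(n) {
  scaffolds <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCOC1", "c1ccsc1")
  tails <- c("", "C", "CC", "CCC", "CCCC", "CCO", "CCN", "CCl", "C(=O)O",
             "C(=O)N", "OC", "CO", "C(C)C")
  paste0(sample(scaffolds, n, replace = TRUE),
         sample(tails, n, replace = TRUE),
         sample(tails, n, replace = TRUE))
}

# A two-filter model with hand-chosen weights 2 and 3 (nA = nI = 10):
# filter "fx" has TPR 1.0 / FPR 0.5 -> w = 2, "fy" TPR 0.9 / FPR 0.3 -> 3.
toyWeightModel <- function(weightMode = "rate") {
  f1 <- RangeFilter("x", low = 0, high = 1,
                    counts = ConfusionCounts(tp = 10, fp = 5, tn = 5, fn = 0))
  f1@mcc <- balancedMCC(f1@counts)
  f2 <- RangeFilter("y", low = 0, high = 1,
                    counts = ConfusionCounts(tp = 9, fp = 3, tn = 7, fn = 1))
  f2@mcc <- balancedMCC(f2@counts)
  iseScreen:::.newISEModel(list(f1, f2), nA = 10, nI = 10,
                           config = iseConfig(weightMode = weightMode))
}
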