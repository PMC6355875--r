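test_that("tanimoto handles the elementary cases", {
  a <- c(1, 1, 1, 0, 0); b <- c(0, 0, 0, 1, 1)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, b), 0)
  # strict subset: |a| = 5, |b| = 10 -> 5/10
  a2 <- rep(c(1, 0), c(5, 5)); b2 <- rep(1, 10)
  expect_equal(tanimoto(a2, b2), 0.5)
  # both empty defined as 0
  expect_equal(tanimoto(numeric(8), numeric(8)), 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("tanimoto is symmetric with unit self-similarity", {
  withr::local_seed(1)
  for (i in 1:25) {
    a <- rbinom(64, 1, 0.3); b <- rbinom(64, 1, 0.3)
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    if (sum(a) > 0) expect_equal(tanimoto(a, a), 1)
    expect_gte(tanimoto(a, b), 0); expect_lte(tanimoto(a, b), 1)
  }
})

test_that("package tanimoto agrees with the ChemmineR implementation", {
  fp <- moleculeFingerprints(tinyMoleculeSet())
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(tanimoto(fp[i], fp[j]),
                 unname(ChemmineR::fpSim(fp[i], fp[j], method = "Tanimoto",
                                         sorted = FALSE, addone = 0)),
                 tolerance = 1e-12)
  }
})

test_that("fingerprints are structure-determined", {
  tf <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO a", "CCO b", "OCC c"), tf)
  fp <- moleculeFingerprints(readMolecules(tf))
  expect_equal(tanimoto(fp[1], fp[2]), 1)   # same molecule twice
  expect_equal(tanimoto(fp[1], fp[3]), 1)   # alternative spelling
  # bond-less molecules cannot carry a path fingerprint; the chosen
  # convention rejects them at ingest with a report
  writeLines("C methane", tf)
  expect_error(suppressWarnings(readMolecules(tf)), "no parsable")
})

test_that("diversity pruning retains the greedy first-come subset", {
  # duplicates collapse to the first
  tf <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO a", "OCC b"), tf)
  pruned <- diversityPrune(readMolecules(tf), 0.8)
  expect_identical(moleculeIds(pruned), "a")
  expect_identical(attr(pruned, "excluded"), "b")

  # mutually dissimilar molecules all survive
  writeLines(c("CCO a", "c1ccccc1 b", "CCCCCCCCCC c"), tf)
  expect_length(diversityPrune(readMolecules(tf), 0.8), 3L)

  expect_error(diversityPrune(tinyMoleculeSet(), 0), "threshold")
  expect_error(diversityPrune(tinyMoleculeSet(), 1.2), "threshold")
})

test_that("pruning matches an independent greedy oracle and its invariant", {
  withr::local_seed(7)
  tf <- withr::local_tempfile(fileext = ".smi")
  smis <- unique(randomSmiles(30))
  writeLines(paste(smis, sprintf("m%02d", seq_along(smis))), tf)
  ms <- readMolecules(tf)
  fp <- suppressWarnings(moleculeFingerprints(ms))
  n <- length(ms)
  sim <- outer(seq_len(n), seq_len(n),
               Vectorize(function(i, j) tanimoto(fp[i], fp[j])))
  # hand-rolled greedy walk over the similarity matrix
  kept <- integer(0)
  for (i in seq_len(n)) if (!any(sim[i, kept] >= 0.8)) kept <- c(kept, i)
  pruned <- diversityPrune(ms, 0.8)
  expect_identical(moleculeIds(pruned), moleculeIds(ms)[kept])
  # post-hoc invariant: no retained pair at or above the threshold
  off <- sim[kept, kept]; diag(off) <- 0
  expect_true(all(off < 0.8))
})

test_that("similarity reports reduce the full matrix faithfully", {
  tf <- withr::local_tempfile(fileext = ".smi")
  writeLines("CCO a", tf)
  one <- readMolecules(tf)
  expect_equal(similarityReport(one, one)$max, 1)

  ms <- tinyMoleculeSet()
  rep <- similarityReport(ms, ms)
  fp <- moleculeFingerprints(ms)
  manual <- outer(1:4, 1:4, Vectorize(function(i, j) tanimoto(fp[i], fp[j])))
  expect_equal(unname(rep$matrix), manual, tolerance = 1e-12)
  expect_equal(rep$max, max(manual))
  expect_equal(unname(rep$countsAbove[">0.4"]), sum(manual > 0.4))
  expect_equal(rep$nPairs, 16)
  expect_equal(sum(rep$histogram$count), 16)
})

test_that("the applicability domain box uses mean +- 2 sample sd of actives", {
  withr::local_seed(3)
  X <- matrix(rnorm(200, mean = 5), 50, 4,
              dimnames = list(NULL, c("lip_acc", "lip_don", "cLogP", "MW")))
  dt <- DescriptorTable(X, labels = "active")
  box <- domainBox(dt)
  expect_equal(box$mean, unname(colMeans(X)))
  expect_equal(box$sd, unname(apply(X, 2, sd)))  # n-1 denominator
  expect_equal(box$low, box$mean - 2 * box$sd)
  expect_true(all(box$low <= box$high))
})

test_that("inactive sampling respects the domain box and the seed", {
  withr::local_seed(4)
  ro5 <- c("lip_acc", "lip_don", "cLogP", "MW")
  act <- DescriptorTable(matrix(rnorm(400), 100, 4, dimnames = list(NULL, ro5)),
                         labels = "active")
  box <- domainBox(act)
  cand <- matrix(rnorm(4000, sd = 2), 1000, 4, dimnames = list(NULL, ro5))
  pool <- DescriptorTable(cand, labels = "unknown")

  s1 <- sampleInactives(act, pool, n = 50, seed = 17)
  s2 <- sampleInactives(act, pool, n = 50, seed = 17)
  expect_identical(moleculeIds(s1), moleculeIds(s2))
  expect_equal(ncol(s1), 50)
  expect_true(all(moleculeLabels(s1) == "inactive"))
  X <- descriptorMatrix(s1)
  for (i in 1:4)
    expect_true(all(X[, box$descriptor[i]] >= box$low[i] &
                    X[, box$descriptor[i]] <= box$high[i]))

  # a candidate at the actives' means is eligible; one at mean + 3 sd is not
  mid <- matrix(box$mean, 1, dimnames = list("mid", ro5))
  far <- matrix(box$mean + 3 * box$sd, 1, dimnames = list("far", ro5))
  pool2 <- DescriptorTable(rbind(mid, far), labels = "unknown")
  expect_warning(got <- sampleInactives(act, pool2, n = 2, seed = 1), "eligible")
  expect_identical(moleculeIds(got), "mid")
})

test_that("degenerate and empty domains behave as specified", {
  ro5 <- c("lip_acc", "lip_don", "cLogP", "MW")
  # sigma = 0: only exact-value candidates are eligible
  act <- DescriptorTable(matrix(1, 10, 4, dimnames = list(NULL, ro5)),
                         labels = "active")
  cand <- matrix(c(rep(1, 4), rep(1.01, 4)), 2, 4, byrow = TRUE,
                 dimnames = list(c("exact", "near"), ro5))
  pool <- DescriptorTable(cand, labels = "unknown")
  expect_warning(got <- sampleInactives(act, pool, n = 2, seed = 1))
  expect_identical(moleculeIds(got), "exact")

  # nothing eligible: fatal, naming a limiting descriptor
  none <- DescriptorTable(matrix(99, 3, 4, dimnames = list(NULL, ro5)),
                          labels = "unknown")
  expect_error(sampleInactives(act, none, n = 1, seed = 1),
               "limiting descriptor")
})
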