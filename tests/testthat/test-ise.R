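test_that("filter passage is a closed-interval conjunction", {
  f <- RangeFilter(c("a", "b", "c", "d"), low = c(0, 0, 0, 0),
                   high = c(1, 1, 1, 1))
  expect_true(filterPasses(f, c(a = .5, b = .5, c = .5, d = .5)))
  expect_false(filterPasses(f, c(a = .5, b = 1.5, c = .5, d = .5)))
  # boundary values pass (closed intervals)
  expect_true(filterPasses(f, c(a = 0, b = 1, c = 0, d = 1)))
  expect_error(filterPasses(f, c(a = .5, b = .5, c = .5)), "missing")
  # vectorized over a matrix
  m <- rbind(c(a = .5, b = .5, c = .5, d = .5),
             c(a = 2, b = .5, c = .5, d = .5))
  expect_identical(filterPasses(f, m), c(TRUE, FALSE))
})

test_that("balanced MCC reproduces the published confusion-table values", {
  # two cells agree with the printed table to 3 decimals ...
  expect_equal(round(balancedMCC(ConfusionCounts(tp = 285, fp = 124,
                                                 tn = 9876, fn = 110)), 3),
               0.736)
  expect_equal(round(balancedMCC(ConfusionCounts(tp = 118, fp = 0,
                                                 tn = 10000, fn = 277)), 3),
               0.419)
  # ... the remaining printed cells carry a 0.001 rounding slack
  expect_equal(round(balancedMCC(ConfusionCounts(383, 3952, 6048, 12)), 3),
               0.616, tolerance = 0.0011 / 0.616)
  expect_equal(round(balancedMCC(ConfusionCounts(314, 318, 9682, 81)), 3),
               0.774, tolerance = 0.0011 / 0.774)
  expect_equal(round(balancedMCC(ConfusionCounts(184, 17, 9983, 211)), 3),
               0.547, tolerance = 0.0011 / 0.547)
})

test_that("balanced MCC conventions: perfect, degenerate, absent class", {
  expect_equal(balancedMCC(ConfusionCounts(tp = 50, fp = 0, tn = 70, fn = 0)), 1)
  # a filter passing everything has a zero denominator factor -> 0
  expect_equal(balancedMCC(ConfusionCounts(tp = 50, fp = 70, tn = 0, fn = 0)), 0)
  expect_error(balancedMCC(ConfusionCounts(tp = 0, fp = 5, tn = 5, fn = 0)),
               "both classes")
})

test_that("balanced MCC equals standard MCC on the class-replicated dataset", {
  withr::local_seed(11)
  for (cc in randomCounts(120)) {
    nA <- cc@tp + cc@fn; nI <- cc@fp + cc@tn
    # replicate every active row nI times and every inactive row nA times
    rep <- ConfusionCounts(tp = cc@tp * nI, fp = cc@fp * nA,
                           tn = cc@tn * nA, fn = cc@fn * nI)
    expect_equal(balancedMCC(cc), standardMCC(rep), tolerance = 1e-12)
  }
})

test_that("sampled filters draw k descriptors with decile-grid bounds", {
  dt <- smallTable()
  pool4 <- descriptorNames(dt)[1:4]
  f <- withr::with_seed(1, sampleFilter(pool4, dt))
  expect_setequal(f@descriptors, pool4)

  f1 <- withr::with_seed(9, sampleFilter(descriptorNames(dt), dt))
  f2 <- withr::with_seed(9, sampleFilter(descriptorNames(dt), dt))
  expect_equal(f1, f2)

  # bounds must belong to the deciles of the actives' values
  X <- descriptorMatrix(dt)
  act <- moleculeLabels(dt) == "active"
  for (j in seq_along(f1@descriptors)) {
    q <- unname(quantile(X[act, f1@descriptors[j]], probs = seq(0, 1, 0.1)))
    expect_true(any(abs(q - f1@low[j]) < 1e-12))
    expect_true(any(abs(q - f1@high[j]) < 1e-12))
  }
  expect_error(sampleFilter(pool4[1:2], dt), "smaller than k")
})

test_that("descriptor elimination removes the consistently worst scorers", {
  mk <- function(desc, mcc) {
    f <- RangeFilter(desc, low = rep(0, length(desc)), high = rep(1, length(desc)))
    f@mcc <- mcc
    f
  }
  pool <- c("bad", "g1", "g2", "g3", "g4", "g5", "g6", "g7")
  filters <- c(lapply(1:3, function(i) mk(c("bad", "g1", "g2", "g3"), 0)),
               lapply(1:5, function(i) mk(c("g4", "g5", "g6", "g7"), 0.9)),
               list(mk(c("g1", "g2", "g3", "g4"), 0.9)))
  out <- eliminateDescriptors(filters, pool, iseConfig(elimFraction = 0.25))
  expect_false("bad" %in% out)
  expect_length(out, 6)  # floor(0.25 * 8) = 2 removed

  # equal means: ties broken by name order, fraction still removed
  tied <- lapply(1:4, function(i) mk(c("a", "b", "c", "d"), 0.5))
  expect_error(eliminateDescriptors(tied, c("a", "b", "c", "d", "e"),
                                    iseConfig(elimFraction = 0.2)),
               "without any scored filter")
  out3 <- eliminateDescriptors(tied, c("a", "b", "c", "d"),
                               iseConfig(k = 3, elimFraction = 0.25))
  expect_identical(out3, c("b", "c", "d"))  # "a" first in name order

  # 20 descriptors at fraction 0.2 -> 16 remain
  pool20 <- sprintf("d%02d", 1:20)
  f20 <- lapply(seq(1, 20, 4), function(i) mk(pool20[i:(i + 3)], runif(1)))
  expect_length(eliminateDescriptors(f20, pool20, iseConfig(elimFraction = 0.2)),
                16)

  # refusal to shrink below k
  expect_identical(eliminateDescriptors(tied, c("a", "b", "c", "d"),
                                        iseConfig(elimFraction = 0.5, k = 4)),
                   c("a", "b", "c", "d"))
})

test_that("the exhaustive phase enumerates every k-subset", {
  dt <- smallTable()
  pool <- descriptorNames(dt)[1:5]
  scored <- exhaustivePhase(pool, dt, iseConfig(exhaustiveMax = 10))
  expect_length(scored, choose(5, 4))
  expect_length(exhaustivePhase(pool[1:4], dt, iseConfig(exhaustiveMax = 10)), 1)
  expect_length(exhaustivePhase(descriptorNames(dt)[1:6], dt,
                                iseConfig(exhaustiveMax = 20)), 15)
  expect_error(exhaustivePhase(descriptorNames(dt), dt,
                               iseConfig(exhaustiveMax = 10)), "exceeds")
  # every scored filter's counts total the class sizes
  for (f in scored) {
    expect_equal(f@counts@tp + f@counts@fn, 60)
    expect_equal(f@counts@fp + f@counts@tn, 300)
  }
})

test_that("near-duplicate filters collapse to the higher-MCC member", {
  # deterministic descriptor: values 1..1000 scaled to [0, 1]
  X <- matrix((1:1000) / 1000, 1000, 1, dimnames = list(NULL, "x"))
  dt <- DescriptorTable(X, labels = rep(c("active", "inactive"), c(200, 800)))
  mk <- function(hi, mcc) {
    f <- RangeFilter("x", low = 0, high = hi)
    f@mcc <- mcc
    f
  }
  a <- mk(0.5, 0.6); b <- mk(0.505, 0.5)   # agree on 995/1000 molecules
  expect_length(dedupFilters(list(a, b), dt, overlap = 0.99), 1)
  expect_equal(dedupFilters(list(a, b), dt, overlap = 0.99)[[1]]@high, 0.5)
  # byte-identical filters collapse too
  expect_length(dedupFilters(list(a, mk(0.5, 0.6)), dt, overlap = 0.99), 1)
  # filters disagreeing on half the molecules both survive
  cc <- mk(1.0, 0.4)
  expect_length(dedupFilters(list(a, cc), dt, overlap = 0.99), 2)
  # output is MCC-descending
  out <- dedupFilters(list(b, cc, a), dt, overlap = 0.9999)
  expect_true(!is.unsorted(rev(vapply(out, function(f) f@mcc, numeric(1)))))
})

test_that("model building is reproducible and validates its inputs", {
  dt <- smallTable()
  cfg <- iseConfig(filtersPerIteration = 100, seed = 21)
  m1 <- buildModel(dt, cfg)
  m2 <- buildModel(dt, cfg)
  expect_equal(m1, m2)
  # counts of every model filter total the class sizes
  for (f in modelFilters(m1)) {
    expect_equal(f@counts@tp + f@counts@fn, m1@nActives)
    expect_equal(f@counts@fp + f@counts@tn, m1@nInactives)
  }
  expect_error(buildModel(genDescriptorDataset(
    syntheticSpec(nActives = 20, nInactives = 20, nInformative = 2,
                  nNoise = 2, shift = 3, seed = 1)),
    iseConfig(k = 5)), "fewer descriptors")
})

test_that("classes drawn from one distribution yield no usable model", {
  null <- genDescriptorDataset(syntheticSpec(nActives = 80, nInactives = 400,
                                             nInformative = 0, nNoise = 10,
                                             shift = 0, seed = 6))
  res <- tryCatch(buildModel(null, iseConfig(filtersPerIteration = 100,
                                             seed = 2)),
                  error = function(e) e)
  if (is(res, "error")) {
    expect_match(conditionMessage(res), "no discriminating filter")
  } else {
    # anything surviving is overfit noise: weak in-sample MCC and no
    # out-of-sample ranking power
    expect_lt(max(vapply(modelFilters(res), function(f) f@mcc, numeric(1))),
              0.4)
    held <- genDescriptorDataset(syntheticSpec(nActives = 80,
                                               nInactives = 400,
                                               nInformative = 0, nNoise = 10,
                                               shift = 0, seed = 7))
    auc <- rocAndEnrichment(mbiScore(res, held)$mbi, moleculeLabels(held))$auc
    expect_equal(auc, 0.5, tolerance = 0.2)
  }
})

test_that("raising the band fraction never shrinks the model", {
  dt <- smallTable()
  narrow <- buildModel(dt, iseConfig(filtersPerIteration = 100, seed = 3,
                                     bandFraction = 0.1))
  wide <- buildModel(dt, iseConfig(filtersPerIteration = 100, seed = 3,
                                   bandFraction = 0.3))
  expect_gte(length(wide), length(narrow))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(iseConfig(elimFraction = 0), "elimFraction")
  expect_error(iseConfig(bandFraction = 1), "bandFraction")
  expect_error(iseConfig(dedupOverlap = 1.5), "dedupOverlap")
  expect_error(iseConfig(quantileProbs = c(0.5, 0.1)), "increasing")
  expect_equal(iseConfig(k = 5)$exhaustiveMax, choose(7, 5))
})
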