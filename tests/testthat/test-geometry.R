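# Minimal in-memory protein builder: one atom per row.
mkProtein <- function(resno, x, y = 0, z = 0, element = "C",
                      resid = "LEU", chain = "A") {
  n <- length(x)
  data.frame(key = paste(chain, resid, resno, sep = ":"),
             chain = chain, resid = resid, resno = resno,
             elety = element, element = element,
             x = x, y = rep(y, n)[seq_len(n)], z = rep(z, n)[seq_len(n)],
             het = FALSE, stringsAsFactors = FALSE)
}

test_that("residue-ligand distance is the minimum over heavy-atom pairs", {
  expect_equal(residueLigandDistance(rbind(c(0, 0, 0)), rbind(c(3, 0, 0))), 3)
  expect_equal(residueLigandDistance(rbind(c(0, 0, 0), c(10, 0, 0)),
                                     rbind(c(4, 0, 0))), 4)
  # 3x3 constructed case against brute force over all 9 pairs
  withr::local_seed(2)
  A <- matrix(rnorm(9), 3, 3); B <- matrix(rnorm(9), 3, 3)
  brute <- min(apply(A, 1, function(a)
    apply(B, 1, function(b) sqrt(sum((a - b)^2)))))
  expect_equal(residueLigandDistance(A, B), brute, tolerance = 1e-12)
})

test_that("contacts are typed by the 3.3 / 3.9 Angstrom rules", {
  lig <- list(coords = rbind(c(0, 0, 0)), elements = "N")
  # receptor O at 3.2 A from ligand N: hydrogen bond (and so vdw)
  p <- mkProtein(1, x = 3.2, element = "O")
  prof <- contactProfile(p, lig)
  expect_true(prof$hbond); expect_true(prof$vdw)
  # receptor C at 3.8 A: vdw only
  prof2 <- contactProfile(mkProtein(2, x = 3.8, element = "C"), lig)
  expect_false(prof2$hbond); expect_true(prof2$vdw)
  # nearest pair at 4.1 A: no contact
  prof3 <- contactProfile(mkProtein(3, x = 4.1, element = "O"), lig)
  expect_false(prof3$hbond); expect_false(prof3$vdw)
  # N/O pair beyond 3.3 but inside 3.9: vdw without hbond
  prof4 <- contactProfile(mkProtein(4, x = 3.5, element = "O"), lig)
  expect_false(prof4$hbond); expect_true(prof4$vdw)
})

test_that("an H-bond contact always implies a vdw contact", {
  withr::local_seed(3)
  for (i in 1:30) {
    p <- mkProtein(1:4, x = runif(4, 2.5, 5),
                   element = sample(c("C", "N", "O"), 4, replace = TRUE))
    lig <- list(coords = rbind(c(0, 0, 0)),
                elements = sample(c("C", "N", "O"), 1))
    prof <- contactProfile(p, lig)
    expect_true(all(!prof$hbond | prof$vdw))
  }
})

test_that("consensus residues follow the contact-count and H-bond rules", {
  # 5 reference complexes; profiles keyed by residue
  mkProfile <- function(hb, vdw) {
    data.frame(key = sprintf("A:RES:%d", seq_along(hb)),
               minDist = 3, hbond = hb, vdw = vdw | hb,
               stringsAsFactors = FALSE)
  }
  # residue 1: H-bonds all 5 -> crucial; residue 2: vdw in 4, no H-bond ->
  # important only; residue 3: contacts 2 of 5 -> neither
  profiles <- lapply(1:5, function(i)
    mkProfile(hb = c(TRUE, FALSE, FALSE),
              vdw = c(TRUE, i <= 4, i <= 2)))
  crit <- deriveConsensusResidues(profiles, minImportant = 1)
  expect_identical(crit@crucial, "A:RES:1")
  expect_setequal(crit@important, c("A:RES:1", "A:RES:2"))
  # residue H-bonding one ligand only is still important
  profiles2 <- lapply(1:5, function(i)
    mkProfile(hb = c(TRUE, i == 1, FALSE), vdw = c(TRUE, i == 1, i <= 2)))
  crit2 <- deriveConsensusResidues(profiles2, minImportant = 1)
  expect_true("A:RES:2" %in% crit2@important)
  expect_false("A:RES:2" %in% crit2@crucial)
  # fraction rule: >= 70% of ligands
  crit3 <- deriveConsensusResidues(profiles, rule = "fraction",
                                   minImportant = 1)
  expect_setequal(crit3@important, c("A:RES:1", "A:RES:2"))
  # empty crucial set warns
  profiles4 <- lapply(1:2, function(i)
    mkProfile(hb = c(FALSE, FALSE, FALSE), vdw = c(TRUE, TRUE, TRUE)))
  expect_warning(deriveConsensusResidues(profiles4, minImportant = 1),
                 "crucial")
})

test_that("pose acceptance needs 2 crucial under 3.5 and 7 important under 5", {
  # 2 crucial + 7 important residues on the x axis, pose atom at origin
  mk <- function(dCru, dImp) {
    rbind(mkProtein(1:2, x = dCru, resid = "HIS", element = "O"),
          mkProtein(3:9, x = dImp, resid = "LEU"))
  }
  crit <- GeometryCriteria(crucial = c("A:HIS:1", "A:HIS:2"),
                           important = c("A:HIS:1", "A:HIS:2",
                                         sprintf("A:LEU:%d", 3:9)),
                           minImportant = 7)
  pose <- rbind(c(0, 0, 0))
  expect_true(as.logical(posePasses(pose, mk(3.4, 4.9), crit)))
  # only 1 crucial close enough
  p2 <- rbind(mkProtein(1, x = 3.4, resid = "HIS", element = "O"),
              mkProtein(2, x = 3.6, resid = "HIS", element = "O"),
              mkProtein(3:9, x = 4.9, resid = "LEU"))
  v2 <- posePasses(pose, p2, crit)
  expect_false(as.logical(v2))
  expect_equal(attr(v2, "nCrucial"), 1)
  expect_equal(attr(v2, "nImportant"), 9)  # both HIS also inside 5.0
  # only 6 important close enough (both crucial fine)
  p3 <- rbind(mkProtein(1:2, x = 3.0, resid = "HIS", element = "O"),
              mkProtein(3:6, x = 4.5, resid = "LEU"),
              mkProtein(7:9, x = 6.0, resid = "LEU"))
  expect_false(as.logical(posePasses(pose, p3, crit)))
  # strict inequality at the boundary
  p4 <- mk(3.5, 4.9)
  expect_false(as.logical(posePasses(pose, p4, crit)))
})

test_that("molecule verdicts pick the lowest-energy passing pose", {
  protein <- rbind(mkProtein(1:2, x = 3.0, resid = "HIS", element = "O"),
                   mkProtein(3:9, x = 4.5, resid = "LEU"))
  crit <- GeometryCriteria(crucial = c("A:HIS:1", "A:HIS:2"),
                           important = c("A:HIS:1", "A:HIS:2",
                                         sprintf("A:LEU:%d", 3:9)),
                           minImportant = 7)
  passPose <- matrix(c(0, 0, 0), 1)        # at the origin: passes
  failPose <- matrix(c(50, 0, 0), 1)       # far away: fails
  ps <- PoseSet(list(passPose, passPose, failPose),
                rep(list("C"), 3), energy = c(-8, -10, -20))
  v <- moleculeDockVerdict(ps, protein, crit)
  expect_true(v$accepted)
  expect_identical(v$pose, "pose002")      # -10 beats -8; -20 fails
  expect_equal(v$nPassing, 2L)
  # no passing pose: rejected
  v2 <- moleculeDockVerdict(PoseSet(list(failPose, failPose),
                                    rep(list("C"), 2), c(-8, -9)),
                            protein, crit)
  expect_false(v2$accepted)
  expect_identical(v2$pose, NA_character_)
  # a single passing pose is selected
  v3 <- moleculeDockVerdict(PoseSet(list(passPose), list("C"), -5),
                            protein, crit)
  expect_true(v3$accepted); expect_identical(v3$pose, "pose001")
  # tie on energy: lowest pose index wins
  v4 <- moleculeDockVerdict(PoseSet(list(passPose, passPose),
                                    rep(list("C"), 2), c(-7, -7)),
                            protein, crit)
  expect_identical(v4$pose, "pose001")
  # more than 30 poses: truncated to the best energies, with a warning
  many <- PoseSet(rep(list(failPose), 31), rep(list("C"), 31),
                  energy = seq(-31, -1))
  expect_warning(moleculeDockVerdict(many, protein, crit), "truncating")
})

test_that("consensus voting accepts only sufficiently replicated hits", {
  v <- matrix(c(TRUE, TRUE, TRUE,
                TRUE, TRUE, FALSE,
                TRUE, FALSE, FALSE), 3, byrow = TRUE,
              dimnames = list(c("m1", "m2", "m3"), NULL))
  all3 <- consensusVote(v)                 # default: all structures
  expect_identical(all3$accepted, c(TRUE, FALSE, FALSE))
  expect_identical(all3$votes, c(3L, 2L, 1L))
  any1 <- consensusVote(v, required = 1)
  expect_true(all(any1$accepted))
  # monotone in `required`
  for (r in 1:2)
    expect_true(all(consensusVote(v, r + 1)$accepted <=
                    consensusVote(v, r)$accepted))
  # tally reports the 3/2/1 breakdown
  expect_equal(as.integer(attr(all3, "tally")), c(1L, 1L, 1L, 0L))
})

test_that("criteria configs roundtrip through the text format", {
  crit <- GeometryCriteria(crucial = c("A:HIS:323", "A:TYR:473"),
                           important = c("A:HIS:323", "A:TYR:473",
                                         "A:THR:288", "A:LEU:330"),
                           minImportant = 3, dImportant = 4.5)
  tf <- withr::local_tempfile(fileext = ".cfg")
  writeGeometryCriteria(crit, tf)
  crit2 <- readGeometryCriteria(tf)
  expect_setequal(crit2@crucial, crit@crucial)
  expect_setequal(crit2@important, crit@important)
  expect_equal(crit2@dImportant, 4.5)
  expect_equal(crit2@minImportant, 3)
})
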