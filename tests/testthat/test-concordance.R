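# Trio Mendelian matching, Descent Accuracy, transmission phase and Method
# Agreement.

test_that("trio matching explains child alleles under one-allele-per-parent", {
  ch <- aCall("c", "A", c("A*02:01", "A*01:01"))
  mo <- aCall("m", "A", c("A*02:01", "A*03:01"))
  fa <- aCall("f", "A", c("A*01:01", "A*11:01"))
  m <- matchTrioLocus(ch, mo, fa)
  expect_equal(m@nEq, 2L)
  expect_false(m@ambiguous)
  asg <- m@assignment
  expect_equal(asg$parent[asg$child_allele == "A*02:01"], "mother")
  expect_equal(asg$parent[asg$child_allele == "A*01:01"], "father")

  # homozygous child: both slots explained only if both parents carry it
  hom <- matchTrioLocus(aCall("c", "A", c("A*02:01", "A*02:01")),
                        mo, aCall("f", "A", c("A*24:02", "A*11:01")))
  expect_equal(hom@nEq, 1L)
  expect_false(hom@ambiguous)
  both <- matchTrioLocus(aCall("c", "A", c("A*02:01", "A*02:01")),
                         mo, aCall("f", "A", c("A*02:01", "A*11:01")))
  expect_equal(both@nEq, 2L)

  # either child allele could come from the mother, but not both
  amb <- matchTrioLocus(aCall("c", "A", c("A*02:01", "A*03:01")),
                        aCall("m", "A", c("A*02:01", "A*03:01")),
                        aCall("f", "A", c("A*24:02", "A*11:01")))
  expect_equal(amb@nEq, 1L)
  expect_true(amb@ambiguous)

  # the relaxed rule credits both alleles to the same parent
  lax <- matchTrioLocus(aCall("c", "A", c("A*02:01", "A*03:01")),
                        aCall("m", "A", c("A*02:01", "A*03:01")),
                        aCall("f", "A", c("A*24:02", "A*11:01")),
                        requireDistinctParents = FALSE)
  expect_equal(lax@nEq, 2L)

  expect_error(matchTrioLocus(ch, mo, aCall("f", "B", c("B*07:02", "B*08:01"))),
               "locus mismatch")
})

test_that("matching works after reduction: an 8-digit call can explain a 4-digit child", {
  ch <- aCall("c", "A", c("A*02:01", "A*01:01"))
  mo <- aCall("m", "A", c("A*02:01:01:02", "A*03:01:01"))
  fa <- aCall("f", "A", c("A*01:01:01", "A*11:01"))
  expect_equal(matchTrioLocus(ch, mo, fa, resolution = 4)@nEq, 2L)
  expect_equal(matchTrioLocus(ch, mo, fa, resolution = 8)@nEq, 0L)
  # at 2 digits serotype groups suffice
  expect_equal(matchTrioLocus(aCall("c", "A", c("A*02:05", "A*01:08")),
                              mo, fa, resolution = 2)@nEq, 2L)
})

test_that("trio matching agrees with the exhaustive transmission oracle", {
  alleles <- paste0("A*0", 1:3, ":01")
  genos <- allGenotypes(alleles)
  for (ci in seq_along(genos)) {
    for (mi in seq_along(genos)) {
      for (fi in seq_along(genos)) {
        m <- matchTrioLocus(aCall("c", "A", genos[[ci]]),
                            aCall("m", "A", genos[[mi]]),
                            aCall("f", "A", genos[[fi]]))
        expect_identical(m@nEq,
                         trioOracle(sort(genos[[ci]]), genos[[mi]],
                                    genos[[fi]]),
                         label = sprintf("trio %d/%d/%d", ci, mi, fi))
      }
    }
  }
})

test_that("descent accuracy counts explained child alleles per locus", {
  # 1 trio, 3 loci: five child alleles explained, one not -> DA = 5/6
  cohort <- makeCohort(list(fam1 = list(
    father = list(A = c("A*01:01", "A*11:01"), B = c("B*07:02", "B*08:01"),
                  C = c("C*07:01", "C*05:01")),
    mother = list(A = c("A*02:01", "A*03:01"), B = c("B*44:02", "B*15:01"),
                  C = c("C*07:02", "C*06:02")),
    child = list(A = c("A*02:01", "A*01:01"), B = c("B*07:02", "B*44:02"),
                 C = c("C*07:01", "C*12:03")))))
  da <- descentAccuracy(cohort, "test")
  expect_equal(da@nEq, 5L)
  expect_equal(da@nAlleles, 6L)
  expect_equal(daOverall(da), 5 / 6)
  expect_equal(unname(daPerLocus(da)), c(1, 1, 0.5))
  # denominator identity: N_alleles = N_children x 2 x |loci|
  expect_equal(da@nAlleles, da@nChildren * 2L * length(da@loci))
  expect_equal(daOverall(da) * da@nAlleles, da@nEq)

  # perfectly transmitted cohort
  perfect <- makeCohort(list(fam1 = list(
    father = list(A = c("A*01:01", "A*11:01")),
    mother = list(A = c("A*02:01", "A*03:01")),
    child = list(A = c("A*02:01", "A*01:01")))))
  expect_equal(daOverall(descentAccuracy(perfect, "test")), 1)
})

test_that("descent accuracy excludes incomplete families and missing calls, never silently", {
  fams <- list(
    fam1 = list(father = list(A = c("A*01:01", "A*11:01")),
                mother = list(A = c("A*02:01", "A*03:01")),
                child = list(A = c("A*02:01", "A*01:01"))),
    fam2 = list(father = list(A = c("A*01:01", "A*11:01")),
                mother = list(A = c("A*02:01", "A*03:01"))))  # no child
  cohort <- makeCohort(fams)
  expect_equal(incompleteFamilies(cohort), "fam2")
  da <- descentAccuracy(cohort, "test")
  expect_equal(da@nChildren, 1L)

  # complete family but a missing locus call for the father
  fams3 <- list(
    fam1 = list(father = list(A = c("A*01:01", "A*11:01")),
                mother = list(A = c("A*02:01", "A*03:01"),
                              B = c("B*07:02", "B*08:01")),
                child = list(A = c("A*02:01", "A*01:01"),
                             B = c("B*07:02", "B*15:01"))))
  coh3 <- makeCohort(fams3)
  da3 <- descentAccuracy(coh3, "test")
  expect_equal(da3@excluded$locus, "B")
  expect_match(da3@excluded$reason, "father")
  expect_equal(da3@nAlleles, 2L)  # only locus A evaluated

  onlyIncomplete <- makeCohort(list(
    fam2 = list(father = list(A = c("A*01:01", "A*11:01")))))
  expect_error(descentAccuracy(onlyIncomplete, "test"), "no evaluable")
})

test_that("descent accuracy on random cohorts equals the brute-force oracle", {
  set.seed(11)
  alleles <- sprintf("A*%02d:01", 1:10)
  for (rep in 1:10) {
    fams <- list()
    truthEq <- 0L
    for (f in 1:5) {
      mo <- sample(alleles, 2, replace = TRUE)
      fa <- sample(alleles, 2, replace = TRUE)
      ch <- sample(alleles, 2, replace = TRUE)
      fams[[sprintf("fam%d", f)]] <- list(
        father = list(A = fa), mother = list(A = mo), child = list(A = ch))
      truthEq <- truthEq + trioOracle(sort(ch), mo, fa)
    }
    da <- descentAccuracy(makeCohort(fams), "test")
    expect_equal(da@nEq, truthEq)
    expect_equal(da@nAlleles, 10L)
  }
})

test_that("DA is invariant under family relabelling", {
  set.seed(5)
  alleles <- sprintf("A*%02d:01", 1:6)
  fams <- lapply(1:6, function(f) list(
    father = list(A = sample(alleles, 2, replace = TRUE)),
    mother = list(A = sample(alleles, 2, replace = TRUE)),
    child = list(A = sample(alleles, 2, replace = TRUE))))
  names(fams) <- sprintf("fam%d", 1:6)
  da1 <- descentAccuracy(makeCohort(fams), "test")
  names(fams) <- sprintf("zz%d", 6:1)
  da2 <- descentAccuracy(makeCohort(rev(fams)), "test")
  expect_equal(daOverall(da1), daOverall(da2))
})

test_that("transmission classification marks transmitted and unresolved slots", {
  cohort <- makeCohort(list(fam1 = list(
    father = list(A = c("A*01:01", "A*11:01")),
    mother = list(A = c("A*02:01", "A*03:01")),
    child = list(A = c("A*02:01", "A*01:01")))))
  phase <- classifyTransmission(cohort, "fam1", "test")
  moRows <- phase[phase$role == "mother", ]
  expect_equal(moRows$status[moRows$allele == "A*02:01"], "transmitted")
  expect_equal(moRows$status[moRows$allele == "A*03:01"], "non_transmitted")
  faRows <- phase[phase$role == "father", ]
  expect_equal(faRows$status[faRows$allele == "A*01:01"], "transmitted")

  # homozygous mother: first slot transmitted by tie-break, flagged
  homMo <- makeCohort(list(fam1 = list(
    father = list(A = c("A*01:01", "A*11:01")),
    mother = list(A = c("A*02:01", "A*02:01")),
    child = list(A = c("A*02:01", "A*01:01")))))
  ph <- classifyTransmission(homMo, "fam1", "test")
  mo <- ph[ph$role == "mother", ]
  expect_equal(mo$status[mo$slot == 1], "transmitted")
  expect_equal(mo$status[mo$slot == 2], "non_transmitted")
  expect_true(all(mo$slot_ambiguous))

  # fully inconsistent locus: everything unresolved
  bad <- makeCohort(list(fam1 = list(
    father = list(A = c("A*01:01", "A*11:01")),
    mother = list(A = c("A*02:01", "A*03:01")),
    child = list(A = c("A*24:02", "A*26:01")))))
  phBad <- classifyTransmission(bad, "fam1", "test")
  expect_true(all(phBad$status == "unresolved"))

  # ambiguous maximal assignments: unresolved
  amb <- makeCohort(list(fam1 = list(
    father = list(A = c("A*24:02", "A*11:01")),
    mother = list(A = c("A*02:01", "A*03:01")),
    child = list(A = c("A*02:01", "A*03:01")))))
  phAmb <- classifyTransmission(amb, "fam1", "test")
  expect_true(all(phAmb$status == "unresolved"))

  incomplete <- makeCohort(list(
    fam2 = list(father = list(A = c("A*01:01", "A*11:01")))))
  expect_error(classifyTransmission(incomplete, "fam2", "test"),
               "not a complete trio")
})

test_that("pair agreement uses multiset semantics and matches the pairing oracle", {
  expect_equal(alleleAgreement(c("A*02:01", "A*01:01"),
                               c("A*02:01", "A*03:01")), 1L)
  expect_equal(alleleAgreement(c("A*02:01", "A*02:01"),
                               c("A*02:01", "A*01:01")), 1L)
  expect_equal(alleleAgreement(c("A*02:01", "A*01:01"),
                               c("A*01:01", "A*02:01")), 2L)
  expect_equal(alleleAgreement(c("A*02:01:01:02", "A*01:01"),
                               c("A*02:01", "A*03:01"), resolution = 4), 1L)
  # exhaustive: every pair of unordered genotypes over three alleles
  genos <- allGenotypes(paste0("A*0", 1:3, ":01"))
  for (a in genos) {
    for (b in genos) {
      expect_identical(alleleAgreement(a, b), pairingOracle(sort(a), sort(b)),
                       label = paste(paste(a, collapse = "/"), "vs",
                                     paste(b, collapse = "/")))
    }
  }
})

test_that("method agreement is a symmetric per-allele rate with exact denominators", {
  mk <- function(childB) list(
    father = list(A = c("A*01:01", "A*11:01"), B = c("B*07:02", "B*08:01")),
    mother = list(A = c("A*02:01", "A*03:01"), B = c("B*44:02", "B*15:01")),
    child = list(A = c("A*02:01", "A*01:01"), B = childB))
  cohortA <- makeCohort(list(fam1 = mk(c("B*07:02", "B*44:02"))), "m1")
  cohortB <- makeCohort(list(fam1 = mk(c("B*07:02", "B*07:05"))), "m2")
  cohort <- TrioCohort(cohortSamples(cohortA),
                       rbind(cohortTypings(cohortA), cohortTypings(cohortB)))
  ma <- methodAgreement(cohort, "m1", "m2")
  # 3 samples x 2 loci x 2 alleles = 12 slots; child B disagrees in one
  expect_equal(ma@nPopulation, 3L)
  expect_equal(ma@nAgree, 11L)
  expect_equal(maTotal(ma), 11 / 12)
  sym <- methodAgreement(cohort, "m2", "m1")
  expect_equal(maTotal(sym), maTotal(ma))
  expect_equal(sum(ma@perIndividual$n_agree), ma@nAgree)
  expect_true(all(ma@perIndividual$n_agree <= 2 * length(cohortLoci(cohort))))
  hist <- agreementHistogram(ma)
  expect_equal(sum(hist$n_individuals), ma@nPopulation)

  expect_error(methodAgreement(cohort, "m1", "m1"), "different")
})

test_that("identical typings give MA_total = MA_T = MA_NT = 1", {
  cohortA <- makeCohort(list(fam1 = list(
    father = list(A = c("A*01:01", "A*11:01")),
    mother = list(A = c("A*02:01", "A*03:01")),
    child = list(A = c("A*02:01", "A*01:01")))), "m1")
  typB <- cohortTypings(cohortA)
  typB$method <- "m2"
  cohort <- TrioCohort(cohortSamples(cohortA),
                       rbind(cohortTypings(cohortA), typB))
  ma <- methodAgreement(cohort, "m1", "m2")
  expect_equal(maTotal(ma), 1)
  expect_equal(maTransmitted(ma), 1)
  expect_equal(maNonTransmitted(ma), 1)
  expect_equal(ma@nUnresolvedSlots, 0L)
  expect_equal(ma@perIndividual$n_agree,
               rep(2L * length(cohortLoci(cohort)), 3L))
})

test_that("the transmitted/non-transmitted split partitions resolved parent slots", {
  set.seed(23)
  cfg <- simulationConfig(nFamilies = 12, seed = 23,
                          methods = list(errorModel("obs", miscallRate = 0.1,
                                                    homozygoteInflationRate = 0.05)))
  coh <- mergedCohort(simulateBenchmark(cfg))
  ma <- methodAgreement(coh, "truth", "obs", resolution = 4,
                        phaseReference = "truth")
  p <- ma@perLocus
  # slot classes are disjoint and, with child slots, cover all non-unresolved
  total <- 2L * ma@nPopulation * length(ma@loci)
  expect_equal(sum(p$n_slots_t) + sum(p$n_slots_nt) + ma@nUnresolvedSlots,
               total)
  expect_true(all(p$n_agree_t <= p$n_slots_t))
  expect_true(all(p$n_agree_nt <= p$n_slots_nt))
  expect_true(ma@maT >= 0 && ma@maT <= 1)
  expect_true(ma@maNT >= 0 && ma@maNT <= 1)
})

test_that("samples typed by only one method are excluded and logged", {
  fams <- list(fam1 = list(
    father = list(A = c("A*01:01", "A*11:01")),
    mother = list(A = c("A*02:01", "A*03:01")),
    child = list(A = c("A*02:01", "A*01:01"))))
  cohortA <- makeCohort(fams, "m1")
  typB <- cohortTypings(cohortA)
  typB$method <- "m2"
  typB <- typB[typB$sample_id != "fam1_child", ]  # child untyped by m2
  cohort <- TrioCohort(cohortSamples(cohortA),
                       rbind(cohortTypings(cohortA), typB))
  ma <- methodAgreement(cohort, "m1", "m2")
  expect_equal(ma@nPopulation, 2L)
  expect_equal(ma@excludedSamples, "fam1_child")
})
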