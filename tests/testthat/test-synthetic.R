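# Synthetic trio-cohort simulator: configuration, truth generation, error
# operators and reproducibility.

test_that("configurations validate rates, pools and labels", {
  expect_error(errorModel("m", miscallRate = 1.2), "\\[0, 1\\]")
  expect_error(errorModel("m", homozygoteInflationRate = -0.1), "\\[0, 1\\]")
  expect_error(errorModel("m", outputResolution = 6), "4 or 8")
  expect_error(errorModel(""), "label")
  expect_error(simulationConfig(nFamilies = 0), "at least 1")
  expect_error(simulationConfig(methods = list(errorModel("a"),
                                               errorModel("a"))),
               "unique")
  badPool <- list(A = list(alleles = c("A*01:01", "A*02:01"),
                           frequencies = c(0.6, 0.6)))
  expect_error(simulationConfig(loci = "A", allelePool = badPool),
               "sum to 1")
  onePool <- list(A = list(alleles = "A*01:01:01:01", frequencies = 1))
  expect_error(simulationConfig(loci = "A", allelePool = onePool,
                                methods = list(errorModel("m", miscallRate = 0.5))),
               "pool of >= 2")
  # a single-allele pool is fine when nothing miscalls from the pool
  cfg <- simulationConfig(nFamilies = 3, loci = "A", allelePool = onePool,
                          methods = list(errorModel("m", miscallRate = 0,
                                                    homozygoteInflationRate = 0)))
  expect_s4_class(simulateTruthCohort(cfg), "TrioCohort")
})

test_that("YAML configurations round-trip through the reader", {
  path <- system.file("extdata", "sim_config_example.yaml",
                      package = "HLAtrio")
  cfg <- readSimulationConfig(path)
  expect_equal(cfg$nFamilies, 20L)
  expect_equal(cfg$loci, c("A", "B", "C"))
  expect_equal(cfg$seed, 7L)
  expect_named(cfg$methods, c("cleanTyper", "noisyTyper"))
  expect_equal(cfg$methods$noisyTyper$outputResolution, 8L)
  expect_equal(cfg$methods$cleanTyper$miscallRate, 0)
})

test_that("identical config and seed reproduce byte-identical outputs", {
  cfg <- simulationConfig(nFamilies = 8, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSimulatedCohort(simulateBenchmark(cfg), d1)
  writeSimulatedCohort(simulateBenchmark(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the cohort
  cfg2 <- simulationConfig(nFamilies = 8, seed = 100)
  t1 <- cohortTypings(simulateTruthCohort(cfg))
  t2 <- cohortTypings(simulateTruthCohort(cfg2))
  expect_false(identical(t1, t2))
})

test_that("truth cohorts are Mendelian-consistent with HWE founders", {
  cfg <- simulationConfig(nFamilies = 30, seed = 17)
  truth <- simulateTruthCohort(cfg)
  for (r in c(2L, 4L, 8L))
    expect_equal(daOverall(descentAccuracy(truth, "truth", r)), 1)

  # degenerate frequency vector: every individual homozygous
  mono <- simulationConfig(nFamilies = 5, loci = "A",
    allelePool = list(A = list(alleles = "A*01:01:01:01", frequencies = 1)),
    methods = list(errorModel("m", miscallRate = 0,
                              homozygoteInflationRate = 0)), seed = 1)
  coh <- simulateTruthCohort(mono)
  expect_equal(hrOverall(homozygosityRate(coh, "truth", 8)), 1)

  # p = (0.5, 0.5): parental HR near 0.5 (binomial SE)
  bi <- simulationConfig(nFamilies = 250, loci = "A",
    allelePool = list(A = list(alleles = c("A*01:01:01:01", "A*02:01:01:01"),
                               frequencies = c(0.5, 0.5))),
    methods = list(errorModel("m", miscallRate = 0,
                              homozygoteInflationRate = 0)), seed = 5)
  hr <- hrOverall(homozygosityRate(simulateTruthCohort(bi), "truth", 8))
  expect_lt(abs(hr - 0.5), 3 * sqrt(0.25 / 500))
})

test_that("error-free models reproduce the reduced truth exactly", {
  cfg <- simulationConfig(nFamilies = 10, seed = 3,
                          methods = list(errorModel("clean", miscallRate = 0,
                                                    homozygoteInflationRate = 0,
                                                    outputResolution = 4)))
  sim <- simulateBenchmark(cfg)
  expect_equal(nrow(sim@provenance), 0L)
  coh <- mergedCohort(sim)
  expect_equal(maTotal(methodAgreement(coh, "truth", "clean", 4)), 1)
  # two identical error configs agree perfectly with each other
  cfg2 <- simulationConfig(nFamilies = 10, seed = 3,
                           methods = list(errorModel("clean", miscallRate = 0,
                                                     homozygoteInflationRate = 0),
                                          errorModel("clean2", miscallRate = 0,
                                                     homozygoteInflationRate = 0)))
  coh2 <- mergedCohort(simulateBenchmark(cfg2))
  expect_equal(maTotal(methodAgreement(coh2, "clean", "clean2", 4)), 1)
})

test_that("forced miscalls in a two-allele pool flip every slot", {
  pool <- list(A = list(alleles = c("A*01:01:01:01", "A*02:01:01:01"),
                        frequencies = c(0.5, 0.5)))
  cfg <- simulationConfig(nFamilies = 6, loci = "A", allelePool = pool,
                          seed = 21,
                          methods = list(errorModel("flip", miscallRate = 1,
                                                    serotypePreservingFraction = 0,
                                                    homozygoteInflationRate = 0,
                                                    outputResolution = 8)))
  sim <- simulateBenchmark(cfg)
  truth <- cohortTypings(sim@truth)
  obs <- cohortTypings(sim@observed$flip)
  other <- function(x) ifelse(x == "A*01:01:01:01", "A*02:01:01:01",
                              "A*01:01:01:01")
  key <- function(d) paste(d$sample_id, d$locus)
  obs <- obs[match(key(truth), key(obs)), ]
  # each slot flipped to the other allele; pairs re-sorted canonically
  expect_equal(paste(obs$allele1, obs$allele2),
               paste(pmin(other(truth$allele1), other(truth$allele2)),
                     pmax(other(truth$allele1), other(truth$allele2))))
  # flipping both slots maps a heterozygous pair onto itself (unordered),
  # so agreement comes exactly from the heterozygous truth calls
  het <- truth$allele1 != truth$allele2
  expect_equal(maTotal(methodAgreement(mergedCohort(sim), "truth", "flip", 8)),
               mean(het))
})

test_that("serotype-preserving miscalls stay within the 2-digit group", {
  cfg <- simulationConfig(nFamilies = 40, seed = 9,
                          methods = list(errorModel("sero", miscallRate = 0.3,
                                                    serotypePreservingFraction = 1,
                                                    homozygoteInflationRate = 0,
                                                    outputResolution = 8)))
  sim <- simulateBenchmark(cfg)
  prov <- sim@provenance
  sero <- prov[prov$operator == "miscall_serotype", ]
  expect_gt(nrow(sero), 0L)
  same2 <- function(x, y) {
    formatHLAAllele(serotypeGroup(parseHLAAllele(x))) ==
      formatHLAAllele(serotypeGroup(parseHLAAllele(y)))
  }
  expect_true(all(mapply(same2, sero$original, sero$replacement)))
  expect_true(all(sero$original != sero$replacement))
})

test_that("provenance covers every call that differs from the reduced truth", {
  cfg <- simulationConfig(nFamilies = 25, seed = 41,
                          methods = list(errorModel("obs", miscallRate = 0.1,
                                                    homozygoteInflationRate = 0.1,
                                                    outputResolution = 4)))
  sim <- simulateBenchmark(cfg)
  truth <- cohortTypings(sim@truth)
  obs <- cohortTypings(sim@observed$obs)
  key <- function(d) paste(d$sample_id, d$locus)
  obs <- obs[match(key(truth), key(obs)), ]
  reduce2 <- function(a1, a2) {
    k1 <- formatHLAAllele(reduceAllele(parseHLAAllele(a1), 4))
    k2 <- formatHLAAllele(reduceAllele(parseHLAAllele(a2), 4))
    paste(pmin(k1, k2), pmax(k1, k2))
  }
  differs <- reduce2(truth$allele1, truth$allele2) !=
    paste(obs$allele1, obs$allele2)
  provKeys <- unique(paste(sim@provenance$sample_id[sim@provenance$changed_call],
                           sim@provenance$locus[sim@provenance$changed_call]))
  expect_setequal(key(truth)[differs], provKeys)
})

test_that("per-slot miscall provenance matches the configured rate", {
  eps <- 0.08
  cfg <- simulationConfig(nFamilies = 300, seed = 77,
                          methods = list(errorModel("obs", miscallRate = eps,
                                                    homozygoteInflationRate = 0,
                                                    outputResolution = 8)))
  sim <- simulateBenchmark(cfg)
  slots <- 300 * 3 * 3 * 2   # families x members x loci x slots
  nMiscall <- sum(grepl("^miscall", sim@provenance$operator))
  se <- sqrt(eps * (1 - eps) * slots)
  expect_lt(abs(nMiscall - eps * slots), 3 * se)
})

test_that("homozygote inflation raises measured HR; miscalls lower MA", {
  base <- function(eta, label) {
    cfg <- simulationConfig(nFamilies = 150, seed = 55,
                            methods = list(errorModel(label, miscallRate = 0,
                                                      homozygoteInflationRate = eta,
                                                      outputResolution = 8)))
    mergedCohort(simulateBenchmark(cfg))
  }
  coh0 <- base(0, "obs")
  coh3 <- base(0.3, "obs")
  expect_gt(hrOverall(homozygosityRate(coh3, "obs", 8)),
            hrOverall(homozygosityRate(coh0, "obs", 8)))
  # a noisier typer agrees less with the truth
  noisy <- function(eps) {
    cfg <- simulationConfig(nFamilies = 60, seed = 56,
                            methods = list(errorModel("obs", miscallRate = eps,
                                                      homozygoteInflationRate = 0)))
    maTotal(methodAgreement(mergedCohort(simulateBenchmark(cfg)),
                            "truth", "obs", 4))
  }
  expect_gt(noisy(0.02), noisy(0.25))
})
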