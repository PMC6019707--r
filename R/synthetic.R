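# Synthetic trio-cohort simulator.
#
# Ground truth: per locus, founder (parent) alleles are drawn i.i.d. from a
# configured frequency vector (Hardy-Weinberg equilibrium), and each child
# receives one uniformly chosen allele from each parent. Observed typings
# perturb the truth with typer error operators modelled on the failure
# modes reported for real typers: homozygote inflation (a heterozygous
# call collapsed onto one of its alleles), serotype-preserving miscalls
# (replacement within the same 2-digit group), random miscalls, and
# resolution truncation of the output.
#
# Determinism: every random decision draws from a stream seeded by a hash
# of (seed, stream label, sample, locus), so results are reproducible and
# independent of iteration order.

# deterministic 31-bit string hash (polynomial rolling hash)
.callSeed <- function(...) {
  s <- paste(..., sep = "\r")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

#' Typer error model for the simulator
#'
#' Describes one synthetic typing method: with probability \code{eta} a
#' heterozygous call is replaced by a homozygous call on one of its alleles
#' (chosen uniformly); then each allele slot is independently miscalled
#' with probability \code{epsilon} — with probability \code{sigma} the
#' replacement is a different pool allele from the same 2-digit serotype
#' group (falling back to any other pool allele when the group has no
#' alternative), otherwise a uniformly chosen different allele; finally the
#' call is truncated to \code{outputResolution}. The default rates
#' (\code{epsilon} 0.05, \code{sigma} 0.5, \code{eta} 0.02) are
#' illustrative only: they mimic the reported failure phenomenology
#' qualitatively, not any measured rate.
#'
#' @param label method label for the perturbed typings.
#' @param miscallRate epsilon, per-slot miscall probability in [0, 1].
#' @param serotypePreservingFraction sigma, fraction of miscalls that stay
#'   within the 2-digit serotype group.
#' @param homozygoteInflationRate eta, per-call probability of collapsing a
#'   heterozygote.
#' @param outputResolution resolution of the emitted calls (4 or 8).
#' @param roles pedigree roles subjected to errors; others are passed
#'   through (only truncated).
#' @param replacement \code{"pool"} draws replacements from the allele
#'   pool; \code{"novel"} invents identifiers outside the pool, so a
#'   miscalled allele can never be explained by inheritance — useful for
#'   calibration experiments with a known expected Descent Accuracy.
#' @return an error-model configuration list.
#' @export
errorModel <- function(label, miscallRate = 0.05,
                       serotypePreservingFraction = 0.5,
                       homozygoteInflationRate = 0.02,
                       outputResolution = 4L,
                       roles = c("father", "mother", "child"),
                       replacement = c("pool", "novel")) {
  replacement <- match.arg(replacement)
  if (!nzchar(label)) stop("error model needs a non-empty label")
  for (nm in c("miscallRate", "serotypePreservingFraction",
               "homozygoteInflationRate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single value in [0, 1]", nm))
  }
  if (!outputResolution %in% c(4L, 8L))
    stop("'outputResolution' must be 4 or 8")
  roles <- .checkRoles(roles)
  structure(list(label = label, miscallRate = miscallRate,
                 serotypePreservingFraction = serotypePreservingFraction,
                 homozygoteInflationRate = homozygoteInflationRate,
                 outputResolution = as.integer(outputResolution),
                 roles = roles, replacement = replacement),
            class = "hlaErrorModel")
}

# default pool: n 8-digit alleles per locus, two 4-digit proteins per
# 2-digit serotype group (so serotype-preserving replacements exist),
# frequencies from a symmetric Dirichlet draw
.defaultAllelePool <- function(loci, nAlleles, concentration, seed) {
  pool <- lapply(loci, function(locus) {
    i <- seq_len(nAlleles)
    alleles <- sprintf("%s*%02d:%02d:01:01", locus, (i + 1L) %/% 2L,
                       (i - 1L) %% 2L + 1L)
    set.seed(.callSeed(seed, "pool", locus))
    g <- stats::rgamma(nAlleles, shape = concentration)
    list(alleles = alleles, frequencies = g / sum(g))
  })
  stats::setNames(pool, loci)
}

#' Simulation configuration
#'
#' Assembles and validates the full configuration of a synthetic benchmark:
#' cohort size, loci, per-locus allele pools with frequency vectors, error
#' models for the synthetic methods, and the master seed. When
#' \code{allelePool} is \code{NULL} a default pool of
#' \code{nAllelesPerLocus} 8-digit alleles per locus is built (two 4-digit
#' proteins per 2-digit serotype group) with frequencies drawn from a
#' symmetric Dirichlet with the given concentration.
#'
#' @param nFamilies number of father-mother-child trios.
#' @param loci locus symbols to simulate.
#' @param allelePool named list (one entry per locus) of
#'   \code{list(alleles =, frequencies =)}; alleles at 8-digit resolution.
#' @param methods list of [errorModel()] configurations.
#' @param seed master integer seed.
#' @param nAllelesPerLocus pool size for the default pool.
#' @param dirichletConcentration concentration of the symmetric Dirichlet
#'   used for default pool frequencies.
#' @return a validated configuration list.
#' @export
simulationConfig <- function(nFamilies = 50L, loci = c("A", "B", "C"),
                             allelePool = NULL,
                             methods = list(errorModel("typer1")),
                             seed = 1L, nAllelesPerLocus = 12L,
                             dirichletConcentration = 1) {
  if (nFamilies < 1L) stop("'nFamilies' must be at least 1")
  loci <- as.character(loci)
  if (!length(loci)) stop("at least one locus is required")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  if (is.null(allelePool)) {
    allelePool <- .defaultAllelePool(loci, as.integer(nAllelesPerLocus),
                                     dirichletConcentration, seed)
  }
  if (!all(loci %in% names(allelePool)))
    stop("'allelePool' must have one entry per locus")
  anyMiscall <- any(vapply(methods, function(m)
    m$miscallRate > 0 && m$replacement == "pool", logical(1L)))
  for (locus in loci) {
    p <- allelePool[[locus]]
    if (length(p$alleles) != length(p$frequencies))
      stop(sprintf("locus %s: alleles and frequencies differ in length", locus))
    if (abs(sum(p$frequencies) - 1) > 1e-8)
      stop(sprintf("locus %s: frequencies must sum to 1", locus))
    if (any(p$frequencies < 0))
      stop(sprintf("locus %s: negative frequency", locus))
    canon <- .canonicalAllele(p$alleles)
    gene <- sub("\\*.*$", "", canon)
    if (!all(gene == locus))
      stop(sprintf("locus %s: pool allele from a different gene", locus))
    if (anyDuplicated(canon))
      stop(sprintf("locus %s: duplicate pool alleles", locus))
    if (anyMiscall && length(canon) < 2L)
      stop(sprintf("locus %s: a pool of >= 2 alleles is required when a method miscalls with pool replacement",
                   locus))
    allelePool[[locus]]$alleles <- canon
  }
  if (!length(methods)) stop("at least one error model is required")
  if (!all(vapply(methods, inherits, logical(1L), "hlaErrorModel")))
    stop("'methods' must be a list of errorModel() configurations")
  labels <- vapply(methods, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) stop("method labels must be unique")
  names(methods) <- labels
  structure(list(nFamilies = as.integer(nFamilies), loci = loci,
                 allelePool = allelePool[loci], methods = methods,
                 seed = seed),
            class = "hlaSimulationConfig")
}

#' Read a simulation configuration file
#'
#' Reads a YAML configuration with top-level keys \code{n_families},
#' \code{loci}, \code{seed}, optional \code{allele_pool} (per locus:
#' \code{alleles}, \code{frequencies}), optional \code{n_alleles_per_locus}
#' and \code{dirichlet_concentration}, and a \code{methods} list whose
#' entries take the [errorModel()] fields in snake_case
#' (\code{label}, \code{miscall_rate}, \code{serotype_preserving_fraction},
#' \code{homozygote_inflation_rate}, \code{output_resolution},
#' \code{roles}, \code{replacement}).
#'
#' @param path YAML file path.
#' @return a validated [simulationConfig()] list.
#' @export
readSimulationConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  y <- yaml::read_yaml(path)
  grab <- function(x, nm, default) if (!is.null(x[[nm]])) x[[nm]] else default
  methods <- lapply(grab(y, "methods", list()), function(m) {
    if (is.null(m$label)) stop("config error: every method needs a 'label'")
    errorModel(label = m$label,
               miscallRate = grab(m, "miscall_rate", 0.05),
               serotypePreservingFraction =
                 grab(m, "serotype_preserving_fraction", 0.5),
               homozygoteInflationRate =
                 grab(m, "homozygote_inflation_rate", 0.02),
               outputResolution = grab(m, "output_resolution", 4L),
               roles = grab(m, "roles", c("father", "mother", "child")),
               replacement = grab(m, "replacement", "pool"))
  })
  pool <- grab(y, "allele_pool", NULL)
  if (!is.null(pool))
    pool <- lapply(pool, function(p)
      list(alleles = as.character(p$alleles),
           frequencies = as.numeric(p$frequencies)))
  simulationConfig(
    nFamilies = grab(y, "n_families", 50L),
    loci = as.character(grab(y, "loci", c("A", "B", "C"))),
    allelePool = pool,
    methods = if (length(methods)) methods else list(errorModel("typer1")),
    seed = grab(y, "seed", 1L),
    nAllelesPerLocus = grab(y, "n_alleles_per_locus", 12L),
    dirichletConcentration = grab(y, "dirichlet_concentration", 1))
}

#' Simulate a ground-truth trio cohort
#'
#' Draws founder genotypes under Hardy-Weinberg equilibrium (two
#' independent allele draws per parent and locus from the configured
#' frequency vector) and transmits one uniformly chosen allele from each
#' parent to the child. The resulting cohort (method label \code{"truth"})
#' is Mendelian-consistent by construction: its Descent Accuracy is 1 at
#' every resolution.
#'
#' @param config a [simulationConfig()].
#' @return a [TrioCohort-class].
#' @export
simulateTruthCohort <- function(config) {
  stopifnot(inherits(config, "hlaSimulationConfig"))
  n <- config$nFamilies
  famIds <- sprintf("fam%04d", seq_len(n))
  samples <- data.frame(
    sample_id = paste0(rep(famIds, each = 3L), "_", c("F", "M", "C")),
    family_id = rep(famIds, each = 3L),
    role = rep(c("father", "mother", "child"), n),
    stringsAsFactors = FALSE)
  seed <- config$seed
  rows <- vector("list", n * length(config$loci) * 3L)
  k <- 0L
  for (fam in famIds) {
    for (locus in config$loci) {
      pool <- config$allelePool[[locus]]
      nA <- length(pool$alleles)
      draw2 <- function(sid) {
        set.seed(.callSeed(seed, "truth", sid, locus))
        pool$alleles[sample.int(nA, 2L, replace = TRUE,
                                prob = pool$frequencies)]
      }
      fal <- draw2(paste0(fam, "_F"))
      mal <- draw2(paste0(fam, "_M"))
      set.seed(.callSeed(seed, "truth", paste0(fam, "_C"), locus))
      cal <- c(fal[sample.int(2L, 1L)], mal[sample.int(2L, 1L)])
      for (p in list(list(paste0(fam, "_F"), fal),
                     list(paste0(fam, "_M"), mal),
                     list(paste0(fam, "_C"), cal))) {
        k <- k + 1L
        rows[[k]] <- data.frame(method = "truth", sample_id = p[[1L]],
                                locus = locus, allele1 = p[[2L]][1L],
                                allele2 = p[[2L]][2L],
                                stringsAsFactors = FALSE)
      }
    }
  }
  TrioCohort(samples, do.call(rbind, rows), loci = config$loci)
}

#' Apply a typer error model to a truth cohort
#'
#' Perturbs every call of a truth cohort according to an [errorModel()]:
#' homozygote inflation first, then per-slot miscalls, then truncation to
#' the model's output resolution. Errors are applied independently per
#' individual and locus, only to samples whose pedigree role is listed in
#' the model. Each random decision is seeded by (seed, method label,
#' sample, locus), so the result is deterministic and independent of
#' iteration order.
#'
#' @param truth a [TrioCohort-class] (typically from
#'   [simulateTruthCohort()]).
#' @param model an [errorModel()].
#' @param pool named per-locus allele pool (as in [simulationConfig()]),
#'   the source of replacement alleles.
#' @param seed integer seed.
#' @param truthMethod method label of the calls to perturb.
#' @return list with \code{cohort} (a [TrioCohort-class] with the model's
#'   label) and \code{provenance} (data.frame of fired operators: method,
#'   sample_id, locus, slot, operator, original, replacement,
#'   changed_call).
#' @export
applyTypingError <- function(truth, model, pool, seed,
                             truthMethod = "truth") {
  stopifnot(is(truth, "TrioCohort"), inherits(model, "hlaErrorModel"))
  t <- truth@typings
  t <- t[t$method == truthMethod, , drop = FALSE]
  if (!nrow(t)) stop(sprintf("no '%s' typings to perturb", truthMethod))
  roleOf <- stats::setNames(truth@samples$role, truth@samples$sample_id)
  eps <- model$miscallRate
  sig <- model$serotypePreservingFraction
  eta <- model$homozygoteInflationRate
  outRes <- model$outputResolution
  prov <- list()
  out1 <- out2 <- character(nrow(t))
  for (i in seq_len(nrow(t))) {
    sid <- t$sample_id[i]
    locus <- t$locus[i]
    a <- c(t$allele1[i], t$allele2[i])
    fired <- list()
    if (roleOf[[sid]] %in% model$roles && (eps > 0 || eta > 0)) {
      set.seed(.callSeed(seed, model$label, sid, locus))
      if (a[1L] != a[2L] && stats::runif(1L) < eta) {
        keep <- sample.int(2L, 1L)
        fired[[length(fired) + 1L]] <- data.frame(
          slot = NA_integer_, operator = "homozygote_inflation",
          original = a[3L - keep], replacement = a[keep],
          stringsAsFactors = FALSE)
        a <- rep(a[keep], 2L)
      }
      for (s in 1:2) {
        if (stats::runif(1L) < eps) {
          if (model$replacement == "novel") {
            newA <- sprintf("%s*99:9%02d", locus, sample.int(99L, 1L))
            op <- "miscall_novel"
          } else {
            poolA <- pool[[locus]]$alleles
            if (stats::runif(1L) < sig) {
              grp <- .reduceKey(a[s], 2L)
              cand <- poolA[.reduceKey(poolA, 2L) == grp & poolA != a[s]]
              op <- "miscall_serotype"
              if (!length(cand)) {
                cand <- poolA[poolA != a[s]]
                op <- "miscall_random"
              }
            } else {
              cand <- poolA[poolA != a[s]]
              op <- "miscall_random"
            }
            if (!length(cand))
              stop(sprintf("locus %s: allele pool too small for a forced replacement",
                           locus))
            newA <- cand[sample.int(length(cand), 1L)]
          }
          fired[[length(fired) + 1L]] <- data.frame(
            slot = s, operator = op, original = a[s], replacement = newA,
            stringsAsFactors = FALSE)
          a[s] <- newA
        }
      }
    }
    obs <- sort(.reduceKey(a, outRes, ignoreSuffix = FALSE))
    tru <- sort(.reduceKey(c(t$allele1[i], t$allele2[i]), outRes,
                           ignoreSuffix = FALSE))
    out1[i] <- obs[1L]
    out2[i] <- obs[2L]
    if (length(fired)) {
      f <- do.call(rbind, fired)
      f$method <- model$label
      f$sample_id <- sid
      f$locus <- locus
      f$changed_call <- !identical(obs, tru)
      prov[[length(prov) + 1L]] <- f
    }
  }
  typings <- data.frame(method = model$label, sample_id = t$sample_id,
                        locus = t$locus, allele1 = out1, allele2 = out2,
                        stringsAsFactors = FALSE)
  provenance <- if (length(prov)) {
    p <- do.call(rbind, prov)
    p[, c("method", "sample_id", "locus", "slot", "operator", "original",
          "replacement", "changed_call")]
  } else {
    data.frame(method = character(0), sample_id = character(0),
               locus = character(0), slot = integer(0),
               operator = character(0), original = character(0),
               replacement = character(0), changed_call = logical(0))
  }
  list(cohort = TrioCohort(truth@samples, typings, loci = truth@loci),
       provenance = provenance)
}

#' Run a full synthetic benchmark
#'
#' Simulates a ground-truth trio cohort and one error-perturbed observed
#' cohort per configured method, keeping provenance of every fired error
#' operator.
#'
#' @param config a [simulationConfig()].
#' @return a [SimulatedCohort-class].
#' @export
simulateBenchmark <- function(config) {
  stopifnot(inherits(config, "hlaSimulationConfig"))
  truth <- simulateTruthCohort(config)
  observed <- list()
  prov <- list()
  for (model in config$methods) {
    res <- applyTypingError(truth, model, config$allelePool, config$seed)
    observed[[model$label]] <- res$cohort
    prov[[model$label]] <- res$provenance
  }
  new("SimulatedCohort", truth = truth, observed = observed,
      provenance = do.call(rbind, c(prov, list(make.row.names = FALSE))),
      config = unclass(config))
}

#' @describeIn SimulatedCohort single cohort holding the truth typings and
#'   every observed method's typings, ready for [descentAccuracy()] and
#'   [methodAgreement()].
#' @param sim a \code{SimulatedCohort}.
#' @export
mergedCohort <- function(sim) {
  stopifnot(is(sim, "SimulatedCohort"))
  typings <- rbind(sim@truth@typings,
                   do.call(rbind, c(lapply(sim@observed, slot, "typings"),
                                    list(make.row.names = FALSE))))
  TrioCohort(sim@truth@samples, typings, loci = sim@truth@loci)
}

#' Write a simulated cohort to disk
#'
#' Writes \code{pedigree.tsv} plus one generic genotype table
#' \code{genotypes_<method>.tsv} per method (truth included) into a
#' directory. Re-running with the same configuration reproduces identical
#' files.
#'
#' @param sim a [SimulatedCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeSimulatedCohort <- function(sim, dir) {
  stopifnot(is(sim, "SimulatedCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, "pedigree.tsv")
  writePedigree(sim@truth@samples, paths)
  for (m in c("truth", names(sim@observed))) {
    coh <- if (m == "truth") sim@truth else sim@observed[[m]]
    p <- file.path(dir, sprintf("genotypes_%s.tsv", m))
    writeGenotypeTable(coh@typings, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

setMethod("show", "SimulatedCohort", function(object) {
  cat("SimulatedCohort\n")
  cat(sprintf("  %d families, loci %s\n", object@config$nFamilies,
              paste(object@config$loci, collapse = ", ")))
  cat(sprintf("  observed methods: %s\n",
              paste(names(object@observed), collapse = ", ")))
  cat(sprintf("  %d error events recorded (%d changed a call)\n",
              nrow(object@provenance), sum(object@provenance$changed_call)))
  invisible(NULL)
})
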