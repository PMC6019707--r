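# Population-level statistics on a trio cohort: homozygosity rates,
# direct-counting allele frequencies, top-k ranking against reference
# populations, and common/well-documented classification.
#
# Parents are the default population: their genetic background is
# unconstrained and therefore representative, whereas a child's alleles are
# a subset defined by its parents.

.checkRoles <- function(roles) {
  roles <- unique(as.character(roles))
  if (!length(roles)) stop("empty role selection")
  bad <- setdiff(roles, .ROLES)
  if (length(bad))
    stop(sprintf("unknown role(s): %s", paste(bad, collapse = ", ")))
  roles
}

# typings restricted to a method and role set, with reduced allele keys
.roleTypings <- function(cohort, method, resolution, roles, ignoreSuffix) {
  s <- cohort@samples
  keep <- s$sample_id[s$role %in% roles]
  t <- cohort@typings
  t <- t[t$method == method & t$sample_id %in% keep, , drop = FALSE]
  if (nrow(t)) {
    t$key1 <- .reduceKey(t$allele1, resolution, ignoreSuffix)
    t$key2 <- .reduceKey(t$allele2, resolution, ignoreSuffix)
  }
  t
}

#' Homozygosity rate per locus
#'
#' An individual is homozygous at a locus when its two alleles are
#' identical at the working resolution (so an 8-digit heterozygote whose
#' alleles share a 4-digit protein is homozygous at 4 digits). HR per locus
#' is N_homozygous / N_population; the overall rate pools counts across
#' loci, and the unweighted per-locus mean is also reported. Parents are
#' the default population.
#'
#' @param cohort a [TrioCohort-class].
#' @param method method label to evaluate.
#' @param resolution working resolution in digits.
#' @param roles pedigree roles included; default father and mother.
#' @param ignoreSuffix drop expression suffixes before comparing.
#' @return an [HRReport-class].
#' @export
homozygosityRate <- function(cohort, method, resolution = 4L,
                             roles = c("father", "mother"),
                             ignoreSuffix = TRUE) {
  stopifnot(is(cohort, "TrioCohort"))
  roles <- .checkRoles(roles)
  t <- .roleTypings(cohort, method, resolution, roles, ignoreSuffix)
  if (!nrow(t))
    stop(sprintf("no typings for method '%s' in roles %s", method,
                 paste(roles, collapse = "/")))
  perLocus <- do.call(rbind, lapply(cohort@loci, function(locus) {
    d <- t[t$locus == locus, ]
    data.frame(locus = locus, n_homozygous = sum(d$key1 == d$key2),
               n_population = nrow(d),
               hr = if (nrow(d)) sum(d$key1 == d$key2) / nrow(d) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(perLocus) <- NULL
  evaluated <- perLocus[perLocus$n_population > 0L, ]
  new("HRReport", method = method, resolution = as.integer(resolution),
      roles = roles, perLocus = perLocus,
      hrOverall = sum(evaluated$n_homozygous) / sum(evaluated$n_population),
      hrLocusMean = mean(evaluated$hr))
}

#' @describeIn HRReport pooled homozygosity rate across loci.
#' @param report an \code{HRReport}.
#' @export
hrOverall <- function(report) {
  stopifnot(is(report, "HRReport"))
  report@hrOverall
}

#' @describeIn HRReport named vector of per-locus homozygosity rates.
#' @export
hrPerLocus <- function(report) {
  stopifnot(is(report, "HRReport"))
  stats::setNames(report@perLocus$hr, report@perLocus$locus)
}

#' Direct-counting allele frequencies
#'
#' Estimates per-locus allele frequencies by direct counting: each allele
#' occurrence counts once (homozygotes twice) and the denominator is two
#' chromosomes per individual typed at the locus. Frequencies at each locus
#' sum to 1.
#'
#' @inheritParams homozygosityRate
#' @return an [AlleleFrequencyTable-class].
#' @export
alleleFrequencies <- function(cohort, method, resolution = 4L,
                              roles = c("father", "mother"),
                              ignoreSuffix = TRUE) {
  stopifnot(is(cohort, "TrioCohort"))
  roles <- .checkRoles(roles)
  t <- .roleTypings(cohort, method, resolution, roles, ignoreSuffix)
  if (!nrow(t))
    stop(sprintf("no typings for method '%s' in roles %s", method,
                 paste(roles, collapse = "/")))
  tab <- do.call(rbind, lapply(unique(t$locus), function(locus) {
    d <- t[t$locus == locus, ]
    counts <- table(c(d$key1, d$key2))
    chrom <- 2L * nrow(d)
    res <- data.frame(locus = locus, allele = names(counts),
                      count = as.integer(counts), chromosomes = chrom,
                      frequency = as.integer(counts) / chrom,
                      stringsAsFactors = FALSE)
    res[order(-res$frequency, res$allele), ]
  }))
  tab <- tab[order(match(tab$locus, cohort@loci), -tab$frequency, tab$allele), ]
  rownames(tab) <- NULL
  new("AlleleFrequencyTable", method = method,
      resolution = as.integer(resolution), roles = roles, table = tab)
}

#' @describeIn AlleleFrequencyTable the frequency table as a data.frame.
#' @param freqs an \code{AlleleFrequencyTable}.
#' @export
frequencyTable <- function(freqs) {
  stopifnot(is(freqs, "AlleleFrequencyTable"))
  freqs@table
}

#' Rank the most frequent cohort alleles
#'
#' Top-k alleles per locus by descending frequency; exact ties are broken
#' by the lexicographically earlier canonical allele string.
#'
#' @param freqs an [AlleleFrequencyTable-class].
#' @param k number of alleles to rank per locus (k >= 1).
#' @return a [FrequencyComparison-class] with cohort-side columns only.
#' @export
rankTopAlleles <- function(freqs, k = 5L) {
  stopifnot(is(freqs, "AlleleFrequencyTable"))
  if (k < 1L) stop("'k' must be at least 1")
  tab <- freqs@table
  ranked <- do.call(rbind, lapply(split(tab, tab$locus), function(d) {
    d <- d[order(-d$frequency, d$allele), ]
    d <- utils::head(d, k)
    data.frame(locus = d$locus, rank = seq_len(nrow(d)), allele = d$allele,
               cohort_frequency = d$frequency, stringsAsFactors = FALSE)
  }))
  ranked <- ranked[order(match(ranked$locus, unique(tab$locus)),
                         ranked$rank), ]
  rownames(ranked) <- NULL
  new("FrequencyComparison", table = ranked, k = as.integer(k),
      references = character(0), absentFromAll = character(0))
}

#' Compare top cohort alleles to reference population frequencies
#'
#' Ranks the top-k cohort alleles per locus and aligns each against the
#' frequency reported by every reference population (matching at 4-digit
#' resolution after reduction), with an explicit \code{NA} where the allele
#' is absent from a reference. Cohort alleles absent from every reference
#' are listed separately.
#'
#' @param freqs an [AlleleFrequencyTable-class].
#' @param references named list of reference tables as returned by
#'   [readFrequencyReference()].
#' @param k number of alleles to rank per locus.
#' @return a [FrequencyComparison-class].
#' @export
compareToReference <- function(freqs, references, k = 5L) {
  if (!length(references))
    stop("'references' must contain at least one reference population")
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop("'references' must be a named list of population tables")
  cmp <- rankTopAlleles(freqs, k)
  tab <- cmp@table
  key <- .reduceKey(tab$allele, 4L)
  for (pop in names(references)) {
    ref <- references[[pop]]
    tab[[pop]] <- ref$frequency[match(key, ref$allele)]
  }
  refCols <- as.matrix(tab[, names(references), drop = FALSE])
  absent <- tab$allele[rowSums(!is.na(refCols)) == 0L]
  new("FrequencyComparison", table = tab, k = as.integer(k),
      references = names(references), absentFromAll = absent)
}

#' @describeIn FrequencyComparison the comparison table as a data.frame.
#' @param x a \code{FrequencyComparison}.
#' @export
comparisonTable <- function(x) {
  stopifnot(is(x, "FrequencyComparison"))
  x@table
}

#' Classify observed alleles as common/well-documented or rare
#'
#' An observed allele is labelled common/well-documented when its 4-digit
#' reduction appears in the catalogue, and rare otherwise. Per-locus counts
#' of distinct common and rare alleles and the fraction rare are reported
#' alongside the per-allele labels.
#'
#' @param freqs an [AlleleFrequencyTable-class].
#' @param catalogue character vector of catalogued alleles (see
#'   [readCWDCatalogue()]), reduced to 4-digit resolution.
#' @return list with elements \code{alleles} (locus, allele, frequency,
#'   label) and \code{perLocus} (locus, n_common, n_rare, fraction_rare).
#' @export
classifyCWD <- function(freqs, catalogue) {
  stopifnot(is(freqs, "AlleleFrequencyTable"))
  if (!length(catalogue)) stop("'catalogue' must be non-empty")
  catalogue <- unique(.reduceKey(.canonicalAllele(catalogue), 4L))
  tab <- freqs@table
  if (!nrow(tab))
    return(list(alleles = data.frame(locus = character(0),
                                     allele = character(0),
                                     frequency = numeric(0),
                                     label = character(0)),
                perLocus = data.frame(locus = character(0),
                                      n_common = integer(0),
                                      n_rare = integer(0),
                                      fraction_rare = numeric(0))))
  label <- ifelse(.reduceKey(tab$allele, 4L) %in% catalogue,
                  "common/well-documented", "rare")
  alleles <- data.frame(locus = tab$locus, allele = tab$allele,
                        frequency = tab$frequency, label = label,
                        stringsAsFactors = FALSE)
  perLocus <- do.call(rbind, lapply(split(alleles, alleles$locus),
    function(d) {
      nc <- sum(d$label == "common/well-documented")
      nr <- sum(d$label == "rare")
      data.frame(locus = d$locus[1L], n_common = nc, n_rare = nr,
                 fraction_rare = nr / (nc + nr), stringsAsFactors = FALSE)
    }))
  perLocus <- perLocus[order(match(perLocus$locus, unique(tab$locus))), ]
  rownames(perLocus) <- NULL
  list(alleles = alleles, perLocus = perLocus)
}

#' Build a CWD-style catalogue from reference frequency tables
#'
#' Applies the common/well-documented criterion — observed at a frequency
#' above \code{minFrequency} in a reference population of at least
#' \code{minIndividuals} individuals — to reference tables from
#' [readFrequencyReference()]. Population sizes come from the optional
#' \code{n} column of the reference, or from \code{populationSizes}.
#'
#' @param references named list of reference tables.
#' @param minFrequency frequency threshold (default 0.001).
#' @param minIndividuals minimum population sample size (default 1500).
#' @param populationSizes optional named numeric vector of individuals per
#'   population, used for references lacking an \code{n} column.
#' @return character vector of catalogued 4-digit alleles.
#' @export
buildCWDCatalogue <- function(references, minFrequency = 0.001,
                              minIndividuals = 1500,
                              populationSizes = NULL) {
  if (!length(references)) stop("'references' must be non-empty")
  out <- character(0)
  for (pop in names(references)) {
    ref <- references[[pop]]
    n <- if ("n" %in% names(ref)) ref$n
         else if (!is.null(populationSizes) && pop %in% names(populationSizes))
           rep(populationSizes[[pop]], nrow(ref))
         else rep(NA_real_, nrow(ref))
    if (all(is.na(n)))
      stop(sprintf("no sample size known for population '%s': provide an 'n' column or 'populationSizes'",
                   pop))
    keep <- !is.na(n) & n >= minIndividuals & ref$frequency > minFrequency
    out <- c(out, ref$allele[keep])
  }
  sort(unique(out))
}

setMethod("show", "HRReport", function(object) {
  cat(sprintf("Homozygosity Rate: method '%s' at %d-digit resolution (%s)\n",
              object@method, object@resolution,
              paste(object@roles, collapse = "+")))
  cat(sprintf("  HR overall = %.4f (per-locus mean %.4f)\n",
              object@hrOverall, object@hrLocusMean))
  for (i in seq_len(nrow(object@perLocus)))
    cat(sprintf("  %-4s HR = %.4f (%d/%d)\n", object@perLocus$locus[i],
                object@perLocus$hr[i], object@perLocus$n_homozygous[i],
                object@perLocus$n_population[i]))
  invisible(NULL)
})

setMethod("show", "AlleleFrequencyTable", function(object) {
  cat(sprintf("Allele frequencies (direct counting): method '%s', %d-digit, roles %s\n",
              object@method, object@resolution,
              paste(object@roles, collapse = "+")))
  print(utils::head(object@table, 10L))
  if (nrow(object@table) > 10L)
    cat(sprintf("  ... and %d more alleles\n", nrow(object@table) - 10L))
  invisible(NULL)
})

setMethod("show", "FrequencyComparison", function(object) {
  cat(sprintf("Top-%d allele frequency comparison", object@k))
  if (length(object@references))
    cat(sprintf(" against %d reference population(s)",
                length(object@references)))
  cat("\n")
  print(object@table)
  if (length(object@absentFromAll))
    cat(sprintf("  absent from every reference: %s\n",
                paste(object@absentFromAll, collapse = ", ")))
  invisible(NULL)
})
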