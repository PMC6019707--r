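#' @import methods
NULL

#' Vector of structured HLA allele identifiers
#'
#' An \code{HLAAllele} holds one or more parsed HLA allele identifiers as a
#' vectorised S4 object. Each element records the gene symbol, one to four
#' numeric fields (leading zeros preserved) and an optional single-letter
#' expression suffix (e.g. \code{N} for null, \code{L} for low expression).
#' The resolution of an element is twice its number of fields: 2-digit
#' identifiers name the serological allele group, 4-digit the distinct
#' protein, 6-digit synonymous coding variants and 8-digit non-coding
#' variants.
#'
#' @slot gene character vector of locus symbols (e.g. \code{"A"}, \code{"B"}).
#' @slot fields character matrix with four columns; column \code{j} holds the
#'   j-th numeric field or \code{NA} when absent. Fields are kept as strings
#'   of 2--4 digit characters so leading zeros are significant.
#' @slot suffix character vector of expression suffixes (\code{NA} if none).
#'
#' @seealso [parseHLAAllele()], [formatHLAAllele()], [reduceAllele()],
#'   [resolutionOf()], [allelesEqualAt()], [serotypeGroup()]
#' @export
setClass("HLAAllele",
  slots = c(gene = "character", fields = "matrix", suffix = "character"),
  validity = function(object) {
    n <- length(object@gene)
    f <- object@fields
    msg <- character(0)
    if (!is.character(f) || ncol(f) != 4L || nrow(f) != n)
      return("'fields' must be a character matrix with 4 columns and one row per allele")
    if (length(object@suffix) != n)
      return("'suffix' length must match 'gene' length")
    if (n == 0L) return(TRUE)
    if (any(!nzchar(object@gene) | is.na(object@gene)))
      msg <- c(msg, "gene symbols must be non-empty")
    if (any(is.na(f[, 1L])))
      msg <- c(msg, "every allele needs at least one field")
    # no gaps: a field may only be present if the previous one is
    for (j in 2:4) {
      if (any(!is.na(f[, j]) & is.na(f[, j - 1L])))
        msg <- c(msg, "allele fields must be contiguous")
    }
    present <- !is.na(f)
    if (any(!grepl("^[0-9]{2,4}$", f[present])))
      msg <- c(msg, "allele fields must be 2-4 digit character strings")
    sfx <- object@suffix[!is.na(object@suffix)]
    if (length(sfx) && any(!grepl("^[A-Z]$", sfx)))
      msg <- c(msg, "expression suffix must be a single uppercase letter")
    if (length(msg)) msg else TRUE
  }
)

#' A genotype call: an unordered pair of alleles for one sample and locus
#'
#' @slot sampleId sample identifier.
#' @slot locus locus symbol; both alleles must belong to this gene.
#' @slot method label of the typing method that produced the call.
#' @slot alleles character vector of length 2 with canonical colon-dialect
#'   identifiers, sorted so the pair is order-independent; homozygous calls
#'   keep both copies (multiset semantics).
#' @export
setClass("GenotypeCall",
  slots = c(sampleId = "character", locus = "character",
            method = "character", alleles = "character"),
  validity = function(object) {
    if (length(object@alleles) != 2L)
      return("a genotype call holds exactly two alleles")
    gene <- sub("\\*.*$", "", object@alleles)
    if (!all(gene == object@locus))
      return(sprintf("alleles [%s] do not belong to locus %s",
                     paste(object@alleles, collapse = ", "), object@locus))
    if (is.unsorted(object@alleles))
      return("alleles must be stored in canonical (sorted) order")
    TRUE
  }
)

#' Trio cohort: samples, pedigree roles and per-method genotype calls
#'
#' Container for a family-trio cohort. \code{samples} is a data.frame with
#' columns \code{sample_id}, \code{family_id} and \code{role} (father /
#' mother / child); \code{typings} has columns \code{method},
#' \code{sample_id}, \code{locus}, \code{allele1}, \code{allele2} with
#' canonical colon-dialect identifiers and the pair sorted. Families missing
#' any of the three roles are flagged incomplete and excluded from
#' trio-based statistics.
#'
#' @slot samples data.frame of sample records.
#' @slot typings data.frame of genotype calls, one row per
#'   (method, sample, locus).
#' @slot loci ordered character vector of locus symbols.
#' @slot incompleteFamilies family ids lacking a father, mother or child.
#' @seealso [TrioCohort()], [descentAccuracy()], [methodAgreement()],
#'   [homozygosityRate()]
#' @export
setClass("TrioCohort",
  slots = c(samples = "data.frame", typings = "data.frame",
            loci = "character", incompleteFamilies = "character"),
  validity = function(object) {
    s <- object@samples
    t <- object@typings
    msg <- character(0)
    need <- c("sample_id", "family_id", "role")
    if (!all(need %in% names(s)))
      return(paste("samples must have columns", paste(need, collapse = ", ")))
    needT <- c("method", "sample_id", "locus", "allele1", "allele2")
    if (!all(needT %in% names(t)))
      return(paste("typings must have columns", paste(needT, collapse = ", ")))
    if (anyDuplicated(s$sample_id))
      msg <- c(msg, "duplicate sample_id in samples")
    if (!all(s$role %in% c("father", "mother", "child")))
      msg <- c(msg, "role must be one of father, mother, child")
    if (anyDuplicated(paste(s$family_id, s$role)))
      msg <- c(msg, "a family has two members with the same role")
    if (nrow(t)) {
      key <- paste(t$method, t$sample_id, t$locus)
      if (anyDuplicated(key))
        msg <- c(msg, "duplicate (method, sample, locus) typing")
      if (!all(t$sample_id %in% s$sample_id))
        msg <- c(msg, "typings refer to samples absent from the pedigree")
      if (!all(t$locus %in% object@loci))
        msg <- c(msg, "typings refer to loci absent from 'loci'")
      bad <- sub("\\*.*$", "", t$allele1) != t$locus |
             sub("\\*.*$", "", t$allele2) != t$locus
      if (any(bad))
        msg <- c(msg, sprintf("allele/locus gene mismatch in typing row(s) %s",
                              paste(utils::head(which(bad), 3L), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Result of Mendelian matching for one trio and locus
#'
#' @slot familyId family identifier.
#' @slot locus locus symbol.
#' @slot nEq number of child alleles (0, 1 or 2) explained by inheritance.
#' @slot assignment data.frame with columns \code{child_slot},
#'   \code{child_allele}, \code{parent} describing one maximal consistent
#'   assignment of child alleles to parents.
#' @slot ambiguous \code{TRUE} when several maximal assignments exist that
#'   differ in which parent transmits which allele.
#' @export
setClass("TrioMatch",
  slots = c(familyId = "character", locus = "character", nEq = "integer",
            assignment = "data.frame", ambiguous = "logical"))

#' Descent Accuracy report
#'
#' Descent Accuracy (DA) is the fraction of child alleles explainable by
#' Mendelian inheritance from the typed parents: DA = N_eq / N_alleles with
#' N_alleles = N_children x 2 x number of loci.
#'
#' @slot method typing method evaluated.
#' @slot resolution working resolution in digits (2, 4, 6 or 8).
#' @slot nEq total explained child alleles.
#' @slot nAlleles total evaluated child alleles (denominator).
#' @slot nChildren number of children contributing to at least one locus.
#' @slot loci loci evaluated.
#' @slot daOverall pooled DA over all loci.
#' @slot perLocus data.frame: locus, n_children, n_eq, n_alleles, da.
#' @slot perTrio data.frame of per-family-locus matches (n_eq, ambiguous).
#' @slot excluded data.frame of family x locus combinations skipped for
#'   missing calls, with a reason column.
#' @export
setClass("DAReport",
  slots = c(method = "character", resolution = "integer", nEq = "integer",
            nAlleles = "integer", nChildren = "integer", loci = "character",
            daOverall = "numeric", perLocus = "data.frame",
            perTrio = "data.frame", excluded = "data.frame"))

#' Method Agreement report
#'
#' Method Agreement (MA) is the fraction of allele calls identical between
#' two typing methods: MA = N_agree / (N_population x 2 x number of loci),
#' where per sample and locus the agreement is the multiset intersection of
#' the two unordered allele pairs. MA_T and MA_NT restrict numerator and
#' denominator to allele slots classified transmitted resp. non-transmitted
#' under the phase-reference method; unresolved slots are excluded from both
#' and counted separately.
#'
#' @slot methods the two method labels compared.
#' @slot resolution working resolution in digits.
#' @slot nPopulation number of individuals typed at every locus by both
#'   methods.
#' @slot loci loci evaluated.
#' @slot nAgree total identically typed alleles.
#' @slot maTotal,maT,maNT overall agreement ratios.
#' @slot perLocus data.frame with per-locus numerators, denominators and
#'   ratios for the total, transmitted and non-transmitted slot classes.
#' @slot perIndividual data.frame (sample_id, n_agree) feeding the
#'   per-individual concordance histogram.
#' @slot nUnresolvedSlots slots excluded from the MA_T/MA_NT split.
#' @slot excludedSamples samples dropped for incomplete typing.
#' @slot phaseReference method whose calls define transmission phase.
#' @export
setClass("MAReport",
  slots = c(methods = "character", resolution = "integer",
            nPopulation = "integer", loci = "character", nAgree = "integer",
            maTotal = "numeric", maT = "numeric", maNT = "numeric",
            perLocus = "data.frame", perIndividual = "data.frame",
            nUnresolvedSlots = "integer", excludedSamples = "character",
            phaseReference = "character"))

#' Homozygosity rate report
#'
#' HR per locus is the fraction of individuals carrying two alleles that are
#' identical at the working resolution: HR = N_homozygous / N_population.
#' The overall rate pools counts across loci; the per-locus mean is also
#' reported.
#'
#' @slot method typing method evaluated.
#' @slot resolution working resolution in digits.
#' @slot roles pedigree roles included (parents by default).
#' @slot perLocus data.frame: locus, n_homozygous, n_population, hr.
#' @slot hrOverall pooled homozygosity rate.
#' @slot hrLocusMean unweighted mean of the per-locus rates.
#' @export
setClass("HRReport",
  slots = c(method = "character", resolution = "integer", roles = "character",
            perLocus = "data.frame", hrOverall = "numeric",
            hrLocusMean = "numeric"))

#' Direct-counting allele frequency table
#'
#' Allele frequencies per locus estimated by direct counting: each allele
#' occurrence counts once (homozygotes twice) and the denominator is two
#' chromosomes per typed individual at the locus.
#'
#' @slot method typing method evaluated.
#' @slot resolution working resolution in digits.
#' @slot roles pedigree roles included.
#' @slot table data.frame: locus, allele, count, chromosomes, frequency,
#'   ordered by locus then descending frequency (ties broken by allele
#'   string).
#' @export
setClass("AlleleFrequencyTable",
  slots = c(method = "character", resolution = "integer", roles = "character",
            table = "data.frame"))

#' Top-k cohort alleles aligned against reference population frequencies
#'
#' @slot table data.frame with locus, rank, allele, cohort frequency and one
#'   column per reference population (NA where the allele is absent).
#' @slot k number of top alleles per locus.
#' @slot references names of the reference populations (empty when ranking
#'   only).
#' @slot absentFromAll cohort alleles in the table found in no reference.
#' @export
setClass("FrequencyComparison",
  slots = c(table = "data.frame", k = "integer", references = "character",
            absentFromAll = "character"))

#' Simulated benchmark cohort
#'
#' Holds a ground-truth trio cohort (method label \code{"truth"}), one
#' error-perturbed observed cohort per configured synthetic method, and the
#' provenance of every error operator that fired.
#'
#' @slot truth ground-truth [TrioCohort-class].
#' @slot observed named list of perturbed [TrioCohort-class] objects.
#' @slot provenance data.frame: method, sample_id, locus, slot, operator,
#'   original, replacement, changed_call.
#' @slot config the [simulationConfig()] used.
#' @export
setClass("SimulatedCohort",
  slots = c(truth = "TrioCohort", observed = "list",
            provenance = "data.frame", config = "list"),
  validity = function(object) {
    if (length(object@observed) &&
        (is.null(names(object@observed)) || any(!nzchar(names(object@observed)))))
      return("'observed' must be a named list of TrioCohort objects")
    ok <- vapply(object@observed, is, logical(1), "TrioCohort")
    if (!all(ok)) return("'observed' must contain TrioCohort objects")
    TRUE
  }
)
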