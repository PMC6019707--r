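# TrioCohort construction and accessors.

.ROLES <- c("father", "mother", "child")

#' Construct a genotype call
#'
#' Builds a [GenotypeCall-class] from two allele identifiers (any dialect).
#' The pair is unordered: alleles are canonicalised and stored sorted, and a
#' homozygous call keeps both copies (multiset semantics).
#'
#' @param sampleId sample identifier.
#' @param locus locus symbol; both alleles must belong to this gene.
#' @param alleles character vector of length 2.
#' @param method typing method label.
#' @return a [GenotypeCall-class].
#' @examples
#' genotypeCall("s1", "A", c("A*02:01", "A*01:01"), method = "optitype")
#' @export
genotypeCall <- function(sampleId, locus, alleles, method = "manual") {
  if (length(alleles) != 2L)
    stop("a genotype call needs exactly two alleles")
  canon <- sort(.canonicalAllele(alleles))
  gene <- sub("\\*.*$", "", canon)
  if (!all(gene == locus))
    stop(sprintf("allele(s) [%s] do not belong to locus %s",
                 paste(alleles, collapse = ", "), locus))
  new("GenotypeCall", sampleId = as.character(sampleId),
      locus = as.character(locus), method = as.character(method),
      alleles = canon)
}

#' @describeIn GenotypeCall the unordered allele pair, canonical and sorted.
#' @param call a \code{GenotypeCall}.
#' @export
callAlleles <- function(call) {
  stopifnot(is(call, "GenotypeCall"))
  call@alleles
}

setMethod("show", "GenotypeCall", function(object) {
  cat(sprintf("GenotypeCall: %s  %s  {%s}  [%s]\n", object@sampleId,
              object@locus, paste(object@alleles, collapse = ", "),
              object@method))
  invisible(NULL)
})

#' Assemble a trio cohort
#'
#' Combines pedigree sample records with genotype typings into a validated
#' [TrioCohort-class]. Allele identifiers are canonicalised (any input
#' dialect) and each unordered pair is stored sorted. Families missing a
#' father, mother or child are flagged incomplete; they remain in the
#' cohort for population statistics but are excluded from trio-based
#' statistics.
#'
#' @param samples data.frame with columns \code{sample_id},
#'   \code{family_id}, \code{role} (see [readPedigree()]).
#' @param typings data.frame with columns \code{method}, \code{sample_id},
#'   \code{locus}, \code{allele1}, \code{allele2} (see
#'   [readGenotypeTable()]); several methods may be stacked.
#' @param loci ordered locus symbols; defaults to the sorted loci present in
#'   \code{typings}.
#' @return a [TrioCohort-class].
#' @export
TrioCohort <- function(samples, typings, loci = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  typings <- as.data.frame(typings, stringsAsFactors = FALSE)
  for (cn in c("sample_id", "family_id", "role"))
    samples[[cn]] <- as.character(samples[[cn]])
  if (nrow(typings)) {
    for (cn in c("method", "sample_id", "locus", "allele1", "allele2"))
      typings[[cn]] <- as.character(typings[[cn]])
    # canonicalise once per distinct identifier
    uniq <- unique(c(typings$allele1, typings$allele2))
    canon <- stats::setNames(.canonicalAllele(uniq), uniq)
    a1 <- unname(canon[typings$allele1])
    a2 <- unname(canon[typings$allele2])
    typings$allele1 <- pmin(a1, a2)
    typings$allele2 <- pmax(a1, a2)
  } else {
    typings <- data.frame(method = character(0), sample_id = character(0),
                          locus = character(0), allele1 = character(0),
                          allele2 = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(loci)) loci <- sort(unique(typings$locus))
  fams <- split(samples$role, samples$family_id)
  incomplete <- names(fams)[!vapply(fams, function(r) all(.ROLES %in% r),
                                    logical(1L))]
  new("TrioCohort", samples = samples,
      typings = typings[, c("method", "sample_id", "locus",
                            "allele1", "allele2")],
      loci = as.character(loci), incompleteFamilies = incomplete)
}

#' @describeIn TrioCohort pedigree sample records.
#' @param cohort a \code{TrioCohort}.
#' @export
cohortSamples <- function(cohort) {
  stopifnot(is(cohort, "TrioCohort"))
  cohort@samples
}

#' @describeIn TrioCohort genotype typings, one row per
#'   (method, sample, locus).
#' @export
cohortTypings <- function(cohort) {
  stopifnot(is(cohort, "TrioCohort"))
  cohort@typings
}

#' @describeIn TrioCohort ordered locus symbols.
#' @export
cohortLoci <- function(cohort) {
  stopifnot(is(cohort, "TrioCohort"))
  cohort@loci
}

#' @describeIn TrioCohort typing method labels present.
#' @export
cohortMethods <- function(cohort) {
  stopifnot(is(cohort, "TrioCohort"))
  unique(cohort@typings$method)
}

#' @describeIn TrioCohort family ids with all three roles present.
#' @export
completeFamilies <- function(cohort) {
  stopifnot(is(cohort, "TrioCohort"))
  setdiff(unique(cohort@samples$family_id), cohort@incompleteFamilies)
}

#' @describeIn TrioCohort family ids missing a father, mother or child.
#' @export
incompleteFamilies <- function(cohort) {
  stopifnot(is(cohort, "TrioCohort"))
  cohort@incompleteFamilies
}

#' Retrieve one genotype call from a cohort
#'
#' @param cohort a [TrioCohort-class].
#' @param method method label.
#' @param sampleId sample identifier.
#' @param locus locus symbol.
#' @return a [GenotypeCall-class], or \code{NULL} when no call is recorded.
#' @export
getGenotypeCall <- function(cohort, method, sampleId, locus) {
  stopifnot(is(cohort, "TrioCohort"))
  t <- cohort@typings
  i <- which(t$method == method & t$sample_id == sampleId & t$locus == locus)
  if (!length(i)) return(NULL)
  new("GenotypeCall", sampleId = sampleId, locus = locus, method = method,
      alleles = c(t$allele1[i[1L]], t$allele2[i[1L]]))
}

setMethod("show", "TrioCohort", function(object) {
  s <- object@samples
  cat("TrioCohort\n")
  cat(sprintf("  %d samples in %d families (%d complete)\n", nrow(s),
              length(unique(s$family_id)), length(completeFamilies(object))))
  cat(sprintf("  loci: %s\n", paste(object@loci, collapse = ", ")))
  cat(sprintf("  methods: %s (%d typings)\n",
              paste(cohortMethods(object), collapse = ", "),
              nrow(object@typings)))
  if (length(object@incompleteFamilies))
    cat(sprintf("  incomplete families: %s\n",
                paste(object@incompleteFamilies, collapse = ", ")))
  invisible(NULL)
})

# fast lookup of typing rows: named integer index by method\rsample\rlocus
.typingIndex <- function(cohort) {
  t <- cohort@typings
  stats::setNames(seq_len(nrow(t)), paste(t$method, t$sample_id, t$locus,
                                          sep = "\r"))
}

# members of a family as a named list father/mother/child -> sample_id
.familyMembers <- function(cohort, familyId) {
  s <- cohort@samples
  rows <- s[s$family_id == familyId, ]
  stats::setNames(as.list(rows$sample_id), rows$role)
}
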