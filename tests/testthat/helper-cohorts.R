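# Shared test helpers: compact cohort builders and independent brute-force
# oracles for trio matching and pair agreement.

# Build a TrioCohort from a list of families. Each family is
# list(father =, mother =, child =) where each member is a named list
# locus -> character(2) of allele identifiers. `method` labels the calls.
makeCohort <- function(families, method = "test", loci = NULL) {
  samples <- list()
  typings <- list()
  for (fam in names(families)) {
    for (role in names(families[[fam]])) {
      sid <- paste(fam, role, sep = "_")
      samples[[length(samples) + 1L]] <- data.frame(
        sample_id = sid, family_id = fam, role = role,
        stringsAsFactors = FALSE)
      calls <- families[[fam]][[role]]
      for (locus in names(calls)) {
        typings[[length(typings) + 1L]] <- data.frame(
          method = method, sample_id = sid, locus = locus,
          allele1 = calls[[locus]][1L], allele2 = calls[[locus]][2L],
          stringsAsFactors = FALSE)
      }
    }
  }
  TrioCohort(do.call(rbind, samples), do.call(rbind, typings), loci = loci)
}

aCall <- function(sid, locus, alleles, method = "test") {
  genotypeCall(sid, locus, alleles, method)
}

# Independent oracle for trio Mendelian matching under the one-allele-per-
# parent rule: enumerate the four possible transmitted pairs (one allele
# from each parent) and take the largest multiset intersection with the
# child pair. Works on reduced allele strings.
trioOracle <- function(child, mother, father) {
  best <- 0L
  for (i in 1:2) {
    for (j in 1:2) {
      transmitted <- c(mother[i], father[j])
      best <- max(best, multisetIntersection(child, transmitted))
    }
  }
  best
}

# Independent oracle for pair agreement: brute force over the two possible
# slot pairings of a against b, counting equal matched slots.
pairingOracle <- function(a, b) {
  max(sum(a[1] == b[1]) + sum(a[2] == b[2]),
      sum(a[1] == b[2]) + sum(a[2] == b[1]))
}

multisetIntersection <- function(x, y) {
  n <- 0L
  for (v in x) {
    j <- match(v, y)
    if (!is.na(j)) {
      n <- n + 1L
      y <- y[-j]
    }
  }
  n
}

# all unordered genotypes (pairs with repetition) over an allele alphabet
allGenotypes <- function(alleles) {
  out <- list()
  for (i in seq_along(alleles))
    for (j in i:length(alleles))
      out[[length(out) + 1L]] <- c(alleles[i], alleles[j])
  out
}
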