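# Trio Mendelian matching and the two accuracy statistics.
#
# Descent Accuracy (DA = N_eq / N_alleles, N_alleles = N_children x 2 x
# |loci|) counts child alleles explainable by inheritance from the typed
# parents; by default each of the two child alleles must come from a
# DIFFERENT parent (one from each progenitor). Method Agreement
# (MA = N_agree / (N_population x 2 x |loci|)) counts alleles typed
# identically by two methods, with multiset semantics on the unordered
# pairs, and splits into transmitted / non-transmitted slot classes.

# Core matcher on reduced allele keys. ck, mk, fk: length-2 character
# vectors (child / mother / father). Two assignments are the same
# configuration when they induce the same set of (parent, allele)
# transmissions, so a slot swap of a homozygous child is not an ambiguity.
.matchKeys <- function(ck, mk, fk, requireDistinctParents = TRUE) {
  parents <- list(mother = mk, father = fk)
  mkAssign <- function(slots, alleles, who) {
    data.frame(child_slot = as.integer(slots), child_allele = alleles,
               parent = who, stringsAsFactors = FALSE)
  }
  if (requireDistinctParents) {
    best <- -1L
    assigns <- list()
    for (ord in list(c("mother", "father"), c("father", "mother"))) {
      hit <- c(ck[1L] %in% parents[[ord[1L]]], ck[2L] %in% parents[[ord[2L]]])
      sc <- sum(hit)
      df <- mkAssign(which(hit), ck[hit], ord[hit])
      if (sc > best) {
        best <- sc
        assigns <- list(df)
      } else if (sc == best) {
        assigns <- c(assigns, list(df))
      }
    }
    sig <- vapply(assigns,
                  function(d) paste(sort(paste(d$parent, d$child_allele)),
                                    collapse = "|"),
                  character(1L))
    list(nEq = as.integer(best), assignment = assigns[[1L]],
         ambiguous = best > 0L && length(unique(sig)) > 1L)
  } else {
    hitM <- ck %in% mk
    hitF <- ck %in% fk
    matched <- hitM | hitF
    who <- ifelse(hitM, "mother", "father")
    list(nEq = as.integer(sum(matched)),
         assignment = mkAssign(which(matched), ck[matched], who[matched]),
         ambiguous = any(hitM & hitF))
  }
}

#' Mendelian matching of one trio at one locus
#'
#' Determines how many of the two child alleles are explained by
#' inheritance from the typed parents, comparing alleles at the given
#' resolution after reduction. By default the two child alleles must be
#' assigned to two different parents (a child inherits one allele from each
#' progenitor); both assignment orders are enumerated and a maximal one is
#' recorded. When several maximal assignments imply different
#' (parent, allele) transmissions the match is flagged ambiguous. Setting
#' \code{requireDistinctParents = FALSE} relaxes the constraint to
#' "explained by either parent" for sensitivity analysis.
#'
#' @param child,mother,father [GenotypeCall-class] objects for one locus.
#' @param resolution comparison resolution in digits (2, 4, 6, 8).
#' @param ignoreSuffix drop expression suffixes before comparing.
#' @param requireDistinctParents enforce one allele per parent (default).
#' @return a [TrioMatch-class].
#' @examples
#' ch <- genotypeCall("c", "A", c("A*02:01", "A*01:01"))
#' mo <- genotypeCall("m", "A", c("A*02:01", "A*03:01"))
#' fa <- genotypeCall("f", "A", c("A*01:01", "A*11:01"))
#' matchTrioLocus(ch, mo, fa)
#' @export
matchTrioLocus <- function(child, mother, father, resolution = 4L,
                           ignoreSuffix = TRUE,
                           requireDistinctParents = TRUE) {
  stopifnot(is(child, "GenotypeCall"), is(mother, "GenotypeCall"),
            is(father, "GenotypeCall"))
  if (child@locus != mother@locus || child@locus != father@locus)
    stop(sprintf("locus mismatch across the trio: %s / %s / %s",
                 child@locus, mother@locus, father@locus))
  ck <- .reduceKey(child@alleles, resolution, ignoreSuffix)
  mk <- .reduceKey(mother@alleles, resolution, ignoreSuffix)
  fk <- .reduceKey(father@alleles, resolution, ignoreSuffix)
  m <- .matchKeys(ck, mk, fk, requireDistinctParents)
  new("TrioMatch", familyId = NA_character_, locus = child@locus,
      nEq = m$nEq, assignment = m$assignment, ambiguous = m$ambiguous)
}

# per-family-locus matching over a cohort; returns per-trio rows plus
# exclusions. Used by descentAccuracy() and classifyTransmission().
.cohortMatches <- function(cohort, method, resolution, ignoreSuffix,
                           requireDistinctParents) {
  idx <- .typingIndex(cohort)
  t <- cohort@typings
  fams <- completeFamilies(cohort)
  rows <- list()
  excluded <- list()
  for (fam in fams) {
    mem <- .familyMembers(cohort, fam)
    for (locus in cohort@loci) {
      keys <- paste(method, c(mem$child, mem$mother, mem$father), locus,
                    sep = "\r")
      i <- idx[keys]
      if (anyNA(i)) {
        missing <- c("child", "mother", "father")[is.na(i)]
        excluded[[length(excluded) + 1L]] <- data.frame(
          family_id = fam, locus = locus,
          reason = paste("missing call for", paste(missing, collapse = "/")),
          stringsAsFactors = FALSE)
        next
      }
      get2 <- function(j) .reduceKey(c(t$allele1[j], t$allele2[j]),
                                     resolution, ignoreSuffix)
      m <- .matchKeys(get2(i[1L]), get2(i[2L]), get2(i[3L]),
                      requireDistinctParents)
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = fam, locus = locus, n_eq = m$nEq,
        ambiguous = m$ambiguous, stringsAsFactors = FALSE)
    }
  }
  list(matches = if (length(rows)) do.call(rbind, rows) else
         data.frame(family_id = character(0), locus = character(0),
                    n_eq = integer(0), ambiguous = logical(0)),
       excluded = if (length(excluded)) do.call(rbind, excluded) else
         data.frame(family_id = character(0), locus = character(0),
                    reason = character(0)))
}

#' Descent Accuracy of a typing method on a trio cohort
#'
#' Computes DA = N_eq / N_alleles over all complete families with calls for
#' the method, where N_eq sums the explained child alleles from
#' [matchTrioLocus()] and the denominator counts two alleles per child per
#' evaluated locus. Family x locus combinations missing any of the three
#' calls are excluded from that locus only and listed in the report.
#'
#' @param cohort a [TrioCohort-class].
#' @param method method label to evaluate.
#' @param resolution comparison resolution in digits.
#' @param ignoreSuffix drop expression suffixes before comparing.
#' @param requireDistinctParents enforce one allele per parent (default).
#' @return a [DAReport-class].
#' @export
descentAccuracy <- function(cohort, method, resolution = 4L,
                            ignoreSuffix = TRUE,
                            requireDistinctParents = TRUE) {
  stopifnot(is(cohort, "TrioCohort"))
  if (!method %in% cohortMethods(cohort))
    stop(sprintf("method '%s' has no typings in this cohort", method))
  res <- .cohortMatches(cohort, method, resolution, ignoreSuffix,
                        requireDistinctParents)
  m <- res$matches
  if (!nrow(m))
    stop("no evaluable complete family with calls for method '", method, "'")
  perLocus <- do.call(rbind, lapply(split(m, m$locus), function(d) {
    data.frame(locus = d$locus[1L], n_children = nrow(d),
               n_eq = sum(d$n_eq), n_alleles = 2L * nrow(d),
               da = sum(d$n_eq) / (2L * nrow(d)), stringsAsFactors = FALSE)
  }))
  perLocus <- perLocus[order(match(perLocus$locus, cohort@loci)), ]
  rownames(perLocus) <- NULL
  nEq <- sum(perLocus$n_eq)
  nAlleles <- sum(perLocus$n_alleles)
  new("DAReport", method = method, resolution = as.integer(resolution),
      nEq = as.integer(nEq), nAlleles = as.integer(nAlleles),
      nChildren = length(unique(m$family_id)),
      loci = unique(m$locus), daOverall = nEq / nAlleles,
      perLocus = perLocus, perTrio = m, excluded = res$excluded)
}

#' @describeIn DAReport overall Descent Accuracy ratio.
#' @param report a \code{DAReport}.
#' @export
daOverall <- function(report) {
  stopifnot(is(report, "DAReport"))
  report@daOverall
}

#' @describeIn DAReport named vector of per-locus DA ratios.
#' @export
daPerLocus <- function(report) {
  stopifnot(is(report, "DAReport"))
  stats::setNames(report@perLocus$da, report@perLocus$locus)
}

#' Classify transmitted and non-transmitted parental allele slots
#'
#' For one complete family and method, marks for each parent and locus
#' which of the parent's two allele slots was transmitted to the child,
#' using the maximal assignment from [matchTrioLocus()]. A homozygous
#' parent transmits its first slot by tie-break (flagged
#' \code{slot_ambiguous}). Parents whose assigned child allele cannot be
#' matched, loci with ambiguous maximal assignments and loci with missing
#' calls are marked unresolved.
#'
#' @param cohort a [TrioCohort-class].
#' @param familyId a complete family id.
#' @param method method label whose calls define the phase.
#' @param resolution comparison resolution in digits.
#' @param ignoreSuffix drop expression suffixes before comparing.
#' @param requireDistinctParents enforce one allele per parent (default).
#' @return data.frame with columns \code{family_id}, \code{locus},
#'   \code{sample_id}, \code{role}, \code{slot}, \code{allele},
#'   \code{status} (transmitted / non_transmitted / unresolved) and
#'   \code{slot_ambiguous}.
#' @export
classifyTransmission <- function(cohort, familyId, method, resolution = 4L,
                                 ignoreSuffix = TRUE,
                                 requireDistinctParents = TRUE) {
  stopifnot(is(cohort, "TrioCohort"))
  if (familyId %in% cohort@incompleteFamilies ||
      !familyId %in% cohort@samples$family_id)
    stop(sprintf("family '%s' is not a complete trio", familyId))
  mem <- .familyMembers(cohort, familyId)
  idx <- .typingIndex(cohort)
  t <- cohort@typings
  out <- list()
  for (locus in cohort@loci) {
    keys <- paste(method, c(mem$child, mem$mother, mem$father), locus,
                  sep = "\r")
    i <- idx[keys]
    parentIds <- c(mother = mem$mother, father = mem$father)
    emit <- function(role, slot, allele, status, slotAmb = FALSE) {
      data.frame(family_id = familyId, locus = locus,
                 sample_id = parentIds[[role]], role = role,
                 slot = as.integer(slot), allele = allele, status = status,
                 slot_ambiguous = slotAmb, stringsAsFactors = FALSE)
    }
    if (anyNA(i)) {
      for (role in c("mother", "father")) {
        j <- idx[paste(method, parentIds[[role]], locus, sep = "\r")]
        al <- if (is.na(j)) c(NA_character_, NA_character_) else
          c(t$allele1[j], t$allele2[j])
        out[[length(out) + 1L]] <- rbind(emit(role, 1L, al[1L], "unresolved"),
                                         emit(role, 2L, al[2L], "unresolved"))
      }
      next
    }
    alleles <- list(child = c(t$allele1[i[1L]], t$allele2[i[1L]]),
                    mother = c(t$allele1[i[2L]], t$allele2[i[2L]]),
                    father = c(t$allele1[i[3L]], t$allele2[i[3L]]))
    keysRed <- lapply(alleles, .reduceKey, resolution, ignoreSuffix)
    m <- .matchKeys(keysRed$child, keysRed$mother, keysRed$father,
                    requireDistinctParents)
    for (role in c("mother", "father")) {
      pk <- keysRed[[role]]
      pa <- alleles[[role]]
      assigned <- m$assignment[m$assignment$parent == role, , drop = FALSE]
      if (m$ambiguous || nrow(assigned) == 0L) {
        out[[length(out) + 1L]] <- rbind(emit(role, 1L, pa[1L], "unresolved"),
                                         emit(role, 2L, pa[2L], "unresolved"))
        next
      }
      tslot <- which(pk == assigned$child_allele[1L])[1L]
      slotAmb <- pk[1L] == pk[2L]
      status <- c("non_transmitted", "non_transmitted")
      status[tslot] <- "transmitted"
      out[[length(out) + 1L]] <- rbind(
        emit(role, 1L, pa[1L], status[1L], slotAmb),
        emit(role, 2L, pa[2L], status[2L], slotAmb))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Agreement between two unordered allele pairs
#'
#' The number of identically typed alleles between two calls for the same
#' sample and locus: the size (0, 1 or 2) of the multiset intersection of
#' the two unordered pairs after reduction. A homozygous pair matching a
#' heterozygous one contributes 1, not 2.
#'
#' @param a,b character vectors of length 2 (canonical colon identifiers)
#'   or [GenotypeCall-class] objects.
#' @param resolution comparison resolution in digits.
#' @param ignoreSuffix drop expression suffixes before comparing.
#' @return integer in 0..2.
#' @examples
#' alleleAgreement(c("A*02:01", "A*02:01"), c("A*02:01", "A*01:01"))
#' @export
alleleAgreement <- function(a, b, resolution = 4L, ignoreSuffix = TRUE) {
  if (is(a, "GenotypeCall")) a <- a@alleles
  if (is(b, "GenotypeCall")) b <- b@alleles
  ra <- .reduceKey(.canonicalAllele(a), resolution, ignoreSuffix)
  rb <- .reduceKey(.canonicalAllele(b), resolution, ignoreSuffix)
  sum(.slotAgreement(ra, rb))
}

# per-slot agreement indicators for the pair ra against multiset rb;
# greedy slot-by-slot removal realises a maximum multiset matching
.slotAgreement <- function(ra, rb) {
  hit <- c(FALSE, FALSE)
  pool <- rb
  for (s in 1:2) {
    j <- match(ra[s], pool)
    if (!is.na(j)) {
      hit[s] <- TRUE
      pool <- pool[-j]
    }
  }
  hit
}

#' Method Agreement between two typing methods
#'
#' Computes MA = N_agree / (N_population x 2 x |loci|) over individuals
#' typed at every locus by both methods (others are excluded and listed).
#' Per sample and locus the agreement count is the multiset intersection of
#' the two unordered pairs after reduction. MA_T (resp. MA_NT) restricts
#' numerator and denominator to allele slots of the phase-reference
#' method's calls classified transmitted (resp. non-transmitted) by
#' [classifyTransmission()]; child alleles count as transmitted, and
#' unresolved slots are excluded from both classes and counted separately.
#'
#' @param cohort a [TrioCohort-class].
#' @param methodA,methodB distinct method labels.
#' @param resolution comparison resolution in digits.
#' @param phaseReference method whose calls define transmission phase
#'   (default \code{methodA}).
#' @param ignoreSuffix drop expression suffixes before comparing.
#' @return an [MAReport-class].
#' @export
methodAgreement <- function(cohort, methodA, methodB, resolution = 4L,
                            phaseReference = methodA, ignoreSuffix = TRUE) {
  stopifnot(is(cohort, "TrioCohort"))
  if (methodA == methodB)
    stop("methodA and methodB must be different typing methods")
  for (m in unique(c(methodA, methodB, phaseReference)))
    if (!m %in% cohortMethods(cohort))
      stop(sprintf("method '%s' has no typings in this cohort", m))
  t <- cohort@typings
  loci <- cohort@loci
  countLoci <- function(meth) {
    d <- t[t$method == meth & t$locus %in% loci, ]
    tab <- table(d$sample_id)
    names(tab)[tab == length(loci)]
  }
  common <- intersect(countLoci(methodA), countLoci(methodB))
  allTyped <- unique(t$sample_id[t$method %in% c(methodA, methodB)])
  excludedSamples <- setdiff(allTyped, common)
  if (!length(common))
    stop(sprintf("no sample is typed at all loci by both '%s' and '%s'",
                 methodA, methodB))

  idx <- .typingIndex(cohort)
  # transmission phase under the reference method: status per
  # (sample, locus, slot) of that method's calls
  status <- new.env(parent = emptyenv())
  skey <- function(sid, locus, slot) paste(sid, locus, slot, sep = "\r")
  samples <- cohort@samples
  fams <- completeFamilies(cohort)
  for (fam in fams) {
    mem <- .familyMembers(cohort, fam)
    phase <- tryCatch(
      classifyTransmission(cohort, fam, phaseReference, resolution,
                           ignoreSuffix),
      error = function(e) NULL)
    if (is.null(phase)) next
    for (r in seq_len(nrow(phase)))
      assign(skey(phase$sample_id[r], phase$locus[r], phase$slot[r]),
             phase$status[r], envir = status)
    # child alleles are inherited by definition: transmitted wherever the
    # trio locus was evaluable (parents not unresolved for missing calls)
    for (locus in loci) {
      evaluable <- !anyNA(idx[paste(
        phaseReference, c(mem$child, mem$mother, mem$father), locus,
        sep = "\r")])
      st <- if (evaluable) "transmitted" else "unresolved"
      for (slot in 1:2)
        assign(skey(mem$child, locus, slot), st, envir = status)
    }
  }

  num <- stats::setNames(numeric(length(loci)), loci)        # total agree
  numT <- denT <- numNT <- denNT <- num
  nUnresolved <- 0L
  perInd <- stats::setNames(integer(length(common)), common)
  for (sid in common) {
    for (locus in loci) {
      ia <- idx[paste(methodA, sid, locus, sep = "\r")]
      ib <- idx[paste(methodB, sid, locus, sep = "\r")]
      pa <- .reduceKey(c(t$allele1[ia], t$allele2[ia]), resolution,
                       ignoreSuffix)
      pb <- .reduceKey(c(t$allele1[ib], t$allele2[ib]), resolution,
                       ignoreSuffix)
      # slot indicators on the phase-reference method's call
      ref <- if (phaseReference == methodB) pb else pa
      oth <- if (phaseReference == methodB) pa else pb
      hit <- .slotAgreement(ref, oth)
      agree <- sum(hit)
      num[locus] <- num[locus] + agree
      perInd[sid] <- perInd[sid] + agree
      for (slot in 1:2) {
        st <- if (exists(skey(sid, locus, slot), envir = status))
          get(skey(sid, locus, slot), envir = status) else "unresolved"
        if (st == "transmitted") {
          denT[locus] <- denT[locus] + 1L
          numT[locus] <- numT[locus] + hit[slot]
        } else if (st == "non_transmitted") {
          denNT[locus] <- denNT[locus] + 1L
          numNT[locus] <- numNT[locus] + hit[slot]
        } else {
          nUnresolved <- nUnresolved + 1L
        }
      }
    }
  }
  nPop <- length(common)
  den <- stats::setNames(rep(2L * nPop, length(loci)), loci)
  ratio <- function(n, d) ifelse(d > 0, n / d, NA_real_)
  perLocus <- data.frame(
    locus = loci, n_agree = as.integer(num), n_slots = as.integer(den),
    ma_total = ratio(num, den),
    n_agree_t = as.integer(numT), n_slots_t = as.integer(denT),
    ma_t = ratio(numT, denT),
    n_agree_nt = as.integer(numNT), n_slots_nt = as.integer(denNT),
    ma_nt = ratio(numNT, denNT), stringsAsFactors = FALSE)
  rownames(perLocus) <- NULL
  new("MAReport", methods = c(methodA, methodB),
      resolution = as.integer(resolution), nPopulation = as.integer(nPop),
      loci = loci, nAgree = as.integer(sum(num)),
      maTotal = sum(num) / sum(den),
      maT = ratio(sum(numT), sum(denT)),
      maNT = ratio(sum(numNT), sum(denNT)),
      perLocus = perLocus,
      perIndividual = data.frame(sample_id = names(perInd),
                                 n_agree = as.integer(perInd),
                                 stringsAsFactors = FALSE, row.names = NULL),
      nUnresolvedSlots = as.integer(nUnresolved),
      excludedSamples = excludedSamples, phaseReference = phaseReference)
}

#' @describeIn MAReport overall Method Agreement ratio.
#' @param report an \code{MAReport}.
#' @export
maTotal <- function(report) {
  stopifnot(is(report, "MAReport"))
  report@maTotal
}

#' @describeIn MAReport agreement ratio over transmitted allele slots.
#' @export
maTransmitted <- function(report) {
  stopifnot(is(report, "MAReport"))
  report@maT
}

#' @describeIn MAReport agreement ratio over non-transmitted allele slots.
#' @export
maNonTransmitted <- function(report) {
  stopifnot(is(report, "MAReport"))
  report@maNT
}

#' Per-individual concordance histogram
#'
#' Tabulates how many individuals were typed with each possible number of
#' identical alleles (0 to 2 x number of loci) by the two methods of an
#' [MAReport-class] — the per-individual concordance distribution.
#'
#' @param report an [MAReport-class].
#' @return data.frame with columns \code{n_agree} and \code{n_individuals};
#'   the counts sum to the MA population size.
#' @export
agreementHistogram <- function(report) {
  stopifnot(is(report, "MAReport"))
  lev <- 0:(2L * length(report@loci))
  counts <- table(factor(report@perIndividual$n_agree, levels = lev))
  data.frame(n_agree = lev, n_individuals = as.integer(counts))
}

setMethod("show", "DAReport", function(object) {
  cat(sprintf("Descent Accuracy: method '%s' at %d-digit resolution\n",
              object@method, object@resolution))
  cat(sprintf("  DA = %d / %d = %.4f over %d children\n", object@nEq,
              object@nAlleles, object@daOverall, object@nChildren))
  for (i in seq_len(nrow(object@perLocus)))
    cat(sprintf("  %-4s DA = %.4f (%d/%d)\n", object@perLocus$locus[i],
                object@perLocus$da[i], object@perLocus$n_eq[i],
                object@perLocus$n_alleles[i]))
  if (nrow(object@excluded))
    cat(sprintf("  %d family x locus combination(s) excluded\n",
                nrow(object@excluded)))
  invisible(NULL)
})

setMethod("show", "MAReport", function(object) {
  cat(sprintf("Method Agreement: '%s' vs '%s' at %d-digit resolution\n",
              object@methods[1L], object@methods[2L], object@resolution))
  cat(sprintf("  MA_total = %.4f (%d agreeing alleles, %d individuals)\n",
              object@maTotal, object@nAgree, object@nPopulation))
  cat(sprintf("  MA_T = %s, MA_NT = %s (phase ref '%s', %d unresolved slots)\n",
              format(round(object@maT, 4)), format(round(object@maNT, 4)),
              object@phaseReference, object@nUnresolvedSlots))
  invisible(NULL)
})
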