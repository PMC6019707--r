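# HLA allele nomenclature: parsing, formatting, reduction and comparison.
#
# Identifiers are composed of up to four numeric fields separated by colons
# (gene*f1:f2:f3:f4) plus an optional expression suffix letter. The number
# of fields determines the resolution: 2-digit (allele group / serotype),
# 4-digit (protein), 6-digit (synonymous variants), 8-digit (non-coding
# variants). The underscore dialect is the token style used in Polysolver
# winners files (hla_a_02_01_01_02).

.EXPRESSION_SUFFIXES <- c("N", "L", "S", "C", "A", "Q")

.emptyAllele <- function(n = 0L) {
  new("HLAAllele", gene = character(n),
      fields = matrix(NA_character_, nrow = n, ncol = 4L),
      suffix = rep(NA_character_, n))
}

.parseOne <- function(text, dialect, idx) {
  raw <- text
  x <- trimws(text)
  if (is.na(x) || !nzchar(x))
    stop(sprintf("allele identifier %d is empty", idx), call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("*", x, fixed = TRUE)) "colon" else "underscore"
  }
  if (dialect == "colon") {
    x <- sub("^[Hh][Ll][Aa]-", "", x)
    parts <- strsplit(x, "*", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !nzchar(parts[1L]))
      stop(sprintf("malformed allele identifier '%s': expected '<gene>*<field>[:<field>...]'",
                   raw), call. = FALSE)
    gene <- parts[1L]
    toks <- strsplit(parts[2L], ":", fixed = TRUE)[[1L]]
    if (grepl(":$", parts[2L])) toks <- c(toks, "")
  } else {
    x <- sub("^[Hh][Ll][Aa]_", "", x)
    toks <- strsplit(x, "_", fixed = TRUE)[[1L]]
    if (length(toks) < 2L)
      stop(sprintf("malformed underscore identifier '%s': expected 'hla_<gene>_<field>[_<field>...]'",
                   raw), call. = FALSE)
    gene <- toupper(toks[1L])
    toks <- toks[-1L]
  }
  if (!grepl("^[A-Za-z][A-Za-z0-9]*$", gene))
    stop(sprintf("invalid gene symbol '%s' in '%s'", gene, raw), call. = FALSE)
  if (length(toks) == 0L || !nzchar(toks[1L]))
    stop(sprintf("no allele fields in '%s'", raw), call. = FALSE)
  if (length(toks) > 4L)
    stop(sprintf("'%s' has %d fields; at most 4 are allowed", raw, length(toks)),
         call. = FALSE)
  suffix <- NA_character_
  last <- toks[length(toks)]
  m <- regmatches(last, regexec("^([0-9]{2,4})[ ]?([A-Za-z])$", last))[[1L]]
  if (length(m) == 3L) {
    suffix <- toupper(m[3L])
    if (suffix %in% c("G", "P"))
      stop(sprintf("'%s' is a %s-group ambiguity identifier; these are not supported",
                   raw, suffix), call. = FALSE)
    if (!suffix %in% .EXPRESSION_SUFFIXES)
      stop(sprintf("unknown expression suffix '%s' in '%s'", m[3L], raw),
           call. = FALSE)
    toks[length(toks)] <- m[2L]
  }
  bad <- !grepl("^[0-9]{2,4}$", toks)
  if (any(bad)) {
    tok <- toks[which(bad)[1L]]
    if (!nzchar(tok))
      stop(sprintf("empty field in '%s'", raw), call. = FALSE)
    stop(sprintf("non-numeric field '%s' in '%s'", tok, raw), call. = FALSE)
  }
  list(gene = gene, fields = toks, suffix = suffix)
}

#' Parse HLA allele identifiers
#'
#' Parses textual HLA allele identifiers into an [HLAAllele-class] vector.
#' Two dialects are supported: the standard colon dialect
#' (\code{"HLA-A*02:01:01:02L"}, \code{"A*02:01"}; the \code{"HLA-"} prefix
#' and surrounding whitespace are optional) and the underscore dialect used
#' in Polysolver winners files (\code{"hla_a_02_01_01_02"}). With
#' \code{dialect = "auto"} (default) identifiers containing \code{"*"} are
#' read as colon dialect and all others as underscore dialect. A trailing
#' letter attached to the last field is extracted as the expression suffix.
#' G/P ambiguity-group identifiers are rejected with an error rather than
#' silently truncated.
#'
#' @param text character vector of allele identifiers.
#' @param dialect \code{"auto"}, \code{"colon"} or \code{"underscore"}.
#' @return An [HLAAllele-class] of the same length as \code{text}.
#' @examples
#' parseHLAAllele("HLA-A*02:01:01:02L")
#' parseHLAAllele("hla_b_07_02")
#' @export
parseHLAAllele <- function(text, dialect = c("auto", "colon", "underscore")) {
  dialect <- match.arg(dialect)
  if (!is.character(text))
    stop("'text' must be a character vector")
  parsed <- lapply(seq_along(text), function(i) .parseOne(text[i], dialect, i))
  fields <- matrix(NA_character_, nrow = length(text), ncol = 4L)
  for (i in seq_along(parsed))
    fields[i, seq_along(parsed[[i]]$fields)] <- parsed[[i]]$fields
  new("HLAAllele",
      gene = vapply(parsed, `[[`, character(1L), "gene"),
      fields = fields,
      suffix = vapply(parsed, `[[`, character(1L), "suffix"))
}

#' Format HLA allele identifiers as text
#'
#' Serialises an [HLAAllele-class] vector back to text.
#' \code{parseHLAAllele(formatHLAAllele(a))} recovers \code{a} exactly.
#'
#' @param a an [HLAAllele-class].
#' @param dialect \code{"colon"} (default, \code{"A*02:01"}) or
#'   \code{"underscore"} (\code{"hla_a_02_01"}).
#' @param withPrefix prepend \code{"HLA-"} in the colon dialect; the
#'   underscore dialect always carries its \code{"hla_"} prefix.
#' @return character vector of identifiers.
#' @examples
#' a <- parseHLAAllele("A*02:01:01:02L")
#' formatHLAAllele(a, withPrefix = TRUE)
#' formatHLAAllele(parseHLAAllele("B*07:02"), dialect = "underscore")
#' @export
formatHLAAllele <- function(a, dialect = c("colon", "underscore"),
                            withPrefix = FALSE) {
  stopifnot(is(a, "HLAAllele"))
  dialect <- match.arg(dialect)
  n <- length(a@gene)
  out <- character(n)
  for (i in seq_len(n)) {
    f <- a@fields[i, ]
    f <- f[!is.na(f)]
    sfx <- a@suffix[i]
    if (dialect == "colon") {
      out[i] <- paste0(if (withPrefix) "HLA-" else "", a@gene[i], "*",
                       paste(f, collapse = ":"),
                       if (is.na(sfx)) "" else sfx)
    } else {
      out[i] <- paste0("hla_", tolower(a@gene[i]), "_",
                       paste(f, collapse = "_"),
                       if (is.na(sfx)) "" else tolower(sfx))
    }
  }
  out
}

#' Resolution of an allele identifier
#'
#' The resolution in digits is twice the number of numeric fields:
#' \code{A*02} has 2-digit, \code{A*02:01} 4-digit and
#' \code{A*02:01:01:02} 8-digit resolution.
#'
#' @param a an [HLAAllele-class].
#' @return integer vector with values in 2, 4, 6, 8.
#' @export
resolutionOf <- function(a) {
  stopifnot(is(a, "HLAAllele"))
  as.integer(2L * rowSums(!is.na(a@fields)))
}

#' Reduce alleles to a coarser resolution
#'
#' Truncates identifiers above the target resolution to its number of
#' fields, dropping the expression suffix (an allele \code{A*02:01:01:02}
#' becomes \code{A*02:01} at 4 digits). Identifiers already at or below the
#' target are returned unchanged (no padding); the operation is idempotent.
#'
#' @param a an [HLAAllele-class].
#' @param targetResolution 2, 4, 6 or 8.
#' @return an [HLAAllele-class].
#' @examples
#' formatHLAAllele(reduceAllele(parseHLAAllele("A*02:01:01:02"), 4))
#' @export
reduceAllele <- function(a, targetResolution) {
  stopifnot(is(a, "HLAAllele"))
  if (length(targetResolution) != 1L || !targetResolution %in% c(2, 4, 6, 8))
    stop("'targetResolution' must be one of 2, 4, 6, 8")
  k <- as.integer(targetResolution / 2L)
  over <- rowSums(!is.na(a@fields)) > k
  if (any(over)) {
    if (k < 4L) a@fields[over, (k + 1L):4L] <- NA_character_
    a@suffix[over] <- NA_character_
  }
  a
}

#' Compare alleles at a fixed resolution
#'
#' Two alleles are equal at resolution r when their gene symbols match and
#' their reductions to r have identical fields. Expression suffixes are
#' ignored by default, matching the convention that they play no role in
#' typing comparisons; set \code{ignoreSuffix = FALSE} for strict
#' comparison.
#'
#' @param a,b [HLAAllele-class] vectors (recycled to a common length).
#' @param resolution 2, 4, 6 or 8.
#' @param ignoreSuffix drop expression suffixes before comparing.
#' @return logical vector.
#' @examples
#' allelesEqualAt(parseHLAAllele("A*02:01:01:02"), parseHLAAllele("A*02:01"), 4)
#' @export
allelesEqualAt <- function(a, b, resolution = 4L, ignoreSuffix = TRUE) {
  stopifnot(is(a, "HLAAllele"), is(b, "HLAAllele"))
  ka <- .alleleKey(a, resolution, ignoreSuffix)
  kb <- .alleleKey(b, resolution, ignoreSuffix)
  if (length(ka) != length(kb)) {
    n <- max(length(ka), length(kb))
    ka <- rep_len(ka, n)
    kb <- rep_len(kb, n)
  }
  ka == kb
}

#' Serotype group of an allele
#'
#' The 2-digit allele group shared by alleles with the same serological
#' reactivity; equivalent to reduction to 2-digit resolution.
#'
#' @param a an [HLAAllele-class].
#' @return an [HLAAllele-class] at 2-digit resolution.
#' @export
serotypeGroup <- function(a) reduceAllele(a, 2L)

# canonical comparison key at a given resolution
.alleleKey <- function(a, resolution = 4L, ignoreSuffix = TRUE) {
  r <- reduceAllele(a, resolution)
  if (ignoreSuffix) r@suffix[] <- NA_character_
  formatHLAAllele(r)
}

# Fast string-level reduction for canonical colon-dialect identifiers as
# stored in TrioCohort typings. Mirrors reduceAllele()/.alleleKey() without
# a parse round-trip; only safe on canonical strings.
.reduceKey <- function(x, resolution = 4L, ignoreSuffix = TRUE) {
  if (ignoreSuffix) x <- sub("(?<=[0-9])[A-Z]$", "", x, perl = TRUE)
  k <- as.integer(resolution / 2L)
  parts <- strsplit(x, "*", fixed = TRUE)
  vapply(parts, function(p) {
    f <- strsplit(p[[2L]], ":", fixed = TRUE)[[1L]]
    if (length(f) > k) {
      paste0(p[[1L]], "*", paste(f[seq_len(k)], collapse = ":"))
    } else {
      paste0(p[[1L]], "*", p[[2L]])
    }
  }, character(1L))
}

# parse arbitrary-dialect text and return canonical colon strings
.canonicalAllele <- function(text, dialect = "auto") {
  formatHLAAllele(parseHLAAllele(text, dialect))
}

#' @describeIn HLAAllele number of alleles in the vector.
#' @param x an \code{HLAAllele}.
#' @export
setMethod("length", "HLAAllele", function(x) length(x@gene))

#' @describeIn HLAAllele canonical colon-dialect identifiers.
#' @export
setMethod("as.character", "HLAAllele", function(x) formatHLAAllele(x))

#' @describeIn HLAAllele subset the vector.
#' @param i index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "HLAAllele", function(x, i, j, ..., drop = TRUE) {
  new("HLAAllele", gene = x@gene[i],
      fields = x@fields[i, , drop = FALSE],
      suffix = x@suffix[i])
})

setMethod("show", "HLAAllele", function(object) {
  n <- length(object)
  cat(sprintf("HLAAllele of length %d\n", n))
  if (n) {
    shown <- utils::head(formatHLAAllele(object), 10L)
    res <- utils::head(resolutionOf(object), 10L)
    cat(paste0("  ", format(shown), "  [", res, "-digit]\n"), sep = "")
    if (n > 10L) cat(sprintf("  ... and %d more\n", n - 10L))
  }
  invisible(NULL)
})
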