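# Tabular input/output: pedigrees, genotype tables (generic and two typer
# output dialects), reference frequency tables and CWD catalogues. All
# formats are plain tab-separated text; reader errors carry row/line
# numbers.

.readTSV <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    blank.lines.skip = TRUE, stringsAsFactors = FALSE)
}

.requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
}

#' Read a pedigree file
#'
#' Reads a tab-separated pedigree with header \code{sample_id},
#' \code{family_id}, \code{role} (father / mother / child). Duplicate
#' sample ids or two same-role members in one family are errors; families
#' missing a member trigger a warning and are flagged via the
#' \code{"incompleteFamilies"} attribute of the result.
#'
#' @param path file path.
#' @return data.frame of sample records with attribute
#'   \code{incompleteFamilies}.
#' @export
readPedigree <- function(path) {
  df <- .readTSV(path)
  .requireColumns(df, c("sample_id", "family_id", "role"), path)
  df <- df[, c("sample_id", "family_id", "role")]
  bad <- which(!df$role %in% .ROLES)
  if (length(bad))
    stop(sprintf("'%s' row %d: unknown role '%s' (expected father, mother or child)",
                 path, bad[1L], df$role[bad[1L]]))
  dup <- which(duplicated(df$sample_id))
  if (length(dup))
    stop(sprintf("'%s' row %d: duplicate sample_id '%s'", path, dup[1L],
                 df$sample_id[dup[1L]]))
  dupRole <- which(duplicated(paste(df$family_id, df$role)))
  if (length(dupRole))
    stop(sprintf("'%s' row %d: family '%s' has two members with role '%s'",
                 path, dupRole[1L], df$family_id[dupRole[1L]],
                 df$role[dupRole[1L]]))
  fams <- split(df$role, df$family_id)
  incomplete <- names(fams)[!vapply(fams, function(r) all(.ROLES %in% r),
                                    logical(1L))]
  if (length(incomplete))
    warning(sprintf("incomplete famil%s (missing a role): %s",
                    if (length(incomplete) > 1L) "ies" else "y",
                    paste(incomplete, collapse = ", ")))
  attr(df, "incompleteFamilies") <- incomplete
  df
}

#' Write a pedigree file
#'
#' @param samples data.frame with columns \code{sample_id},
#'   \code{family_id}, \code{role} (e.g. from [cohortSamples()]).
#' @param path output file path.
#' @export
writePedigree <- function(samples, path) {
  utils::write.table(samples[, c("sample_id", "family_id", "role")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a generic genotype-call table
#'
#' Reads a tab-separated table with header \code{sample_id}, \code{locus},
#' \code{allele1}, \code{allele2}; alleles in the colon dialect. Parse
#' failures and allele/locus gene mismatches are reported with the
#' offending row number and token.
#'
#' @param path file path.
#' @param methodLabel typing method label attached to every call.
#' @return data.frame of typings (\code{method}, \code{sample_id},
#'   \code{locus}, \code{allele1}, \code{allele2}) with canonical, sorted
#'   allele pairs, ready for [TrioCohort()].
#' @export
readGenotypeTable <- function(path, methodLabel) {
  df <- .readTSV(path)
  .requireColumns(df, c("sample_id", "locus", "allele1", "allele2"), path)
  n <- nrow(df)
  a1 <- a2 <- character(n)
  for (i in seq_len(n)) {
    for (col in c("allele1", "allele2")) {
      res <- tryCatch(.canonicalAllele(df[[col]][i], dialect = "colon"),
                      error = function(e)
                        stop(sprintf("'%s' row %d, column %s: %s", path, i,
                                     col, conditionMessage(e)), call. = FALSE))
      gene <- sub("\\*.*$", "", res)
      if (gene != df$locus[i])
        stop(sprintf("'%s' row %d: allele '%s' does not belong to locus '%s'",
                     path, i, df[[col]][i], df$locus[i]))
      if (col == "allele1") a1[i] <- res else a2[i] <- res
    }
  }
  data.frame(method = rep(methodLabel, n), sample_id = df$sample_id,
             locus = df$locus, allele1 = pmin(a1, a2),
             allele2 = pmax(a1, a2), stringsAsFactors = FALSE)
}

#' Write a generic genotype-call table
#'
#' Inverse of [readGenotypeTable()]: writes \code{sample_id}, \code{locus},
#' \code{allele1}, \code{allele2} (colon dialect) for one method.
#'
#' @param typings typings data.frame (e.g. from [cohortTypings()]).
#' @param path output file path.
#' @param method optional method label to filter on when \code{typings}
#'   stacks several methods.
#' @export
writeGenotypeTable <- function(typings, path, method = NULL) {
  if (!is.null(method)) typings <- typings[typings$method == method, ]
  utils::write.table(typings[, c("sample_id", "locus", "allele1", "allele2")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an Optitype result table
#'
#' Reads the Optitype result dialect: a tab-separated table whose columns
#' include \code{A1}, \code{A2}, \code{B1}, \code{B2}, \code{C1}, \code{C2}
#' holding 4-digit colon identifiers without the \code{"HLA-"} prefix
#' (score columns are ignored). One result row yields three genotype calls
#' (loci A, B, C) with method label \code{"optitype"}.
#'
#' @param path file path.
#' @param sampleId sample the result belongs to.
#' @return typings data.frame as in [readGenotypeTable()].
#' @export
readOptitypeResult <- function(path, sampleId) {
  df <- .readTSV(path)
  cols <- c("A1", "A2", "B1", "B2", "C1", "C2")
  .requireColumns(df, cols, path)
  if (nrow(df) < 1L) stop(sprintf("'%s' has no result row", path))
  row <- df[1L, ]
  out <- vector("list", 3L)
  for (k in seq_along(c("A", "B", "C"))) {
    locus <- c("A", "B", "C")[k]
    cells <- paste0(locus, 1:2)
    vals <- as.character(row[, cells])
    empty <- !nzchar(trimws(vals)) | is.na(vals)
    if (any(empty))
      stop(sprintf("'%s': empty allele cell %s", path, cells[which(empty)[1L]]))
    canon <- .canonicalAllele(vals, dialect = "colon")
    gene <- sub("\\*.*$", "", canon)
    if (!all(gene == locus))
      stop(sprintf("'%s': allele '%s' in column %s does not belong to locus %s",
                   path, vals[which(gene != locus)[1L]],
                   cells[which(gene != locus)[1L]], locus))
    out[[k]] <- data.frame(method = "optitype", sample_id = sampleId,
                           locus = locus, allele1 = min(canon),
                           allele2 = max(canon), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read a Polysolver winners file
#'
#' Reads the Polysolver winners dialect: three lines, one per class I
#' locus, of the form
#' \code{"HLA-A<TAB>hla_a_02_01_01_02<TAB>hla_a_01_01"}. Tokens are
#' underscore-dialect identifiers at native (up to 8-digit) resolution;
#' calls carry the method label \code{"polysolver"}.
#'
#' @param path file path.
#' @param sampleId sample the winners belong to.
#' @return typings data.frame as in [readGenotypeTable()].
#' @export
readPolysolverWinners <- function(path, sampleId) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 3L)
    stop(sprintf("'%s': expected 3 winner lines (one per locus), found %d",
                 path, length(lines)))
  out <- vector("list", 3L)
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[\t ]+")[[1L]]
    if (length(toks) != 3L)
      stop(sprintf("'%s' line %d: expected 'HLA-<locus> <allele> <allele>'",
                   path, i))
    locus <- sub("^[Hh][Ll][Aa]-", "", toks[1L])
    canon <- tryCatch(.canonicalAllele(toks[2:3], dialect = "underscore"),
                      error = function(e)
                        stop(sprintf("'%s' line %d: %s", path, i,
                                     conditionMessage(e)), call. = FALSE))
    gene <- sub("\\*.*$", "", canon)
    if (!all(gene == toupper(locus)))
      stop(sprintf("'%s' line %d: allele gene does not match locus '%s'",
                   path, i, toks[1L]))
    out[[i]] <- data.frame(method = "polysolver", sample_id = sampleId,
                           locus = toupper(locus), allele1 = min(canon),
                           allele2 = max(canon), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read a reference allele-frequency table
#'
#' Reads a tab-separated table with header \code{population},
#' \code{allele}, \code{frequency} (an optional \code{n} column records the
#' number of individuals behind the population sample). Alleles are reduced
#' to 4-digit resolution on input; frequencies outside [0, 1] are errors.
#'
#' @param path file path.
#' @return named list with one data.frame (\code{allele},
#'   \code{frequency}, and \code{n} when present) per population.
#' @export
readFrequencyReference <- function(path) {
  df <- .readTSV(path)
  .requireColumns(df, c("population", "allele", "frequency"), path)
  freq <- suppressWarnings(as.numeric(df$frequency))
  bad <- which(is.na(freq) | freq < 0 | freq > 1)
  if (length(bad))
    stop(sprintf("'%s' row %d: frequency '%s' is not in [0, 1]", path,
                 bad[1L], df$frequency[bad[1L]]))
  allele <- .reduceKey(.canonicalAllele(df$allele, dialect = "colon"), 4L)
  out <- data.frame(population = df$population, allele = allele,
                    frequency = freq, stringsAsFactors = FALSE)
  if ("n" %in% names(df)) out$n <- suppressWarnings(as.numeric(df$n))
  lapply(split(out, out$population),
         function(d) d[, setdiff(names(d), "population"), drop = FALSE])
}

#' Read a Common and Well-Documented allele catalogue
#'
#' Reads a tab-separated table with a single required column \code{allele}.
#' Entries are reduced to 4-digit resolution.
#'
#' @param path file path.
#' @return character vector of canonical 4-digit identifiers.
#' @export
readCWDCatalogue <- function(path) {
  df <- .readTSV(path)
  .requireColumns(df, "allele", path)
  unique(.reduceKey(.canonicalAllele(df$allele, dialect = "colon"), 4L))
}
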