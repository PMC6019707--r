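# Report serialisation: every evaluation report can be written as TSV (the
# per-locus table with an overall row, deterministic column order) or JSON
# (the full report including all numerators and denominators). Absent
# values are a literal NA token in TSV and null in JSON.

# tidy per-locus table with an "overall" row, used for the TSV form
setGeneric(".reportTable", function(report) standardGeneric(".reportTable"))

# full nested representation, used for the JSON form
setGeneric(".reportList", function(report) standardGeneric(".reportList"))

setMethod(".reportTable", "DAReport", function(report) {
  p <- report@perLocus
  rbind(
    data.frame(method = report@method, resolution = report@resolution,
               locus = p$locus, n_children = p$n_children, n_eq = p$n_eq,
               n_alleles = p$n_alleles, da = p$da, stringsAsFactors = FALSE),
    data.frame(method = report@method, resolution = report@resolution,
               locus = "overall", n_children = report@nChildren,
               n_eq = report@nEq, n_alleles = report@nAlleles,
               da = report@daOverall, stringsAsFactors = FALSE))
})

setMethod(".reportList", "DAReport", function(report) {
  list(statistic = "descent_accuracy", method = report@method,
       resolution = report@resolution, n_eq = report@nEq,
       n_alleles = report@nAlleles, n_children = report@nChildren,
       da_overall = report@daOverall, per_locus = report@perLocus,
       excluded = report@excluded)
})

setMethod(".reportTable", "MAReport", function(report) {
  p <- report@perLocus
  base <- data.frame(methods = paste(report@methods, collapse = "+"),
                     resolution = report@resolution, locus = p$locus,
                     stringsAsFactors = FALSE)
  overall <- data.frame(methods = paste(report@methods, collapse = "+"),
                        resolution = report@resolution, locus = "overall",
                        n_agree = report@nAgree,
                        n_slots = 2L * report@nPopulation * length(report@loci),
                        ma_total = report@maTotal,
                        n_agree_t = sum(p$n_agree_t),
                        n_slots_t = sum(p$n_slots_t), ma_t = report@maT,
                        n_agree_nt = sum(p$n_agree_nt),
                        n_slots_nt = sum(p$n_slots_nt), ma_nt = report@maNT,
                        stringsAsFactors = FALSE)
  rbind(cbind(base, p[, setdiff(names(p), "locus")]), overall)
})

setMethod(".reportList", "MAReport", function(report) {
  list(statistic = "method_agreement", methods = report@methods,
       resolution = report@resolution, n_population = report@nPopulation,
       n_agree = report@nAgree, ma_total = report@maTotal,
       ma_t = report@maT, ma_nt = report@maNT,
       phase_reference = report@phaseReference,
       n_unresolved_slots = report@nUnresolvedSlots,
       per_locus = report@perLocus, per_individual = report@perIndividual,
       excluded_samples = report@excludedSamples)
})

setMethod(".reportTable", "HRReport", function(report) {
  p <- report@perLocus
  rbind(
    data.frame(method = report@method, resolution = report@resolution,
               locus = p$locus, n_homozygous = p$n_homozygous,
               n_population = p$n_population, hr = p$hr,
               stringsAsFactors = FALSE),
    data.frame(method = report@method, resolution = report@resolution,
               locus = "overall", n_homozygous = sum(p$n_homozygous),
               n_population = sum(p$n_population), hr = report@hrOverall,
               stringsAsFactors = FALSE))
})

setMethod(".reportList", "HRReport", function(report) {
  list(statistic = "homozygosity_rate", method = report@method,
       resolution = report@resolution, roles = report@roles,
       hr_overall = report@hrOverall, hr_locus_mean = report@hrLocusMean,
       per_locus = report@perLocus)
})

setMethod(".reportTable", "AlleleFrequencyTable", function(report) {
  cbind(data.frame(method = report@method, resolution = report@resolution,
                   stringsAsFactors = FALSE)[rep(1L, nrow(report@table)), ,
                                             drop = FALSE],
        report@table, row.names = NULL)
})

setMethod(".reportList", "AlleleFrequencyTable", function(report) {
  list(statistic = "allele_frequencies", method = report@method,
       resolution = report@resolution, roles = report@roles,
       table = report@table)
})

setMethod(".reportTable", "FrequencyComparison", function(report) {
  report@table
})

setMethod(".reportList", "FrequencyComparison", function(report) {
  list(statistic = "frequency_comparison", k = report@k,
       references = report@references,
       absent_from_all = report@absentFromAll, table = report@table)
})

#' Write an evaluation report to disk
#'
#' Serialises any report object ([DAReport-class], [MAReport-class],
#' [HRReport-class], [AlleleFrequencyTable-class],
#' [FrequencyComparison-class]) as tab-separated text (per-locus rows plus
#' an overall row, deterministic column order, missing values as a literal
#' \code{NA}) or as JSON (the full report with all numerators and
#' denominators, missing values as \code{null}).
#'
#' @param report a report object.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return invisibly, \code{path}.
#' @export
writeReport <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(.reportTable(report), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(.reportList(report), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", null = "null",
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
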