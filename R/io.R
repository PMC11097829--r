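#' Read a variant-weights table
#'
#' Reads a delimited text file with columns `variant_id`, `effect_allele`
#' and `weight` (per-allele association with the exposure, external units),
#' the format of published GWAS score weights.
#'
#' @param path file path.
#' @param delim field delimiter (default tab).
#' @return A validated `data.frame`.
#' @export
read_weights <- function(path, delim = "\t") {
  w <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "weight")
  missing <- setdiff(need, names(w))
  if (length(missing))
    stop_ctx("weights file missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(w$variant_id))
    stop_ctx("duplicate variant_id in ", path)
  if (any(!is.finite(w$weight)))
    stop_ctx("non-finite weight in ", path)
  if (all(w$weight == 0))
    stop_ctx("all weights zero in ", path)
  w
}

#' Read and write cohort tables
#'
#' `read_cohort()` reads a delimited text file into a validated cohort
#' `data.frame`. Columns may be renamed to the canonical schema through
#' `mapping`, a named list (or path to a YAML file holding one) of
#' `canonical = file_column` pairs. Mandatory canonical columns are
#' `exposure`, `entry_age`, `exit_age`, `event`, and either `score` or at
#' least one genotype column. Rows with missing mandatory fields or
#' `exit_age <= entry_age` are dropped with a message; the count is kept in
#' attribute `"n_excluded"`, mirroring the usual exclusion of participants
#' without exposure or variant data.
#'
#' @param path file path.
#' @param mapping named list or YAML file path mapping canonical names to
#'   file column names; `NULL` if the file already uses canonical names.
#' @param delim field delimiter (default tab).
#' @return A cohort `data.frame`.
#' @export
read_cohort <- function(path, mapping = NULL, delim = "\t") {
  d <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE)
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- yaml::read_yaml(mapping)
  if (!is.null(mapping)) {
    for (canonical in names(mapping)) {
      src <- mapping[[canonical]]
      if (!src %in% names(d))
        stop_ctx("mapped column `", src, "` not found in ", path)
      names(d)[names(d) == src] <- canonical
    }
  }
  mandatory <- c("exposure", "entry_age", "exit_age", "event")
  missing <- setdiff(mandatory, names(d))
  if (length(missing))
    stop_ctx("cohort file missing mandatory columns: ",
             paste(missing, collapse = ", "))
  has_geno <- any(grepl("^g[0-9]+$", names(d))) || "score" %in% names(d)
  if (!has_geno)
    stop_ctx("cohort file must carry a `score` column or genotype columns")
  n0 <- nrow(d)
  ok <- stats::complete.cases(d[mandatory]) &
    d$exit_age > d$entry_age & d$event %in% c(0, 1)
  if ("score" %in% names(d)) ok <- ok & is.finite(d$score)
  d <- d[ok, , drop = FALSE]
  n_excluded <- n0 - nrow(d)
  if (n_excluded > 0)
    message("excluded ", n_excluded, " rows failing validation")
  if (!"id" %in% names(d)) d$id <- seq_len(nrow(d))
  attr(d, "n_excluded") <- n_excluded
  d
}

#' @rdname read_cohort
#' @param cohort a cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path, delim = "\t") {
  utils::write.table(cohort, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a stratification and its provenance
#'
#' Writes the per-individual assignment as TSV (`id`, `method`, `stratum`,
#' `trimmed`) and a JSON sidecar (`<path>.json`) with the stratum count,
#' seed, and per-stratum means and sizes, so a run can be audited and
#' reproduced.
#'
#' @param assignment a [stratify()] result.
#' @param path output TSV path.
#' @return Invisibly, the TSV path.
#' @export
write_strata <- function(assignment, path) {
  stopifnot(inherits(assignment, "strata_assignment"))
  ids <- c(names(assignment$stratum_of), assignment$trimmed_ids)
  tab <- data.frame(
    id = ids,
    method = assignment$method,
    stratum = c(unname(assignment$stratum_of),
                rep(NA_integer_, length(assignment$trimmed_ids))),
    trimmed = c(rep(0L, length(assignment$stratum_of)),
                rep(1L, length(assignment$trimmed_ids)))
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(method = assignment$method, q = assignment$q,
               seed = assignment$seed,
               stratum_sizes = as.vector(assignment$stratum_sizes),
               stratum_means = as.vector(assignment$stratum_means),
               n_trimmed = length(assignment$trimmed_ids))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
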