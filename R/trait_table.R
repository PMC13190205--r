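#' Validate a raw trait record table
#'
#' A trait table holds one row per plant with identifier columns
#' `plant_id`, `zone_id`, `acre_id`, one numeric column per trait code and
#' an optional `condition` label.
#'
#' @param records data frame of raw trait records.
#' @param traits trait registry (see [pgk_traits()]).
#' @param require_condition require the `condition` column.
#' @return `records`, invisibly, after validation.
#' @export
validate_trait_records <- function(records, traits = pgk_traits(),
                                   require_condition = FALSE) {
  validate_traits(traits)
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data frame of trait records")
  id_cols <- c("plant_id", "zone_id", "acre_id")
  miss <- setdiff(id_cols, names(records))
  if (length(miss))
    stop("trait table is missing identifier column(s): ",
         paste(miss, collapse = ", "))
  codes <- traits$code
  miss <- setdiff(codes, names(records))
  if (length(miss))
    stop("trait table is missing trait column(s): ",
         paste(miss, collapse = ", "))
  for (code in codes) {
    x <- records[[code]]
    if (!is.numeric(x))
      stop("trait column '", code, "' must be numeric")
    bad <- which(!is.finite(x))
    if (length(bad))
      stop("trait '", code, "' has a non-finite value for plant '",
           records$plant_id[bad[1L]], "'")
  }
  if (require_condition && !("condition" %in% names(records)))
    stop("trait table is missing the 'condition' column")
  invisible(records)
}

#' Read a trait table from delimited text
#'
#' Reads a CSV trait table (header required) with columns `plant_id`,
#' `zone_id`, `acre_id`, the six canonical trait columns and an optional
#' `condition` column.
#'
#' @param path path to a CSV file.
#' @param traits trait registry the table must cover.
#' @return Validated data frame of raw trait records.
#' @export
read_trait_table <- function(path, traits = pgk_traits()) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("plant_id", "zone_id", "acre_id"), names(records)))
    records[[col]] <- as.character(records[[col]])
  validate_trait_records(records, traits)
  records
}

#' Write a trait table as CSV
#'
#' @param records validated trait record data frame.
#' @param path destination file.
#' @param traits trait registry.
#' @export
write_trait_table <- function(records, path, traits = pgk_traits()) {
  validate_trait_records(records, traits)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

trait_matrix <- function(records, traits = pgk_traits()) {
  x <- as.matrix(records[, traits$code, drop = FALSE])
  rownames(x) <- records$plant_id
  x
}
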