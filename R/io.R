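#' Read / write NONMEM-style rectangular datasets
#'
#' The on-disk form is a comma-separated file with header row and columns
#' `ID`, `TIME`, `AMT`, `RATE`, `DUR`, `EVID`, `MDV`, `DV`, `BLQ` plus any
#' covariate columns; missing `DV` is written as `.`. A JSON sidecar
#' (`<path>.provenance.json`) stores the generator provenance (seed, true
#' parameters) when present, and is restored on read, so write-then-read is
#' the identity on records.
#'
#' @param path CSV file path.
#' @return `read_dataset()` returns a `pk_dataset` tibble;
#'   `write_dataset()` returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = ".")
  if (nrow(df) == 0L) {
    warning("empty dataset: ", path)
    out <- tibble::as_tibble(df)
    class(out) <- c("pk_dataset", class(out))
    return(out)
  }
  need <- c("ID", "TIME", "AMT", "RATE", "DUR", "EVID", "MDV", "DV", "BLQ")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("dataset is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$MDV == 1L & df$EVID == 0L & !is.na(df$DV))
  if (length(bad)) {
    stop("row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": DV present but MDV = 1", call. = FALSE)
  }
  bad <- which(df$EVID == 0L & df$MDV == 0L & is.na(df$DV))
  if (length(bad)) {
    stop("row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": observation row without DV", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  side <- paste0(path, ".provenance.json")
  if (file.exists(side)) {
    attr(out, "provenance") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  class(out) <- c("pk_dataset", class(out))
  out
}

#' @rdname read_dataset
#' @param d A `pk_dataset` (any data frame with the mandatory columns).
#' @export
write_dataset <- function(d, path) {
  df <- as.data.frame(d)
  utils::write.csv(df, path, row.names = FALSE, na = ".", quote = FALSE)
  prov <- attr(d, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
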