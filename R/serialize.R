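#' Write a survival distribution to JSON
#'
#' Serializes the grid and per-subject survival curves as
#' `{"grid": [...], "S": [[...], ...]}`.
#'
#' @param dist a [surv_distribution].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distribution_json <- function(dist, path) {
  stopifnot(inherits(dist, "surv_distribution"))
  jsonlite::write_json(list(grid = dist$grid, S = dist$S), path,
                       digits = NA)
  invisible(path)
}

#' Read a survival distribution from JSON
#' @param path JSON path written by [write_distribution_json()].
#' @return A [surv_distribution].
#' @export
read_distribution_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  surv_distribution(obj$grid, as.matrix(obj$S))
}
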