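#' Read measurement tables in the package's tidy CSV dialects
#'
#' Three input dialects are supported, with column-name mapping for files
#' whose headers differ:
#' \itemize{
#'   \item retraction curves: \code{curve_id}, \code{t_s} or \code{t_min},
#'     \code{length_um} (seconds are converted to minutes at ingest);
#'   \item recoil records: \code{cell_id}, \code{genotype},
#'     \code{length_before_um}, \code{length_after_um};
#'   \item trajectories: \code{embryo_id}, \code{time_min},
#'     \code{length_um}.
#' }
#'
#' @param path CSV file path.
#' @param col_map optional named character vector mapping standard names to
#'   the file's actual column names, e.g.
#'   \code{c(length_before_um = "L_pre")}.
#' @return A tibble with standard column names; recoil records gain
#'   derived \code{recoil_um} and \code{ratio} columns.
#' @export
read_retraction_curves <- function(path, col_map = NULL) {
  d <- apply_col_map(readr::read_csv(path, show_col_types = FALSE), col_map)
  if (!"t_min" %in% names(d)) {
    if (!"t_s" %in% names(d))
      stop("retraction curves need a t_min or t_s column",
           missing_cols_hint(d))
    d$t_min <- d$t_s / 60
    d$t_s <- NULL
  }
  need <- c("curve_id", "t_min", "length_um")
  if (!all(need %in% names(d)))
    stop("retraction curves need columns ", paste(need, collapse = ", "),
         missing_cols_hint(d))
  d[c("curve_id", "t_min", "length_um")]
}

#' @rdname read_retraction_curves
#' @export
read_recoil_records <- function(path, col_map = NULL) {
  d <- apply_col_map(readr::read_csv(path, show_col_types = FALSE), col_map)
  need <- c("cell_id", "length_before_um", "length_after_um")
  if (!all(need %in% names(d)))
    stop("recoil records need columns ", paste(need, collapse = ", "),
         missing_cols_hint(d))
  if (!"genotype" %in% names(d)) d$genotype <- NA_character_
  d$recoil_um <- d$length_before_um - d$length_after_um
  d$ratio <- d$recoil_um / d$length_before_um
  d
}

#' @rdname read_retraction_curves
#' @export
read_trajectories <- function(path, col_map = NULL) {
  d <- apply_col_map(readr::read_csv(path, show_col_types = FALSE), col_map)
  need <- c("time_min", "length_um")
  if (!all(need %in% names(d)))
    stop("trajectories need columns ", paste(need, collapse = ", "),
         missing_cols_hint(d))
  if (!"embryo_id" %in% names(d)) d$embryo_id <- "embryo_1"
  d
}

apply_col_map <- function(d, col_map) {
  if (is.null(col_map)) return(d)
  for (std in names(col_map)) {
    actual <- col_map[[std]]
    if (!actual %in% names(d))
      stop("col_map: column '", actual, "' not found in file")
    names(d)[names(d) == actual] <- std
  }
  d
}

missing_cols_hint <- function(d) {
  paste0("; found: ", paste(names(d), collapse = ", "),
         ". Use col_map = c(standard_name = \"actual_name\") to map headers.")
}
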