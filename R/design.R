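#' Define a two-stage study design
#'
#' A design is the four cohort sizes of a two-stage case-control study:
#' discovery controls and cases (`n0`, `n1`) and replication controls and
#' cases (`n0p`, `n1p`). Counts are individuals; all allele-level
#' computations in the package use `2n` allele draws per cohort
#' (diploid, Hardy-Weinberg).
#'
#' @param n0,n1 Numbers of discovery controls and cases.
#' @param n0p,n1p Numbers of replication controls and cases.
#' @return A one-row tibble of class `repool_design` with columns
#'   `n0`, `n1`, `n0p`, `n1p`.
#' @examples
#' study_design(20169, 5539, 8806, 6768)
#' @export
study_design <- function(n0, n1, n0p, n1p) {
  d <- tibble::tibble(n0 = n0, n1 = n1, n0p = n0p, n1p = n1p)
  validate_design(d)
  class(d) <- c("repool_design", class(d))
  d
}

#' @keywords internal
validate_design <- function(design) {
  req <- c("n0", "n1", "n0p", "n1p")
  missing <- setdiff(req, names(design))
  if (length(missing) > 0) {
    stop("design is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in req) {
    x <- design[[col]]
    if (any(!is.finite(x)) || any(x < 1) || any(x != round(x))) {
      stop("design column '", col, "' must contain integers >= 1",
           call. = FALSE)
    }
  }
  invisible(design)
}

## Coerce a one-row design data frame (or a named vector/list) to a list of
## four scalar counts used by the scalar core.
#' @keywords internal
as_design <- function(design) {
  if (is.data.frame(design)) {
    validate_design(design)
    if (nrow(design) != 1) {
      stop("expected a single design (one row); got ", nrow(design),
           call. = FALSE)
    }
    lapply(as.list(design[1, c("n0", "n1", "n0p", "n1p")]), as.numeric)
  } else if (is.numeric(design) && length(design) == 4) {
    d <- as.list(design)
    names(d) <- c("n0", "n1", "n0p", "n1p")
    validate_design(tibble::as_tibble(d))
    d
  } else {
    stop("design must be a one-row data frame or a numeric vector of length 4",
         call. = FALSE)
  }
}

#' Read a table of study designs
#'
#' Reads a delimited file with header columns `n0,n1,n0p,n1p` (one design
#' per row). Blank lines and lines starting with `#` are skipped. Every
#' entry is validated as a positive integer; offending rows are reported
#' by row and column.
#'
#' @param path Path to a comma- or tab-delimited file.
#' @return A tibble of designs (class `repool_design`).
#' @export
read_design_table <- function(path) {
  d <- readr::read_delim(path,
    delim = NULL, comment = "#", trim_ws = TRUE,
    show_col_types = FALSE, progress = FALSE
  )
  req <- c("n0", "n1", "n0p", "n1p")
  missing <- setdiff(req, names(d))
  if (length(missing) > 0) {
    stop("design table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- d[, req]
  for (col in req) {
    x <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.finite(x) | x < 1 | x != round(x))
    if (length(bad) > 0) {
      stop("design table row ", bad[1], ", column '", col,
           "': value must be an integer >= 1", call. = FALSE)
    }
    d[[col]] <- x
  }
  class(d) <- c("repool_design", class(d))
  d
}
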