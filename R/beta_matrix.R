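#' Construct a beta-value matrix
#'
#' A `beta_matrix` is a numeric probes-by-samples matrix of methylation beta
#' values (methylated fraction, unitless, in \[0,1\]) with unique probe row
#' names and unique sample column names. Missing values are `NA`;
#' out-of-range values are rejected on construction, never clamped, because
#' silent clamping hides upstream corruption.
#'
#' @param values numeric matrix (probes in rows, samples in columns).
#' @param probe_ids,sample_ids character vectors of identifiers; default to
#'   the dimnames of `values`.
#' @return an object of class `beta_matrix` (a numeric matrix with dimnames).
#' @export
#' @examples
#' m <- matrix(0.5, 3, 2,
#'   dimnames = list(c("cg01", "cg02", "cg03"), c("S1", "S2")))
#' beta_matrix(m)
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("`values` must have probe and sample identifiers", call. = FALSE)
  }
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix shape", call. = FALSE)
  }
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe ids: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(values) <- list(as.character(probe_ids), as.character(sample_ids))
  check_beta_range(values)
  structure(values, class = c("beta_matrix", "matrix", "array"))
}

# error names the first offending probe/sample/value
check_beta_range <- function(values) {
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "beta value out of [0,1]: probe '%s', sample '%s', value %g (%d offending cell%s)",
      rownames(values)[i], colnames(values)[j], values[i, j],
      nrow(bad), if (nrow(bad) == 1) "" else "s"), call. = FALSE)
  }
  invisible(values)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples, %d missing\n",
              nrow(x), ncol(x), sum(is.na(x))))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE],
                    4), ...)
  invisible(x)
}

#' @export
#' @method as_tibble beta_matrix
#' @importFrom tibble as_tibble
as_tibble.beta_matrix <- function(x, ...) {
  tibble::tibble(
    probe_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    beta = as.vector(unclass(x))
  )
}

#' Read / write a beta-value matrix as TSV
#'
#' The on-disk format is tab-separated, UTF-8: first column `probe_id`,
#' remaining columns one per sample (header row holds sample ids), cells
#' numeric or the missing token.
#'
#' @param path file path.
#' @param missing token representing a missing value (default `"NA"`).
#' @return [read_beta_matrix()] returns a [beta_matrix];
#'   [write_beta_matrix()] returns `path` invisibly.
#' @export
read_beta_matrix <- function(path, missing = "NA") {
  stopifnot(file.exists(path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("no sample columns in ", path, call. = FALSE)
  if (anyDuplicated(header[-1])) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(header[-1][duplicated(header[-1])]), collapse = ", "),
         call. = FALSE)
  }
  df <- readr::read_tsv(path, na = missing, show_col_types = FALSE,
                        progress = FALSE,
                        col_types = paste0("c", strrep("d", length(header) - 1L)))
  probe_ids <- df[[1]]
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- probe_ids
  beta_matrix(values, probe_ids, colnames(df)[-1])
}

#' @param x a [beta_matrix].
#' @rdname read_beta_matrix
#' @export
write_beta_matrix <- function(x, path, missing = "NA") {
  stopifnot(inherits(x, "beta_matrix"))
  df <- tibble::as_tibble(as.data.frame(unclass(x)), rownames = "probe_id")
  readr::write_tsv(df, path, na = missing, progress = FALSE)
  invisible(path)
}
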