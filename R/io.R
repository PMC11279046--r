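#' Assemble per-sample methylation files into one beta matrix
#'
#' Portal-style downloads ship one two-column text file per sample
#' (`probe_id<TAB>beta`). This reads every file named in `manifest`,
#' restricts probes to the intersection present in *all* files (complete
#' per-marker pairing downstream requires every sample to carry every
#' probe), sorts probes canonically by id, and records the sample type of
#' each column.
#'
#' @param dir directory containing the files.
#' @param manifest data frame with columns `file`, `sample_id`,
#'   `sample_type` (`"tumor"` or `"normal"`) and optionally `patient_id`.
#' @return a [beta_matrix] with attribute `sample_meta`, a tibble with one
#'   row per column of the matrix (retrieve it with [sample_meta()]).
#' @export
read_tcga_sample_files <- function(dir, manifest) {
  manifest <- tibble::as_tibble(manifest)
  stopifnot(all(c("file", "sample_id", "sample_type") %in% names(manifest)))
  if (anyDuplicated(manifest$sample_id)) {
    stop("duplicate sample ids in manifest", call. = FALSE)
  }
  bad_type <- setdiff(unique(manifest$sample_type), c("tumor", "normal"))
  if (length(bad_type)) {
    stop("unknown sample_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  per_sample <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- file.path(dir, manifest$file[i])
    df <- readr::read_tsv(path, col_names = c("probe_id", "beta"),
                          col_types = "cd", progress = FALSE)
    dup <- df$probe_id[duplicated(df$probe_id)]
    if (length(dup)) {
      conflicting <- vapply(unique(dup), function(p) {
        length(unique(df$beta[df$probe_id == p])) > 1L
      }, logical(1))
      if (any(conflicting)) {
        stop(sprintf("conflicting duplicate probe rows in '%s': %s",
                     manifest$file[i],
                     paste(unique(dup)[conflicting], collapse = ", ")),
             call. = FALSE)
      }
      df <- df[!duplicated(df$probe_id), ]
    }
    df
  })
  common <- Reduce(intersect, lapply(per_sample, `[[`, "probe_id"))
  if (length(common) == 0) {
    stop("no probes shared by all sample files", call. = FALSE)
  }
  common <- sort(common)
  values <- vapply(per_sample, function(df) {
    df$beta[match(common, df$probe_id)]
  }, numeric(length(common)))
  values <- matrix(values, nrow = length(common),
                   dimnames = list(common, manifest$sample_id))
  out <- beta_matrix(values)
  attr(out, "sample_meta") <-
    manifest[, intersect(c("sample_id", "sample_type", "patient_id"),
                         names(manifest))]
  out
}

#' @param x a [beta_matrix] produced by [read_tcga_sample_files()].
#' @rdname read_tcga_sample_files
#' @export
sample_meta <- function(x) attr(x, "sample_meta")

#' Write a beta matrix as per-sample two-column files
#'
#' Inverse of [read_tcga_sample_files()]; mainly used for round-trip
#' testing and for emitting synthetic cohorts in the portal layout.
#'
#' @param x a [beta_matrix].
#' @param meta data frame with `sample_id`, `sample_type` and optionally
#'   `patient_id`, one row per column of `x`.
#' @param dir output directory (created if needed).
#' @return the manifest tibble (with a `file` column), invisibly.
#' @export
write_sample_files <- function(x, meta, dir) {
  stopifnot(inherits(x, "beta_matrix"))
  meta <- tibble::as_tibble(meta)
  stopifnot(setequal(meta$sample_id, colnames(x)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta$file <- paste0(meta$sample_id, ".methylation.txt")
  for (i in seq_len(nrow(meta))) {
    df <- tibble::tibble(probe_id = rownames(x),
                         beta = unclass(x)[, meta$sample_id[i]])
    readr::write_tsv(df, file.path(dir, meta$file[i]), col_names = FALSE,
                     progress = FALSE)
  }
  invisible(meta)
}

#' Build a matched tumor/normal pair set
#'
#' Retains patients with exactly one tumor and one normal sample; patients
#' with only one tissue are dropped (count reported), while patients with
#' two samples of the same tissue are an error because the pairing would be
#' ambiguous. Probes and patients are ordered canonically (sorted by id),
#' so the result is independent of input sample order and downstream
#' results are order-stable.
#'
#' @param x a [beta_matrix] covering both tissues.
#' @param meta data frame with columns `sample_id`, `patient_id`,
#'   `sample_type`; must cover every column of `x`. Defaults to
#'   [sample_meta()] of `x`.
#' @return a `matched_pair_set`: list with `patient_ids`, `probe_ids`,
#'   `normal` and `tumor` (probes-by-patients matrices, columns named by
#'   patient), and `pairing` (tibble patient -> normal/tumor sample id).
#' @export
build_matched_pairs <- function(x, meta = sample_meta(x)) {
  stopifnot(inherits(x, "beta_matrix"))
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("sample_id", "patient_id", "sample_type") %in% names(meta)))
  missing_cov <- setdiff(colnames(x), meta$sample_id)
  if (length(missing_cov)) {
    stop("samples absent from metadata: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  meta <- meta[meta$sample_id %in% colnames(x), ]
  counts <- table(factor(meta$patient_id),
                  factor(meta$sample_type, levels = c("normal", "tumor")))
  multi <- rownames(counts)[counts[, "tumor", drop = TRUE] > 1 |
                              counts[, "normal", drop = TRUE] > 1]
  if (length(multi)) {
    stop("ambiguous pairing (multiple samples of one tissue) for patient: ",
         paste(multi, collapse = ", "), call. = FALSE)
  }
  complete <- rownames(counts)[counts[, "tumor"] == 1 & counts[, "normal"] == 1]
  dropped <- setdiff(unique(meta$patient_id), complete)
  patients <- sort(complete)
  if (length(patients) < 2) {
    stop("fewer than 2 complete tumor/normal pairs", call. = FALSE)
  }
  if (length(dropped)) {
    message(length(dropped), " patient(s) without a complete pair dropped")
  }
  message(length(patients), " matched pair(s) retained")
  probe_ids <- sort(rownames(x))
  pick <- function(type) {
    ids <- vapply(patients, function(p) {
      meta$sample_id[meta$patient_id == p & meta$sample_type == type]
    }, character(1))
    m <- unclass(x)[probe_ids, ids, drop = FALSE]
    colnames(m) <- patients
    m
  }
  structure(list(
    patient_ids = patients,
    probe_ids = probe_ids,
    normal = pick("normal"),
    tumor = pick("tumor"),
    pairing = tibble::tibble(
      patient_id = patients,
      normal_sample = vapply(patients, function(p)
        meta$sample_id[meta$patient_id == p & meta$sample_type == "normal"],
        character(1)),
      tumor_sample = vapply(patients, function(p)
        meta$sample_id[meta$patient_id == p & meta$sample_type == "tumor"],
        character(1)))
  ), class = "matched_pair_set")
}

#' @export
print.matched_pair_set <- function(x, ...) {
  cat(sprintf("<matched_pair_set> %d patients, %d probes\n",
              length(x$patient_ids), length(x$probe_ids)))
  invisible(x)
}

#' Read a clinical survival table
#'
#' Expects tab-separated columns `patient_id`, `vital_status`
#' (`Dead`/`Alive`, case-insensitive), `days_to_death`,
#' `days_to_last_follow_up`. Deceased patients contribute
#' `time = days_to_death` with `event = 1`; surviving patients contribute
#' `time = days_to_last_follow_up` with `event = 0`. Rows with neither time
#' are dropped with a warning; non-positive times are an error.
#'
#' @param path TSV file path.
#' @return tibble with columns `patient_id`, `event` (0/1), `time` (days),
#'   plus any extra columns carried through unmodelled.
#' @export
read_clinical <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("patient_id", "vital_status", "days_to_death",
           "days_to_last_follow_up")
  stopifnot(all(req %in% names(df)))
  dead <- tolower(df$vital_status) %in% c("dead", "deceased")
  time <- ifelse(dead, df$days_to_death, df$days_to_last_follow_up)
  # deceased rows lacking days_to_death fall back to follow-up? no: dropped
  keep <- !is.na(time)
  if (any(!keep)) {
    warning(sum(!keep), " patient(s) dropped: no usable survival time",
            call. = FALSE)
  }
  out <- tibble::tibble(
    patient_id = df$patient_id[keep],
    event = as.integer(dead[keep]),
    time = as.numeric(time[keep])
  )
  extra <- setdiff(names(df), req)
  if (length(extra)) out <- dplyr::bind_cols(out, df[keep, extra])
  validate_clinical(out)
}

validate_clinical <- function(clinical) {
  clinical <- tibble::as_tibble(clinical)
  stopifnot(all(c("patient_id", "event", "time") %in% names(clinical)))
  if (anyDuplicated(clinical$patient_id)) {
    stop("duplicate patient ids in clinical table", call. = FALSE)
  }
  if (!all(clinical$event %in% c(0, 1))) {
    stop("event indicator must be 0/1", call. = FALSE)
  }
  bad <- clinical$patient_id[clinical$time <= 0 | is.na(clinical$time)]
  if (length(bad)) {
    stop("non-positive survival time for patient: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  clinical
}

#' @param clinical a clinical tibble as returned by [read_clinical()].
#' @rdname read_clinical
#' @export
write_clinical <- function(clinical, path) {
  clinical <- validate_clinical(clinical)
  df <- tibble::tibble(
    patient_id = clinical$patient_id,
    vital_status = ifelse(clinical$event == 1, "Dead", "Alive"),
    days_to_death = ifelse(clinical$event == 1, clinical$time, NA_real_),
    days_to_last_follow_up = ifelse(clinical$event == 0, clinical$time,
                                    NA_real_)
  )
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write a probe annotation table
#'
#' Four tab-separated columns: `probe_id`, `gene` (zero or more symbols,
#' `;`-separated, empty or `NA` for unannotated probes), `chromosome`,
#' `position` (1-based). Probe ids must be unique.
#'
#' @param path TSV file path.
#' @return tibble with one row per probe: `probe_id`, `gene` (`;`-joined or
#'   `NA`), `chromosome`, `position`.
#' @export
read_probe_annotation <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = "ccci")
  stopifnot(all(c("probe_id", "gene", "chromosome", "position") %in% names(df)))
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe ids in annotation", call. = FALSE)
  }
  if (any(!is.na(df$position) & df$position < 1)) {
    stop("annotation positions must be >= 1", call. = FALSE)
  }
  df$gene[!is.na(df$gene) & df$gene == ""] <- NA_character_
  tibble::as_tibble(df)
}

#' @param annotation an annotation tibble.
#' @rdname read_probe_annotation
#' @export
write_probe_annotation <- function(annotation, path) {
  readr::write_tsv(annotation[, c("probe_id", "gene", "chromosome",
                                  "position")],
                   path, na = "NA", progress = FALSE)
  invisible(path)
}

# long probe -> gene table (one row per probe-gene link, unannotated dropped)
expand_annotation_genes <- function(annotation) {
  ann <- annotation[!is.na(annotation$gene) & annotation$gene != "", ]
  tidyr::separate_rows(ann[, c("probe_id", "gene")], "gene", sep = ";") |>
    dplyr::filter(.data$gene != "") |>
    dplyr::distinct()
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-separated: `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Lines with no member genes are skipped with a warning; duplicate term ids
#' are an error.
#'
#' @param path GMT file path.
#' @return tibble with columns `term_id`, `term_name`, and `genes`
#'   (list-column of character vectors).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  empty <- vapply(parts, function(p) {
    genes <- unique(p[-(1:2)][nzchar(p[-(1:2)])])
    length(p) < 3 || length(genes) == 0
  }, logical(1))
  if (any(empty)) {
    warning(sum(empty), " gene set(s) with no members skipped",
            call. = FALSE)
    parts <- parts[!empty]
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate term ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    term_id = ids,
    term_name = vapply(parts, `[[`, character(1), 2L),
    genes = lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  )
}

#' @param sets a gene-set tibble as returned by [read_gene_sets()].
#' @rdname read_gene_sets
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$term_id[i], sets$term_name[i], sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
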