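#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (tab-separated: name, description, members).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 member): ", l)
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "", USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (recycled).
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV count matrix (gene id in the first column)
#'
#' @param path Path to a TSV file.
#' @return Integer matrix, genes x samples.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  validate_counts(m)
  m
}

validate_counts <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            all(counts == floor(counts)),
            !anyDuplicated(rownames(counts)), !anyDuplicated(colnames(counts)))
  invisible(counts)
}

#' Read a sample metadata TSV
#'
#' @param path Path to a TSV file with a `sample_id` column.
#' @return data.frame.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(df))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

matrix_to_df <- function(m, id_col = "gene") {
  cbind(stats::setNames(data.frame(rownames(m), stringsAsFactors = FALSE),
                        id_col),
        as.data.frame(m, check.names = FALSE))
}

#' Write a synthetic cohort to disk as plain-text files
#'
#' Writes counts (TSV, gene id first column), metadata (TSV), marker and
#' pathway gene sets (GMT), the truth table (TSV), and a `manifest.tsv`
#' listing every file with its MD5 checksum.
#'
#' @param cohort A `synthetic_cohort` from [generate_counts()].
#' @param directory Output directory (created if missing).
#' @param overwrite Overwrite existing files? Default `FALSE` (refuses).
#' @return data.frame manifest (file, md5), invisibly written as
#'   `manifest.tsv`.
#' @export
write_fixture <- function(cohort, directory, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- c(counts = "counts.tsv", metadata = "metadata.tsv",
             markers = "markers.gmt", pathways = "pathways.gmt",
             truth = "truth.tsv")
  paths <- stats::setNames(file.path(directory, files), names(files))
  existing <- paths[file.exists(paths)]
  if (length(existing) && !overwrite)
    stop("refusing to overwrite existing files: ",
         paste(basename(existing), collapse = ", "))
  write_tsv(matrix_to_df(cohort$counts), paths[["counts"]])
  write_tsv(cohort$metadata, paths[["metadata"]])
  write_gmt(cohort$marker_sets, paths[["markers"]])
  write_gmt(cohort$pathway_sets, paths[["pathways"]])
  write_tsv(cohort$truth, paths[["truth"]])
  manifest <- data.frame(file = unname(files),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(directory, "manifest.tsv"))
  manifest
}
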