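# Plain-text readers/writers for the pipeline's exchange formats: beta and
# detection-p matrices as TSV with probe rownames, manifest and sample
# sheet as CSV, gene sets as GMT, ground truth as JSON.

#' Read a beta-value (or detection p-value) matrix from TSV
#'
#' @param path TSV with probe ids in the first column and sample ids as
#'   header.
#' @return Numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' @rdname read_beta_matrix
#' @export
read_detection_p <- read_beta_matrix

#' Read the probe manifest (CSV)
#' @param path CSV with at least probe_id, chromosome, position.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read the sample sheet (CSV)
#' @param path CSV with at least sample_id.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a full methylation dataset from its component files
#'
#' @param beta_file,manifest_file,samples_file,detection_p_file Paths;
#'   `detection_p_file` optional.
#' @return A [methylation_dataset()].
#' @export
read_methylation_dataset <- function(beta_file, manifest_file,
                                     samples_file,
                                     detection_p_file = NULL) {
  methylation_dataset(
    beta = read_beta_matrix(beta_file),
    manifest = read_manifest(manifest_file),
    samples = read_sample_sheet(samples_file),
    detection_p = if (!is.null(detection_p_file)) {
      read_detection_p(detection_p_file)
    })
}

#' Write a methylation dataset (and optional extras) to a directory
#'
#' Emits `beta.tsv`, `manifest.csv`, `samples.csv`, plus
#' `detection_p.tsv`, `reference.tsv` and `ground_truth.json` when
#' available — the same formats the readers consume.
#'
#' @param ds A [methylation_dataset()].
#' @param dir Output directory (created if needed).
#' @param reference Optional reference methylome matrix.
#' @param truth Optional `ground_truth` object.
#' @return Invisibly, the directory path.
#' @export
write_methylation_dataset <- function(ds, dir, reference = NULL,
                                      truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) {
    utils::write.table(data.frame(probe_id = rownames(m), m,
                                  check.names = FALSE),
                       file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wm(ds$beta, "beta.tsv")
  utils::write.csv(ds$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  if (!is.null(ds$detection_p)) wm(ds$detection_p, "detection_p.tsv")
  if (!is.null(reference)) wm(reference, "reference.tsv")
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(dir)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return Named list of gene-symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1)
  sets
}

#' Read a gene-disease association table (CSV: gene, disease, score)
#' @param path CSV file.
#' @return Data frame.
#' @export
read_disease_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
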