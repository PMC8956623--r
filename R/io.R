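# Reading and writing connectivity matrices, cohort manifests and reports.
# All formats are plain delimited text: imaging front ends are out of scope.

.detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read a connectivity matrix from delimited text
#'
#' Reads a square numeric matrix (CSV, TSV or whitespace-separated), with or
#' without a header row and/or a leading label column, and validates it as a
#' [weighted_network()]. Asymmetry within `tol` (numerical noise from
#' tractography pipelines that average both triangles separately) is repaired
#' by averaging; anything larger is an error.
#'
#' @param path Path to the matrix file.
#' @param labels Optional character vector of region labels overriding any
#'   header; length must match the matrix dimension.
#' @param tol Symmetry tolerance passed to [weighted_network()].
#' @return A [weighted_network()].
#' @export
read_network <- function(path, labels = NULL, tol = 1e-8) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  first <- strsplit(readLines(path, n = 1L),
                    if (sep == "") "[[:space:]]+" else sep)[[1]]
  first <- first[nzchar(first)]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  raw <- read.table(path, header = has_header, sep = sep,
                    check.names = FALSE, stringsAsFactors = FALSE)
  # leading label column?
  if (ncol(raw) > 0 && (is.character(raw[[1]]) || is.factor(raw[[1]]))) {
    rn <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
    if (is.null(labels) && !has_header) labels <- rn
  }
  if (!all(vapply(raw, is.numeric, logical(1))))
    stop("matrix file contains non-numeric entries: ", path, call. = FALSE)
  w <- as.matrix(raw)
  if (nrow(w) != ncol(w))
    stop("matrix in ", path, " is not square (", nrow(w), " x ", ncol(w), ")",
         call. = FALSE)
  if (is.null(labels) && has_header) labels <- colnames(raw)
  if (!is.null(labels) && length(labels) != nrow(w))
    stop("label count (", length(labels), ") does not match matrix dimension (",
         nrow(w), ") in ", path, call. = FALSE)
  dimnames(w) <- NULL
  weighted_network(w, labels = labels, tol = tol)
}

#' Write a connectivity matrix as CSV
#'
#' Inverse of [read_network()]: writes the weight matrix with region labels as
#' the header row. Round-tripping reproduces weights to full double precision.
#'
#' @param net A [weighted_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  df <- as.data.frame(net$weights)
  names(df) <- net$labels
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from a manifest and a directory of matrices
#'
#' The manifest is a CSV with columns `subject_id`, `group`, `age`, `sex`,
#' `matrix_file`, plus optional clinical columns (e.g. `edss`,
#' `disease_duration`). Matrix paths are resolved relative to `matrix_dir`.
#' All matrices are cross-validated for a shared node count and label order;
#' missing clinical values are preserved as `NA`.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param matrix_dir Directory containing the per-subject matrix files
#'   (default: the manifest's directory).
#' @param control Control group label (default `"HC"`).
#' @param labels Optional region labels applied to every matrix.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(manifest_path, matrix_dir = dirname(manifest_path),
                        control = "HC", labels = NULL) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "age", "sex", "matrix_file")
  missing_cols <- setdiff(req, names(man))
  if (length(missing_cols))
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  networks <- vector("list", nrow(man))
  for (k in seq_len(nrow(man))) {
    f <- file.path(matrix_dir, man$matrix_file[k])
    if (!file.exists(f))
      stop("matrix file for subject '", man$subject_id[k], "' not found: ", f,
           call. = FALSE)
    networks[[k]] <- read_network(f, labels = labels)
  }
  clinical <- setdiff(names(man), req)
  cohort_dataset(man[, c(setdiff(req, "matrix_file"), clinical)], networks,
                 control = control, clinical = clinical)
}

#' Write a cohort as manifest + matrix directory
#'
#' Emits `manifest.csv` and one `<subject_id>.csv` matrix per subject under
#' `dir`, in the layout [read_cohort()] consumes.
#'
#' @param cohort A [cohort_dataset()].
#' @param dir Output directory (created if absent).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "connstat_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$subjects
  man$group <- as.character(man$group)
  man$matrix_file <- paste0(man$subject_id, ".csv")
  for (k in seq_len(nrow(man)))
    write_network(cohort$networks[[k]], file.path(dir, man$matrix_file[k]))
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write result tables as CSV reports
#'
#' Serializes a named list of data frames deterministically: fixed column
#' order as given, floats at 10 significant digits, one `<name>.csv` per
#' table. Writing the same tables twice yields byte-identical files.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of file paths, invisibly.
#' @export
write_report <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    for (j in seq_along(tab)) {
      if (is.double(tab[[j]]))
        tab[[j]] <- formatC(tab[[j]], format = "g", digits = 10)
      if (is.factor(tab[[j]])) tab[[j]] <- as.character(tab[[j]])
    }
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Load the bundled reference post-hoc table
#'
#' A machine-readable copy of a published post-hoc edge table from a
#' three-group (MS / NMOSD / healthy-control) structural connectome study:
#' two disrupted subnetworks of 29 and 5 edges with FDR-adjusted p-values for
#' the three pairwise comparisons. Used as a worked example for
#' [count_significant()].
#'
#' @return Data frame with columns `subnetwork`, `edge`, `p_ms_lt_hc`,
#'   `p_nmosd_lt_hc`, `p_ms_lt_nmosd`.
#' @export
reference_posthoc_table <- function() {
  path <- system.file("extdata", "reference_posthoc_pvalues.csv",
                      package = "connstat", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
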