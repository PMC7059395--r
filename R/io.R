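#' Read a gene-by-cell count matrix
#'
#' Accepts either a 10X-style directory (`matrix.mtx[.gz]` plus
#' `barcodes.tsv[.gz]` and `features.tsv[.gz]` or `genes.tsv[.gz]`) or a
#' single dense delimited table with gene rows and a header of cell
#' identifiers. Gzip-compressed members are handled transparently.
#'
#' @param path Path to the directory or delimited file.
#' @param integer Require entries to be non-negative integers (default
#'   `TRUE`; set `FALSE` to read back real-valued decontaminated
#'   matrices).
#' @return Genes x cells `dgCMatrix` with gene and cell identifiers as
#'   dimnames. Non-integer or negative entries are rejected when
#'   `integer = TRUE`; duplicated gene identifiers are made unique with
#'   a warning.
#' @export
read_counts <- function(path, integer = TRUE) {
  if (dir.exists(path)) {
    read_counts_bundle(path, integer)
  } else if (file.exists(path)) {
    read_counts_dense(path, integer)
  } else {
    stop("no such file or directory: ", path, call. = FALSE)
  }
}

find_bundle_file <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  stop(sprintf("none of [%s] found in %s",
               paste(stems, collapse = ", "), dir), call. = FALSE)
}

# readMM needs an explicit connection for gzip members; the text
# readers handle compressed paths natively.
open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

read_counts_bundle <- function(dir, integer = TRUE) {
  mtx_path <- find_bundle_file(dir, "matrix.mtx")
  bc_path <- find_bundle_file(dir, "barcodes.tsv")
  ft_path <- find_bundle_file(dir, c("features.tsv", "genes.tsv"))

  con <- open_maybe_gz(mtx_path)
  on.exit(close(con), add = TRUE)
  X <- as(Matrix::readMM(con), "CsparseMatrix")

  barcodes <- readLines(bc_path)
  feat <- read.table(ft_path, sep = "\t",
                     header = FALSE, stringsAsFactors = FALSE,
                     quote = "", comment.char = "")

  if (length(barcodes) != ncol(X) || nrow(feat) != nrow(X)) {
    stop(sprintf(
      "matrix header says %d genes x %d cells but found %d feature and %d barcode lines",
      nrow(X), ncol(X), nrow(feat), length(barcodes)
    ), call. = FALSE)
  }
  if (integer) {
    check_integral(X@x, X@i + 1L,
                   rep.int(seq_len(ncol(X)), diff(X@p)))
  }

  gene_ids <- as.character(feat[[1]])
  if (anyDuplicated(gene_ids)) {
    warning("duplicated gene identifiers made unique by suffixing",
      call. = FALSE)
    gene_ids <- make.unique(gene_ids)
  }
  dimnames(X) <- list(gene_ids, barcodes)
  as_count_matrix(X)
}

read_counts_dense <- function(path, integer = TRUE) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- read.table(path, sep = sep, header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
  gene_ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  nz <- which(m != 0, arr.ind = TRUE)
  if (integer) check_integral(m[nz], nz[, 1], nz[, 2])
  if (anyDuplicated(gene_ids)) {
    warning("duplicated gene identifiers made unique by suffixing",
      call. = FALSE)
    gene_ids <- make.unique(gene_ids)
  }
  rownames(m) <- gene_ids
  as_count_matrix(m)
}

check_integral <- function(x, i, j) {
  bad <- which(x < 0 | x != round(x))
  if (length(bad)) {
    b <- bad[1]
    stop(sprintf(
      "non-integer or negative count %g at gene %d, cell %d",
      x[b], i[b], j[b]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read per-cell cluster labels
#'
#' Accepts a headered delimited file whose first two columns are cell
#' identifier and label (any order of rows), or a single unnamed label
#' column in matrix cell order. Arbitrary label strings are mapped to
#' `1..K`; the mapping is kept in the `levels` attribute.
#'
#' @param path Path to the labels file.
#' @param cell_ids Cell identifiers of the count matrix, in matrix
#'   order.
#' @return Integer labels in `1..K`, aligned with `cell_ids`, with a
#'   `levels` attribute recording the original label of each index.
#' @export
read_labels <- function(path, cell_ids) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  raw <- read.table(path, sep = sep, header = FALSE,
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "")
  if (ncol(raw) >= 2L) {
    tab <- read.table(path, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "")
    ids <- as.character(tab[[1]])
    labs <- as.character(tab[[2]])
    unknown <- setdiff(ids, cell_ids)
    if (length(unknown)) {
      warning(sprintf("dropping %d label(s) for unknown cell(s)",
                      length(unknown)), call. = FALSE)
      keep <- ids %in% cell_ids
      ids <- ids[keep]
      labs <- labs[keep]
    }
    missing <- setdiff(cell_ids, ids)
    if (length(missing)) {
      shown <- utils::head(missing, 10)
      stop(sprintf(
        "%d cell(s) missing from labels file, e.g.: %s",
        length(missing), paste(shown, collapse = ", ")
      ), call. = FALSE)
    }
    labs <- labs[match(cell_ids, ids)]
  } else {
    labs <- as.character(raw[[1]])
    if (length(labs) != length(cell_ids)) {
      stop(sprintf(
        "labels file has %d rows but the matrix has %d cells",
        length(labs), length(cell_ids)
      ), call. = FALSE)
    }
  }
  normalize_labels(labs)
}

# MatrixMarket coordinate writer. Matrix::writeMM always emits the
# "real" field, so the integer dialect (and a guaranteed column-major
# sorted coordinate order) is written directly; reading uses
# Matrix::readMM.
write_mtx <- function(X, path, dialect = c("real", "integer"),
                      gzip = FALSE) {
  dialect <- match.arg(dialect)
  X <- as(X, "CsparseMatrix")
  tr <- nz_triplets(X)
  vals <- if (dialect == "integer") {
    sprintf("%d", as.integer(round(tr$x)))
  } else {
    sprintf("%.10g", tr$x)
  }
  lines <- c(
    sprintf("%%%%MatrixMarket matrix coordinate %s general", dialect),
    sprintf("%d %d %d", nrow(X), ncol(X), length(tr$x)),
    sprintf("%d %d %s", tr$g, tr$j, vals)
  )
  if (gzip) path <- paste0(path, ".gz")
  con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  path
}

write_lines_maybe_gz <- function(lines, path, gzip = FALSE) {
  if (gzip) path <- paste0(path, ".gz")
  con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  path
}

#' Write a count matrix as a 10X-style MatrixMarket bundle
#'
#' @param counts Genes x cells matrix.
#' @param out_dir Output directory (created if needed).
#' @param dialect MatrixMarket field: `"integer"` or `"real"`.
#' @param gzip Compress the bundle members.
#' @return Named character vector of written paths, invisibly.
#' @export
write_counts <- function(counts, out_dir, dialect = "integer",
                         gzip = FALSE) {
  X <- as_count_matrix(counts)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = write_mtx(X, file.path(out_dir, "matrix.mtx"),
                       dialect = dialect, gzip = gzip),
    barcodes = write_lines_maybe_gz(colnames(X),
      file.path(out_dir, "barcodes.tsv"), gzip),
    features = write_lines_maybe_gz(
      paste(rownames(X), rownames(X), sep = "\t"),
      file.path(out_dir, "features.tsv"), gzip)
  )
  invisible(paths)
}

#' Write a fitted decontamination result
#'
#' Writes the decontaminated (native) matrix as a MatrixMarket bundle,
#' a per-cell table (`cell`, `cluster`, `contamination`,
#' `total_counts`) and a run-metadata file echoing the configuration,
#' iteration count, final lower bound and package version.
#'
#' @param result An `scambient` object from [decontaminate()].
#' @param out_dir Output directory (created if needed).
#' @param gzip Compress the matrix bundle members.
#' @return Named character vector of written paths, invisibly.
#' @export
write_result <- function(result, out_dir, gzip = FALSE) {
  stopifnot(inherits(result, "scambient"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  integer_mode <- isTRUE(result$trace$config$integer_output)
  paths <- write_counts(result$native_counts, out_dir,
    dialect = if (integer_mode) "integer" else "real", gzip = gzip)

  cells <- data.frame(
    cell = colnames(result$counts),
    cluster = attr(result$labels, "levels")[result$labels],
    contamination = unname(result$contamination),
    total_counts = Matrix::colSums(result$counts)
  )
  cell_path <- file.path(out_dir, "contamination.tsv")
  write.table(cells, cell_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  cfg <- result$trace$config
  meta <- c(
    sprintf("scAmbient %s", as.character(packageVersion("scAmbient"))),
    sprintf("genes: %d", nrow(result$counts)),
    sprintf("cells: %d", ncol(result$counts)),
    sprintf("populations: %d", length(attr(result$labels, "levels"))),
    sprintf("iterations: %d", result$trace$iterations),
    sprintf("converged: %s", result$trace$converged),
    sprintf("final_elbo: %.6f",
            result$trace$elbo[length(result$trace$elbo)]),
    sprintf("prior: %.6g %.6g", result$state$prior[1],
            result$state$prior[2]),
    vapply(names(cfg), function(k) {
      sprintf("config.%s: %s", k,
              paste(format(cfg[[k]]), collapse = " "))
    }, character(1))
  )
  meta_path <- file.path(out_dir, "run_metadata.txt")
  writeLines(meta, meta_path)

  invisible(c(paths, contamination = cell_path, metadata = meta_path))
}
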