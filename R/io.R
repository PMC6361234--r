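#' Read a variables-by-samples matrix
#'
#' Delimited formats (`tsv`, `csv`) expect a header row of sample IDs and
#' variable IDs in the first column (RFC-4180-style quoting is honored).
#' MatrixMarket (`mtx`) accepts coordinate or array files and requires
#' `<stem>.rownames` / `<stem>.colnames` sidecar files with one label per
#' line. Duplicate IDs, non-numeric cells and missing values are rejected.
#'
#' @param path Input file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"` (default guessed from the
#'   file extension).
#' @param transpose If TRUE, the file stores samples in rows; the matrix is
#'   transposed after reading.
#' @return A validated numeric matrix (see [as_data_matrix]).
#' @export
read_matrix <- function(path, format = c("tsv", "csv", "mtx"), transpose = FALSE) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tsv", "csv", "mtx")) ext else "tsv"
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  X <- if (format == "mtx") read_matrix_mtx(path) else
    read_matrix_delim(path, sep = if (format == "tsv") "\t" else ",")
  if (transpose) X <- t(X)
  as_data_matrix(X)
}

read_matrix_delim <- function(path, sep) {
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character",
                   quote = "\"", comment.char = "")
  if (ncol(df) < 2L || nrow(df) < 1L) stop("empty matrix in ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate variable id '", ids[duplicated(ids)][1], "' in ", path)
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id '", sample_ids[duplicated(sample_ids)][1], "' in ", path)
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(body)) + 1
    j <- ((bad[1] - 1) %/% nrow(body)) + 1
    stop("non-numeric or missing cell at variable '", ids[i], "', sample '",
         sample_ids[j], "' (value: '", body[bad[1]], "')")
  }
  matrix(vals, nrow(body), ncol(body), dimnames = list(ids, sample_ids))
}

read_matrix_mtx <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  rn_path <- paste0(stem, ".rownames")
  cn_path <- paste0(stem, ".colnames")
  if (!file.exists(rn_path)) stop("missing sidecar file: ", rn_path)
  if (!file.exists(cn_path)) stop("missing sidecar file: ", cn_path)
  header <- readLines(path, n = 1)
  X <- if (grepl("\\barray\\b", header)) {
    read_mtx_array(path)
  } else {
    as.matrix(Matrix::readMM(path))
  }
  rn <- readLines(rn_path)
  cn <- readLines(cn_path)
  if (length(rn) != nrow(X)) stop("rownames sidecar has ", length(rn),
                                  " labels for ", nrow(X), " rows")
  if (length(cn) != ncol(X)) stop("colnames sidecar has ", length(cn),
                                  " labels for ", ncol(X), " columns")
  dimnames(X) <- list(rn, cn)
  X
}

# Minimal MatrixMarket dense-array reader (Matrix::readMM only handles
# coordinate format). Column-major value order per the format spec.
read_mtx_array <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^%", lines) & nzchar(trimws(lines))]
  dims <- as.integer(strsplit(trimws(body[1]), "\\s+")[[1]])
  vals <- as.numeric(body[-1])
  if (length(vals) != dims[1] * dims[2]) stop("malformed MatrixMarket array file")
  matrix(vals, dims[1], dims[2])
}

#' Write a variables-by-samples matrix
#'
#' Numeric values are written with 17 significant digits so reading the file
#' back reproduces the doubles exactly. For `mtx`, the matrix is written in
#' coordinate format with `<stem>.rownames` / `<stem>.colnames` sidecars.
#'
#' @param X Numeric matrix.
#' @param path Output file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`.
#' @export
write_matrix <- function(X, path, format = c("tsv", "csv", "mtx")) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tsv", "csv", "mtx")) ext else "tsv"
  }
  format <- match.arg(format)
  X <- as_data_matrix(X)
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(methods::as(X, "CsparseMatrix"), path)
    writeLines(rownames(X), paste0(stem, ".rownames"))
    writeLines(colnames(X), paste0(stem, ".colnames"))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(id = rownames(X), check.names = FALSE, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(X))) df[[colnames(X)[j]]] <- fmt_num(X[, j])
    write.table(df, path, sep = sep, quote = 1L, row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Write a decomposition to disk
#'
#' Writes `<prefix>.U.tsv` (variables x components, columns named
#' `s<k>c<i>`), `<prefix>.V.tsv` (samples x components), `<prefix>.sigma.tsv`,
#' `<prefix>.signals.json` (per signal: dimension, threshold, selected
#' variable IDs, projection score, and the Frobenius norms of the expanded
#' and submatrix singular values), and one `<prefix>.scoregrid.<k>.tsv` per
#' iteration that recorded a grid.
#'
#' @param result An `smssvd` object.
#' @param prefix Output path prefix.
#' @return Character vector of the files written.
#' @export
write_result <- function(result, prefix) {
  stopifnot(inherits(result, "smssvd"))
  files <- character(0)
  u_path <- paste0(prefix, ".U.tsv")
  v_path <- paste0(prefix, ".V.tsv")
  s_path <- paste0(prefix, ".sigma.tsv")
  write_matrix(result$U, u_path, "tsv")
  write_matrix(result$V, v_path, "tsv")
  sig <- matrix(result$sigma, ncol = 1, dimnames = list(names(result$sigma), "sigma"))
  write_matrix(sig, s_path, "tsv")
  files <- c(u_path, v_path, s_path)

  var_ids <- rownames(result$U)
  sig_meta <- lapply(seq_along(result$signals), function(k) {
    s <- result$signals[[k]]
    sel_ids <- if (!is.null(s$selection) && s$selection$mode == "subset")
      var_ids[s$selection$indices] else var_ids
    list(signal = k, d = s$d, threshold = s$threshold, score = s$score,
         sigma = s$sigma,
         sigma_frobenius = frob(s$sigma),
         submatrix_sigma_frobenius = if (is.null(s$submatrix_sigma)) NULL
                                     else frob(s$submatrix_sigma),
         selected_variables = sel_ids)
  })
  j_path <- paste0(prefix, ".signals.json")
  jsonlite::write_json(sig_meta, j_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(files, j_path)

  for (k in seq_along(result$signals)) {
    g <- result$signals[[k]]$score_grid
    if (!is.null(g)) {
      g_path <- paste0(prefix, ".scoregrid.", k, ".tsv")
      write_score_grid(g, g_path)
      files <- c(files, g_path)
    }
  }
  invisible(files)
}
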