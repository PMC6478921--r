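# Readers and writers for the plain-text formats the pipeline consumes:
# TSV/GCT expression matrices, GMT gene-set collections, sample metadata,
# directional reference tables and gene annotations.

#' Read a log2 expression matrix
#'
#' Loads a genes-by-samples expression matrix from a TSV file (first column
#' gene symbol, header row sample identifiers) or a GCT 1.2 file. Values are
#' expected on the log2 scale; set `log2 = TRUE` to apply `log2(x + 1)` to
#' raw intensities. Rows containing missing values are dropped (with a
#' message); duplicate gene symbols are collapsed by keeping the row with the
#' highest mean intensity, the usual microarray probe-collapse convention.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"gct"`.
#' @param log2 Apply `log2(x + 1)` to the values after loading.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "A\t1\t2", "B\t3\t4"), tf)
#' read_expression(tf)
read_expression <- function(path, dialect = c("tsv", "gct"), log2 = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  if (dialect == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || !startsWith(header[[1L]], "#1.2")) {
      stop_format(paste0("malformed GCT header (line 1): ", header[[1L]]))
    }
    dims <- suppressWarnings(as.integer(strsplit(header[[2L]], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2])) {
      stop_format(paste0("malformed GCT dimension line (line 2): ", header[[2L]]))
    }
    df <- readr::read_tsv(path, skip = 2L, show_col_types = FALSE,
                          progress = FALSE)
    if (ncol(df) < 3L || !identical(toupper(names(df)[1:2]),
                                    c("NAME", "DESCRIPTION"))) {
      stop_format("GCT body must start with NAME and Description columns (line 3)")
    }
    genes <- as.character(df[[1L]])
    values <- as.matrix(df[, -(1:2), drop = FALSE])
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (ncol(df) < 2L) {
      stop_format("TSV expression file needs a gene column plus sample columns (line 1)")
    }
    genes <- as.character(df[[1L]])
    values <- as.matrix(df[, -1L, drop = FALSE])
  }
  storage.mode(values) <- "double"
  rownames(values) <- genes

  n_na <- sum(!complete.cases(values))
  if (n_na > 0L) {
    inform(paste0("dropping ", n_na, " gene row(s) with missing values"))
    values <- values[complete.cases(values), , drop = FALSE]
  }
  values <- collapse_duplicate_genes(values)
  if (isTRUE(log2)) values <- base::log2(values + 1)
  if (ncol(values) < 2L) {
    stop_degenerate("expression matrix has fewer than 2 samples")
  }
  assert_expression(values)
  values
}

# keep the row with the highest mean intensity per gene symbol
collapse_duplicate_genes <- function(values) {
  if (!anyDuplicated(rownames(values))) return(values)
  means <- rowMeans(values)
  ord <- order(rownames(values), -means)
  values <- values[ord, , drop = FALSE]
  values[!duplicated(rownames(values)), , drop = FALSE]
}

#' Write an expression matrix as TSV
#'
#' Values are serialized with full double precision; a write/read round trip
#' reproduces every value to within one unit in the last place of the
#' binary double (relative error below 1e-15).
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  assert_expression(expr)
  df <- tibble(gene = rownames(expr))
  for (s in colnames(expr)) df[[s]] <- expr[, s]
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Construct a gene signature
#'
#' A named set of up-regulated genes, optionally with down-regulated genes,
#' plus a free-text provenance label.
#'
#' @param name Signature name.
#' @param up Character vector of up-regulated gene symbols (non-empty).
#' @param down Character vector of down-regulated gene symbols.
#' @param source Provenance label.
#' @return An object of class `ifn_signature`.
#' @export
ifn_signature <- function(name, up, down = character(), source = "") {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(up) == 0L) stop_validation("a signature needs at least one up gene")
  if (length(intersect(up, down)) > 0L) {
    stop_validation("up and down gene sets must be disjoint")
  }
  structure(list(name = name, up = up, down = down, source = source),
            class = "ifn_signature")
}

#' @export
print.ifn_signature <- function(x, ...) {
  cat("<ifn_signature> ", x$name, ": ", length(x$up), " up",
      if (length(x$down)) paste0(", ", length(x$down), " down"), "\n", sep = "")
  invisible(x)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB gene...`.
#' The description field is stored as the signature source.
#'
#' @param path Path to the GMT file.
#' @return A named list of [ifn_signature()] objects (empty list for an
#'   empty file).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop_format(paste0("GMT line ", i, " has fewer than 3 fields"))
    }
    ifn_signature(fields[[1L]], up = fields[-(1:2)], source = fields[[2L]])
  })
  setNames(sigs, vapply(sigs, `[[`, character(1L), "name"))
}

#' Write signatures to a GMT file
#'
#' Down-regulated genes, when present, are written as a companion set named
#' `<name>_dn` so the format stays standard GMT.
#'
#' @param sigs A list of [ifn_signature()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  lines <- unlist(lapply(sigs, function(s) {
    out <- paste(c(s$name, s$source, s$up), collapse = "\t")
    if (length(s$down)) {
      out <- c(out, paste(c(paste0(s$name, "_dn"), s$source, s$down),
                          collapse = "\t"))
    }
    out
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata
#'
#' A TSV with columns `sample` and `group` plus optional `sledai`,
#' `timepoint`, `cell_type`, `tissue` and `patient`. Group labels are
#' restricted to `control` and `SLE`.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(meta)
}

#' Validate a metadata table
#'
#' @param meta A data frame with at least `sample` and `group` columns.
#' @param expr Optional expression matrix; when given, every metadata sample
#'   must resolve to a matrix column.
#' @return The metadata as a tibble.
#' @export
validate_metadata <- function(meta, expr = NULL) {
  meta <- as_tibble(meta)
  if (!all(c("sample", "group") %in% names(meta))) {
    stop_validation("metadata needs `sample` and `group` columns")
  }
  bad <- setdiff(unique(meta$group), c("control", "SLE"))
  if (length(bad) > 0L) {
    stop_validation(paste0("unknown group label(s): ",
                           paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample)) {
    stop_validation("duplicate sample identifiers in metadata")
  }
  if ("sledai" %in% names(meta)) {
    if (any(meta$sledai < 0, na.rm = TRUE)) {
      stop_validation("sledai must be non-negative")
    }
  }
  if (!is.null(expr)) {
    missing <- setdiff(meta$sample, colnames(expr))
    if (length(missing) > 0L) {
      stop_validation(paste0("metadata sample(s) absent from matrix: ",
                             paste(head(missing, 5L), collapse = ", ")))
    }
  }
  meta
}

#' Read a directional reference table
#'
#' A TSV with columns `gene`, `direction` (+1/-1) and optional `weight`
#' (default 1), describing the expected direction of each downstream target
#' of a reference contrast.
#'
#' @param path Path to the TSV.
#' @param name Reference name; defaults to the file name.
#' @return A tibble with columns gene, direction, weight and the reference
#'   name attached as attribute `reference`.
#' @export
read_directional_reference <- function(path, name = NULL) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  ref <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "direction") %in% names(ref))) {
    stop_validation("reference needs `gene` and `direction` columns")
  }
  if (!"weight" %in% names(ref)) ref$weight <- 1
  validate_directional_reference(ref, name %||% basename(path))
}

validate_directional_reference <- function(ref, name = "reference") {
  ref <- as_tibble(ref)
  if (!all(ref$direction %in% c(-1, 1))) {
    stop_validation("reference directions must be +1 or -1")
  }
  if (any(ref$weight <= 0)) stop_validation("reference weights must be positive")
  attr(ref, "reference") <- name
  ref
}

#' Read a gene annotation table
#'
#' A TSV with columns `gene` and `class`, e.g. an offline export of an
#' interferon-inducibility database assigning each gene a type I / type II
#' class.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns gene and class.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "class") %in% names(ann))) {
    stop_validation("annotation needs `gene` and `class` columns")
  }
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a
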