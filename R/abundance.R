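#' Construct a relative-abundance table
#'
#' An abundance table is a numeric taxa-by-samples matrix of relative
#' abundances in which every sample column sums to one (all-zero columns are
#' tolerated but flagged, since a sample in which no taxon of the given kind
#' was detected carries no compositional information). Each taxon carries a
#' kind tag, `"virus"` or `"bacteria"`, so that downstream stages can enforce
#' bipartite structure.
#'
#' @param values numeric matrix, taxa in rows, samples in columns; rownames
#'   are taxon names and colnames are sample ids (both required).
#' @param kind character vector, one of `"virus"`/`"bacteria"` per taxon;
#'   recycled if length one.
#' @param renormalize if `TRUE`, divide each non-zero column by its sum
#'   instead of requiring unit sums on input.
#' @return a matrix of class `abundance_table` with a `kind` attribute.
#' @examples
#' m <- matrix(c(0.75, 0.25, 0.5, 0.5), 2, 2,
#'             dimnames = list(c("vA", "vB"), c("s1", "s2")))
#' abundance_table(m, kind = "virus")
#' @export
abundance_table <- function(values, kind = "virus", renormalize = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix needs taxon rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate taxon names in abundance table")
  if (any(values < 0)) stop("negative abundances are not allowed")
  kind <- rep_len(as.character(kind), nrow(values))
  if (!all(kind %in% c("virus", "bacteria")))
    stop("taxon kind must be 'virus' or 'bacteria'")
  csum <- colSums(values)
  if (renormalize) {
    nz <- csum > 0
    values[, nz] <- sweep(values[, nz, drop = FALSE], 2, csum[nz], "/")
  } else {
    bad <- which(csum > 0 & abs(csum - 1) > 1e-9)
    if (length(bad))
      stop("sample columns do not sum to 1: ",
           paste(colnames(values)[bad], collapse = ", "),
           " (use renormalize = TRUE to rescale)")
  }
  structure(values,
            kind = stats::setNames(kind, rownames(values)),
            zero_samples = colnames(values)[colSums(values) == 0],
            class = c("abundance_table", class(values)))
}

#' @export
print.abundance_table <- function(x, ...) {
  kind <- attr(x, "kind")
  cat(sprintf("abundance_table: %d taxa (%d virus, %d bacteria) x %d samples\n",
              nrow(x), sum(kind == "virus"), sum(kind == "bacteria"), ncol(x)))
  zs <- attr(x, "zero_samples")
  if (length(zs)) cat("all-zero samples:", paste(zs, collapse = ", "), "\n")
  invisible(x)
}

#' Taxon kind tags of an abundance table
#' @param table an `abundance_table`.
#' @return named character vector of `"virus"`/`"bacteria"` per taxon.
#' @export
taxon_kind <- function(table) {
  k <- attr(table, "kind")
  if (is.null(k)) stop("not an abundance_table: no kind attribute")
  k
}

#' Read / write abundance tables as TSV
#'
#' The on-disk format is a tab-separated file with one row per taxon and the
#' header `taxon  kind  <sample ids...>`. `write_abundance_table` followed by
#' `read_abundance_table` is an identity up to float formatting (~1e-12).
#'
#' @param path file path.
#' @param renormalize passed to [abundance_table()]; when `FALSE` (default)
#'   files whose columns do not sum to one are rejected.
#' @return `read_abundance_table` returns an `abundance_table`.
#' @export
read_abundance_table <- function(path, renormalize = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(colnames(df)[1:2], c("taxon", "kind")))
    stop("malformed abundance TSV: expected header 'taxon\\tkind\\t<samples>' in ", path)
  if (anyDuplicated(df$taxon)) {
    dup <- which(duplicated(df$taxon))[1]
    stop("duplicate taxon '", df$taxon[dup], "' at line ", dup + 1L, " of ", path)
  }
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!apply(df[, -(1:2), drop = FALSE], 1, function(r)
      all(!is.na(suppressWarnings(as.numeric(r))))))[1]
    stop("non-numeric abundance at line ", bad + 1L, " of ", path)
  }
  if (any(vals < 0)) {
    bad <- which(apply(vals, 1, function(r) any(r < 0)))[1]
    stop("negative abundance at line ", bad + 1L, " of ", path)
  }
  rownames(vals) <- df$taxon
  abundance_table(vals, kind = df$kind, renormalize = renormalize)
}

#' @param table an `abundance_table` to serialize.
#' @rdname read_abundance_table
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(taxon = rownames(table),
                   kind = unname(taxon_kind(table)),
                   as.data.frame(unclass(table), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample group labels
#'
#' Two-column TSV `sample_id TAB group`, no header.
#' @param labels named factor (names = sample ids) or the return of
#'   `read_labels`.
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(names(labels), as.character(labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("labels file must have two columns: sample_id, group")
  stats::setNames(factor(df[[2]]), df[[1]])
}

# run code under a temporary RNG state so callers' streams are untouched
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
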