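# File-format suite. All formats are plain UTF-8 text; every reader
# validates structure and reports the file, line and offending content on
# malformed input; write/read round-trips reproduce the canonical object
# (numeric values to full double precision via "%.17g").

fmt_num <- function(x) sprintf("%.17g", x)

#' Read / write a gene list (one symbol per line)
#'
#' @param path file path.
#' @return character vector of trimmed, nonempty gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  x <- trimws(readLines(path, encoding = "UTF-8"))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes character vector of gene symbols.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(trimws(genes), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' Dialect: tab-separated; each record is `name<TAB>description<TAB>member...`
#' with at least three columns and no trailing tabs.
#'
#' @param path file path.
#' @param channel channel label to attach (default: file base name).
#' @param annotation_universe optional explicit annotation universe;
#'   defaults to the union of all set members.
#' @return a [geneset_collection()].
#' @export
read_gmt <- function(path, channel = NULL, annotation_universe = NULL) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    if (endsWith(lines[i], "\t")) {
      stop_format(path, " line ", i, ": trailing tab in GMT record")
    }
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop_format(path, " line ", i, ": GMT record needs >= 3 tab-separated ",
                  "columns, got ", length(f), ": '", lines[i], "'")
    }
    sets[[trimws(f[1])]] <- trimws(f[-(1:2)])
  }
  geneset_collection(channel %||% sub("\\.gmt$", "", basename(path)), sets,
                     annotation_universe %||%
                       unique(unlist(sets, use.names = FALSE)))
}

#' @rdname read_gmt
#' @param collection a [geneset_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$channel, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write an expression dataset (TSV + sidecar label file)
#'
#' Matrix file: header `gene<TAB>sample...`, one row per gene. Label
#' file: two tab-separated columns `sample`, `group` (normal/tumor).
#'
#' @param path matrix TSV path.
#' @param labels_path label TSV path (default `<path>.labels`).
#' @param name dataset label.
#' @return an [expr_dataset()].
#' @export
read_expression <- function(path, labels_path = paste0(path, ".labels"),
                            name = sub("\\.tsv$", "", basename(path))) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") {
    stop_format(path, ": first column must be named 'gene'")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    col <- names(df)[-1][bad]
    cell <- df[[col]][which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]]
    stop_format(path, ": non-numeric expression value '", cell,
                "' in sample column '", col, "'")
  }
  rownames(vals) <- df$gene
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(lab))) {
    stop_format(labels_path, ": needs columns 'sample' and 'group'")
  }
  miss <- setdiff(colnames(vals), lab$sample)
  if (length(miss)) {
    stop_format(labels_path, ": no group label for sample(s) ",
                paste(utils::head(miss, 5), collapse = ", "))
  }
  expr_dataset(vals, lab$group[match(colnames(vals), lab$sample)], name)
}

#' @rdname read_expression
#' @param dataset an [expr_dataset()].
#' @export
write_expression <- function(dataset, path,
                             labels_path = paste0(path, ".labels")) {
  header <- paste(c("gene", colnames(dataset$values)), collapse = "\t")
  body <- paste(rownames(dataset$values),
                apply(dataset$values, 1, function(r)
                  paste(fmt_num(r), collapse = "\t")), sep = "\t")
  writeLines(c(header, body), path, useBytes = TRUE)
  writeLines(c("sample\tgroup",
               paste(names(dataset$group), as.character(dataset$group),
                     sep = "\t")), labels_path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a drug-target table (TSV)
#'
#' Columns: drug, target, status, action.
#'
#' @param path file path.
#' @return a [drug_target_map()].
#' @export
read_drug_targets <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  drug_target_map(df)
}

#' @rdname read_drug_targets
#' @param map a [drug_target_map()].
#' @export
write_drug_targets <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write compound rank profiles (GCT-like TSV)
#'
#' First column `gene`; one column per profile named
#' `compound:cell_line`; cells are integer ranks forming a permutation
#' of 1..N per column. Compound names must not contain ':'.
#'
#' @param path file path.
#' @param reference reference compound name to record (read only).
#' @return a `rank_profiles` object.
#' @export
read_rank_profiles <- function(path, reference = NULL) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") {
    stop_format(path, ": first column must be named 'gene'")
  }
  ranks <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(ranks)) stop_format(path, ": non-numeric rank value")
  storage.mode(ranks) <- "integer"
  rownames(ranks) <- df$gene
  parts <- strsplit(colnames(ranks), ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    bad <- colnames(ranks)[lengths(parts) != 2L][1]
    stop_format(path, ": profile column '", bad,
                "' is not of the form compound:cell_line")
  }
  compound <- vapply(parts, `[`, character(1), 1L)
  cell_line <- vapply(parts, `[`, character(1), 2L)
  N <- nrow(ranks)
  for (j in seq_len(ncol(ranks))) {
    if (!identical(sort(unname(ranks[, j])), seq_len(N))) {
      stop_format(path, ": column '", colnames(ranks)[j],
                  "' is not a permutation of 1..", N)
    }
  }
  structure(list(genes = df$gene, ranks = ranks, compound = compound,
                 cell_line = cell_line,
                 reference = reference %||% compound[1]),
            class = "rank_profiles")
}

#' @rdname read_rank_profiles
#' @param profiles a `rank_profiles` object.
#' @export
write_rank_profiles <- function(profiles, path) {
  if (any(grepl(":", profiles$compound, fixed = TRUE))) {
    stop_format("compound names must not contain ':'")
  }
  header <- paste(c("gene", paste(profiles$compound, profiles$cell_line,
                                  sep = ":")), collapse = "\t")
  body <- paste(profiles$genes,
                apply(profiles$ranks, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write an evidence registry (TSV)
#'
#' Columns: drug, kind (trial/publication), phase (empty for
#' publications), id.
#'
#' @param path file path.
#' @return an [evidence_registry()].
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(phase = "integer"))
  evidence_registry(df)
}

#' @rdname read_evidence
#' @param registry an [evidence_registry()].
#' @export
write_evidence <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
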