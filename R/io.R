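# Readers and writers for the tabular dialects shared by the pipeline:
# tab-separated, UTF-8, header row, '.' decimal, "NA" for missing; GMT for
# term sets; plain one-id-per-line gene lists; JSON for results metadata.

.write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    fileEncoding = "UTF-8")
}

#' Read / write a gene x site expression matrix
#'
#' TSV with a `gene_id` column followed by one column per site. Duplicate
#' gene or site ids are schema violations and raise an error naming them.
#'
#' @param path File path.
#' @param m Gene x site numeric matrix with dimnames.
#' @return `read_expression_matrix`: the matrix; `write_expression_matrix`:
#'   the path, invisibly.
#' @export
read_expression_matrix <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "gene_id")
    .stopf("%s: first column must be gene_id", path)
  if (anyDuplicated(df$gene_id))
    .stopf("%s: duplicated gene id(s): %s", path,
           paste(utils::head(unique(df$gene_id[duplicated(df$gene_id)]), 5),
                 collapse = ", "))
  if (anyDuplicated(names(df)[-1]))
    .stopf("%s: duplicated site id(s) in header", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) .stopf("%s: non-numeric expression values", path)
  rownames(m) <- df$gene_id
  m
}

#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(m, path) {
  .write_tsv(data.frame(gene_id = rownames(m), m, check.names = FALSE),
             path)
}

#' Read / write a group imaging dataset
#'
#' TSV with columns `subject_id`, `group` (`case`/`control`), then one
#' column per site; one file per imaging index.
#'
#' @param path File path.
#' @param index_name Imaging index name to attach.
#' @param dataset A `GroupImagingDataset` list.
#' @return `read_imaging_dataset`: a `GroupImagingDataset`;
#'   `write_imaging_dataset`: the path, invisibly.
#' @export
read_imaging_dataset <- function(path, index_name) {
  df <- .read_tsv(path)
  if (!identical(names(df)[1:2], c("subject_id", "group")))
    .stopf("%s: first columns must be subject_id, group", path)
  bad <- which(!df$group %in% c("case", "control"))
  if (length(bad))
    .stopf("%s: invalid group at row(s) %s", path,
           paste(utils::head(bad, 5), collapse = ", "))
  v <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(v)) .stopf("%s: non-numeric imaging values", path)
  rownames(v) <- df$subject_id
  list(index_name = index_name, values = v, group = df$group)
}

#' @rdname read_imaging_dataset
#' @export
write_imaging_dataset <- function(dataset, path) {
  .write_tsv(data.frame(subject_id = rownames(dataset$values),
                        group = dataset$group, dataset$values,
                        check.names = FALSE), path)
}

#' Read / write a developmental expression set
#'
#' TSV with columns `sample_id`, `period`, `region`, `sex`, then one column
#' per gene.
#'
#' @param path File path.
#' @param periods,regions Level vocabularies (defaults [dev_periods()],
#'   [dev_regions()]).
#' @param dev A `dev_expression` object.
#' @return `read_dev_expression`: a `dev_expression`;
#'   `write_dev_expression`: the path, invisibly.
#' @export
read_dev_expression <- function(path, periods = dev_periods(),
                                regions = dev_regions()) {
  df <- .read_tsv(path)
  meta_cols <- c("sample_id", "period", "region", "sex")
  if (!identical(names(df)[1:4], meta_cols))
    .stopf("%s: first columns must be %s", path,
           paste(meta_cols, collapse = ", "))
  bad <- which(!df$period %in% periods | !df$region %in% regions |
                 !df$sex %in% c("female", "male"))
  if (length(bad))
    .stopf("%s: invalid annotation at row(s) %s", path,
           paste(utils::head(bad, 5), collapse = ", "))
  expr <- as.matrix(df[, -(1:4), drop = FALSE])
  rownames(expr) <- df$sample_id
  structure(list(samples = df[, meta_cols], expr = expr,
                 periods = periods, regions = regions),
            class = "dev_expression")
}

#' @rdname read_dev_expression
#' @export
write_dev_expression <- function(dev, path) {
  .write_tsv(data.frame(dev$samples, dev$expr, check.names = FALSE), path)
}

#' Read / write a scored interaction edge list
#'
#' TSV with columns `protein_a`, `protein_b`, `combined_score` (the
#' detailed-links dialect of interaction databases).
#'
#' @param path File path.
#' @param edges Edge data frame.
#' @return `read_edge_list`: a data frame; `write_edge_list`: the path,
#'   invisibly.
#' @export
read_edge_list <- function(path) {
  df <- .read_tsv(path)
  need <- c("protein_a", "protein_b", "combined_score")
  if (!all(need %in% names(df)))
    .stopf("%s: columns must include %s", path, paste(need, collapse = ", "))
  df$combined_score <- as.numeric(df$combined_score)
  bad <- which(is.na(df$combined_score))
  if (length(bad))
    .stopf("%s: non-numeric combined_score at row(s) %s", path,
           paste(utils::head(bad, 5), collapse = ", "))
  df
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(edges, path) .write_tsv(edges, path)

#' Read / write GMT term sets
#'
#' One term per line: term id, description, then tab-separated gene ids.
#'
#' @param path File path.
#' @param terms Named list of character vectors.
#' @param descriptions Optional per-term descriptions.
#' @return `read_gmt`: named list of character vectors; `write_gmt`: the
#'   path, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      .stopf("%s: line %d has fewer than 3 fields", path, i)
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1),
    USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(terms, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(terms))
  lines <- vapply(seq_along(terms), function(i)
    paste(c(names(terms)[i], descriptions[i], terms[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a plain gene list
#'
#' One gene id per line.
#'
#' @param path File path.
#' @param genes Character vector.
#' @return `read_gene_list`: character vector; `write_gene_list`: the
#'   path, invisibly.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8")
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a probe table
#'
#' Two TSVs of identical shape: intensities with columns `probe_id`,
#' `gene_id` and one column per site, and a matching boolean
#' above-background flag table.
#'
#' @param values_path,flags_path File paths.
#' @param probes A `probe_table`.
#' @return `read_probe_table`: a `probe_table`; `write_probe_table`: the
#'   paths, invisibly.
#' @export
read_probe_table <- function(values_path, flags_path) {
  v <- .read_tsv(values_path)
  f <- .read_tsv(flags_path)
  if (!identical(names(v)[1:2], c("probe_id", "gene_id")))
    .stopf("%s: first columns must be probe_id, gene_id", values_path)
  if (!identical(dim(v), dim(f)) || !identical(v$probe_id, f$probe_id))
    .stopf("probe value and flag tables do not match")
  vm <- as.matrix(v[, -(1:2), drop = FALSE])
  fm <- as.matrix(f[, -(1:2), drop = FALSE])
  storage.mode(fm) <- "logical"
  probe_table(v$probe_id, v$gene_id, vm, fm)
}

#' @rdname read_probe_table
#' @export
write_probe_table <- function(probes, values_path, flags_path) {
  .write_tsv(data.frame(probe_id = probes$probe_id,
                        gene_id = probes$gene_id, probes$values,
                        check.names = FALSE), values_path)
  .write_tsv(data.frame(probe_id = probes$probe_id,
                        gene_id = probes$gene_id, probes$flags,
                        check.names = FALSE), flags_path)
  invisible(c(values_path, flags_path))
}
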