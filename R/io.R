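# Readers and writers for the pipeline's plain-text formats: expression TSV,
# annotation TSV, stage-label TSV, ranked edge TSV, GMT gene sets, GraphML.
# All readers reject malformed input with located errors; every writer/reader
# pair is an inverse on valid data.

split_tsv_lines <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample identifiers; the
#' first column holds gene identifiers, the remaining columns numeric values.
#' Ragged rows, non-numeric cells and duplicated identifiers are rejected
#' with the offending line number.
#'
#' @param path file path.
#' @return numeric matrix (genes x samples) with dimnames.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stopf("%s: empty file", path)
  cells <- split_tsv_lines(lines)
  header <- cells[[1]]
  ncol_expect <- length(header)
  if (ncol_expect < 2L) stopf("%s: header must name at least one sample (line 1)", path)
  samples <- header[-1]
  if (anyDuplicated(samples))
    stopf("%s: duplicated sample ID '%s' (line 1)", path, samples[duplicated(samples)][1])
  body <- cells[-1]
  lens <- lengths(body)
  if (any(lens != ncol_expect)) {
    bad <- which(lens != ncol_expect)[1]
    stopf("%s: ragged row with %d fields, expected %d (line %d)",
          path, lens[bad], ncol_expect, bad + 1L)
  }
  genes <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1]
    stopf("%s: duplicated gene ID '%s' (line %d)",
          path, dup, which(genes == dup)[2] + 1L)
  }
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(ncol_expect - 1L))
  )
  vals <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = ncol_expect - 1L)
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stopf("%s: non-numeric value (line %d)", path, bad + 1L)
  }
  dimnames(vals) <- list(genes, samples)
  validate_expression(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' @param matrix numeric genes-by-samples matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path) {
  validate_expression(matrix)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(matrix, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Read a gene-to-chromosome annotation table
#'
#' Two-column TSV (`gene_id`, `chromosome`) with header. Chromosome labels
#' are opaque strings; an optional "chr" prefix is tolerated and treated as
#' equivalent to the bare label when classifying cis/trans edges.
#'
#' @param path file path.
#' @return named character vector: chromosome label per gene.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stopf("%s: annotation needs columns gene_id, chromosome", path)
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stopf("%s: duplicated gene ID '%s'", path, genes[duplicated(genes)][1])
  stats::setNames(df[[2]], genes)
}

#' @rdname read_annotation
#' @param annotation named character vector (chromosome per gene).
#' @export
write_annotation <- function(annotation, path) {
  df <- data.frame(gene_id = names(annotation), chromosome = unname(annotation))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample-to-phenotype labels
#'
#' Two-column TSV (`sample_id`, `phenotype`) with header. The control
#' phenotype must be present among the labels.
#'
#' @param path file path.
#' @param control label of the control phenotype.
#' @return object of class `stage_labels`: a data.frame with columns
#'   `sample_id`, `phenotype` and attribute `control`.
#' @export
read_labels <- function(path, control) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stopf("%s: labels need columns sample_id, phenotype", path)
  stage_labels(stats::setNames(df[[2]], df[[1]]), control = control)
}

#' @rdname read_labels
#' @param labels a `stage_labels` object.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = labels$sample_id, phenotype = labels$phenotype),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct stage labels
#'
#' @param x named character vector mapping sample_id to phenotype label.
#' @param control the designated control phenotype label.
#' @param phenotype_order optional ordering of phenotype labels
#'   (control first); defaults to control followed by the remaining labels
#'   in order of first appearance.
#' @return a `stage_labels` data.frame.
#' @export
stage_labels <- function(x, control, phenotype_order = NULL) {
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stopf("sample IDs must be unique and named")
  if (!is_string(control)) stopf("control must be a single phenotype label")
  phen <- unname(x)
  if (!control %in% phen) stopf("control phenotype '%s' has no samples", control)
  if (is.null(phenotype_order))
    phenotype_order <- c(control, setdiff(unique(phen), control))
  if (!setequal(phenotype_order, unique(phen)) || phenotype_order[1] != control)
    stopf("phenotype_order must list every phenotype with the control first")
  out <- data.frame(sample_id = names(x), phenotype = phen,
                    stringsAsFactors = FALSE)
  attr(out, "control") <- control
  attr(out, "phenotype_order") <- phenotype_order
  class(out) <- c("stage_labels", "data.frame")
  out
}

#' @export
print.stage_labels <- function(x, ...) {
  tab <- table(factor(x$phenotype, levels = attr(x, "phenotype_order")))
  cat("Stage labels (control =", attr(x, "control"), "):\n")
  print(tab)
  invisible(x)
}

label_samples <- function(labels, phenotype) {
  labels$sample_id[labels$phenotype == phenotype]
}

#' Read / write a ranked edge list
#'
#' TSV with header `gene_a`, `gene_b`, `mi`. On read, pairs are canonicalized
#' (`gene_a < gene_b`) and sorted by decreasing MI with lexicographic
#' tie-break, so a write/read round trip is stable after the first
#' canonicalization. Self-loops, duplicate pairs and negative MI are errors.
#'
#' @param path file path.
#' @return an [mi_edges()] edge list.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE,
                          colClasses = c("character", "character", "numeric"))
  if (!all(c("gene_a", "gene_b", "mi") %in% names(df)))
    stopf("%s: edge file needs columns gene_a, gene_b, mi", path)
  mi_edges(df$gene_a, df$gene_b, df$mi)
}

#' @rdname read_edges
#' @param edges an `mi_edges` edge list.
#' @export
write_edges <- function(edges, path) {
  stopifnot(inherits(edges, "mi_edges"))
  df <- as.data.frame(edges)
  df$mi <- format(df$mi, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-delimited fields
#' `name`, `description`, members... Duplicate members are collapsed.
#'
#' @param path file path.
#' @return named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(list(), character(0)))
  cells <- split_tsv_lines(lines)
  lens <- lengths(cells)
  if (any(lens < 3L))
    stopf("%s: GMT line with fewer than 3 fields (line %d)", path, which(lens < 3L)[1])
  sets <- lapply(cells, function(r) unique(r[-c(1, 2)]))
  names(sets) <- vapply(cells, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stopf("%s: duplicated gene-set name '%s'", path, names(sets)[duplicated(names(sets))][1])
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export an annotated network as GraphML
#'
#' Writes a classified (cis/trans) network in GraphML, with the cis/trans
#' flag stored as an edge attribute, the chromosome as a node attribute and
#' any further per-node attributes (for example differential-expression
#' status) passed via `node_attrs`.
#'
#' @param network an `annotated_network` from [classify_edges()].
#' @param node_attrs optional named list of named vectors; each vector maps
#'   node identifiers to an attribute value. Attributes for unknown nodes
#'   are an error.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, node_attrs = NULL, path) {
  stopifnot(inherits(network, "annotated_network"))
  g <- annotated_network_igraph(network)
  if (!is.null(node_attrs)) {
    for (attr_name in names(node_attrs)) {
      v <- node_attrs[[attr_name]]
      unknown <- setdiff(names(v), network$nodes)
      if (length(unknown) > 0)
        stopf("node attribute '%s' refers to unknown node '%s'",
              attr_name, unknown[1])
      full <- stats::setNames(rep(NA_character_, length(network$nodes)),
                              network$nodes)
      full[names(v)] <- as.character(v)
      g <- igraph::set_vertex_attr(g, attr_name, value = unname(full))
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

annotated_network_igraph <- function(network) {
  edges <- network$edges
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = network$nodes,
                          chromosome = unname(network$annotation[network$nodes])))
  if (nrow(edges) > 0) {
    g <- igraph::set_edge_attr(g, "type", value = edges$type)
    if ("mi" %in% names(edges))
      g <- igraph::set_edge_attr(g, "weight", value = edges$mi)
  }
  g
}
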