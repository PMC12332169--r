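# File ingestion: expression tables, GMT gene-set collections, interaction
# networks.  All readers validate and normalise; matching writers make
# write -> read an identity so synthetic cohorts round-trip exactly.

#' Construct an ExpressionMatrix
#'
#' Bundles a numeric gene x sample matrix (log2 units) with a two-level
#' case/control annotation.  Most users will obtain one from
#' [read_expression()] or [generate_cohort()] rather than calling this
#' directly.
#'
#' @param values numeric matrix, genes in rows (rownames), samples in
#'   columns (colnames); values on the log2 scale.
#' @param group_of named character vector mapping every sample to
#'   `"case"` or `"control"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `group_of` (named vector aligned to the
#'   matrix columns).
#' @export
expression_matrix <- function(values, group_of) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in expression matrix")
  if (!all(is.finite(values)))
    stop("non-finite expression values after transform")
  missing <- setdiff(colnames(values), names(group_of))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  group_of <- group_of[colnames(values)]
  bad <- setdiff(unique(group_of), c("case", "control"))
  if (length(bad))
    stop("group labels must be 'case'/'control', found: ",
         paste(bad, collapse = ", "))
  if (!all(c("case", "control") %in% group_of))
    stop("both 'case' and 'control' groups must be non-empty")
  structure(list(values = values, group_of = group_of),
            class = "ExpressionMatrix")
}

#' @exportS3Method base::print
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group_of == "case"), sum(x$group_of == "control")))
  invisible(x)
}

#' Sample IDs of one group
#'
#' @param expr an `ExpressionMatrix`.
#' @param group `"case"` or `"control"`.
#' @return Character vector of sample IDs.
#' @export
group_samples <- function(expr, group = c("case", "control")) {
  group <- match.arg(group)
  names(expr$group_of)[expr$group_of == group]
}

#' Read a gene x sample expression table
#'
#' Reads a TSV with gene identifiers in the first column and sample IDs in
#' the header.  Unless `assume_log` is set, values are transformed to
#' `log2(x + pseudocount)`.  Duplicate gene rows are collapsed by keeping
#' the row with the highest mean expression.
#'
#' @param path path to the tab-separated table.
#' @param group_map named character vector: sample -> `"case"`/`"control"`.
#' @param pseudocount nonnegative offset added before the log2 transform.
#' @param assume_log if `TRUE` the table is already log2 and is ingested
#'   as-is.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, group_map, pseudocount = 1,
                            assume_log = FALSE) {
  stopifnot(pseudocount >= 0)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs >= 1 sample column")
  genes <- as.character(tab[[1]])
  samples <- colnames(tab)[-1]
  if (anyDuplicated(samples))
    stop("duplicated sample header in ", path)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(tab[[bad + 1]]))))[1]
    stop(sprintf("non-numeric expression value at row %s, column '%s'",
                 ifelse(is.na(badrow), "?", badrow), samples[bad]))
  }
  rownames(vals) <- genes
  if (anyDuplicated(genes)) {
    means <- rowMeans(vals)
    keep <- unlist(lapply(split(seq_along(genes), genes), function(i)
      i[which.max(means[i])]), use.names = FALSE)
    vals <- vals[sort(keep), , drop = FALSE]
  }
  if (!assume_log) vals <- log2(vals + pseudocount)
  missing <- setdiff(colnames(vals), names(group_map))
  if (length(missing))
    stop("missing group label for sample(s): ",
         paste(missing, collapse = ", "))
  expression_matrix(vals, group_map)
}

#' Write an expression table
#'
#' @param expr an `ExpressionMatrix`.
#' @param path output TSV path.  Values are written as-is (log2 scale);
#'   re-read with `assume_log = TRUE`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  chr <- matrix(sprintf("%.17g", expr$values), nrow = nrow(expr$values),
                dimnames = dimnames(expr$values))
  df <- data.frame(gene = rownames(chr), chr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per tab-separated line: name, description, then member genes.
#' Member lists are deduplicated preserving first occurrence; sets with no
#' members after parsing are dropped.
#'
#' @param path path to the `.gmt` file.
#' @return A `GeneSetCollection`: a named list of character vectors with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   i, length(f)))
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) next
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors (members are deduplicated).
#' @param descriptions optional named character vector of descriptions.
#' @return A `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (anyDuplicated(names(sets))) stop("gene-set names must be unique")
  sets <- lapply(sets, unique)
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(sets, descriptions = descriptions[names(sets)],
            class = "GeneSetCollection")
}

#' @exportS3Method base::print
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, median size %s\n", length(x),
              if (length(x)) stats::median(lengths(x)) else NA))
  invisible(x)
}

#' Write a GeneSetCollection to GMT
#'
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(collection)),
                                             names(collection))
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct an InteractionNetwork
#'
#' Edge list with confidences in `[0, 1]`.  Self-loops are dropped;
#' duplicate edges (including reversed pairs when undirected) are merged
#' keeping the maximum confidence.
#'
#' @param edges data frame with columns `source`, `target` and optionally
#'   `confidence` (defaults to 1).
#' @param directed logical; protein interaction networks are undirected by
#'   default.
#' @return An `InteractionNetwork`: list with `edges` data frame and
#'   `directed` flag.
#' @export
interaction_network <- function(edges, directed = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(edges)))
    stop("edges need 'source' and 'target' columns")
  if (is.null(edges$confidence)) edges$confidence <- 1
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (any(!nzchar(edges$source)) || any(!nzchar(edges$target)))
    stop("edge referencing an empty gene symbol")
  if (any(edges$confidence < 0 | edges$confidence > 1))
    stop("confidence values must lie in [0, 1]")
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  key <- if (directed) paste(edges$source, edges$target, sep = "\r")
         else paste(pmin(edges$source, edges$target),
                    pmax(edges$source, edges$target), sep = "\r")
  if (nrow(edges)) {
    conf <- tapply(edges$confidence, key, max)
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$confidence <- as.numeric(conf[key[first]])
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges[, c("source", "target", "confidence")],
                 directed = directed),
            class = "InteractionNetwork")
}

#' @exportS3Method base::print
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d %s edges over %d genes\n",
              nrow(x$edges), if (x$directed) "directed" else "undirected",
              length(network_genes(x))))
  invisible(x)
}

#' Genes appearing in a network
#'
#' @param network an `InteractionNetwork`.
#' @return Sorted character vector of node names.
#' @export
network_genes <- function(network) {
  sort(unique(c(network$edges$source, network$edges$target)))
}

#' Read an interaction network edge list
#'
#' TSV with columns `source`, `target` and optional `confidence` (assumed
#' 1 when absent).  Edges are retained only when confidence is strictly
#' greater than `min_confidence`; an edge at exactly the threshold is
#' excluded, matching the usual "score > 0.7" convention for
#' high-confidence interactomes.
#'
#' @param path edge-list path.
#' @param min_confidence strict lower bound on confidence (default 0 keeps
#'   everything with positive confidence; pass `-Inf` to keep all).
#' @param directed treat edges as directed.
#' @return An [interaction_network()].
#' @export
read_network <- function(path, min_confidence = 0, directed = FALSE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(tab)))
    stop("network file needs 'source' and 'target' columns: ", path)
  if (is.null(tab$confidence)) tab$confidence <- 1
  tab <- tab[tab$confidence > min_confidence, , drop = FALSE]
  interaction_network(tab, directed = directed)
}

#' Write an interaction network edge list
#'
#' @param network an `InteractionNetwork`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  ed <- network$edges
  ed$confidence <- sprintf("%.17g", ed$confidence)
  utils::write.table(ed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a one-gene-per-line list
#'
#' @param path text file, one gene per line; blank lines ignored.
#' @return Character vector, deduplicated preserving order.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  unique(x[nzchar(trimws(x))])
}
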