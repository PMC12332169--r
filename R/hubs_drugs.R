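# Hub-gene selection and drug-target annotation: degree ranking within the
# confidence-filtered interaction subnetwork induced on a gene list, then a
# join against a user-supplied (gene, drug, status) table.

#' Degree hubs of a gene list within an interaction network
#'
#' Filters the network to edges with confidence strictly greater than
#' `min_confidence`, induces the subnetwork on `genes` (or keeps the whole
#' network with `induced = FALSE`), and ranks the query genes by degree.
#'
#' @param genes character vector of query genes.
#' @param network an [interaction_network()].
#' @param min_confidence strict confidence threshold (default 0.7).
#' @param top_n hubs to keep (default 10); ties broken by gene ID.
#' @param induced compute degree on the induced subnetwork (default) or on
#'   the full filtered network.
#' @return A `HubTable` data frame: `gene`, `degree`, descending degree.
#' @export
degree_hubs <- function(genes, network, min_confidence = 0.7, top_n = 10,
                        induced = TRUE) {
  stopifnot(inherits(network, "InteractionNetwork"), top_n >= 1)
  ed <- network$edges[network$edges$confidence > min_confidence, ,
                      drop = FALSE]
  if (induced)
    ed <- ed[ed$source %in% genes & ed$target %in% genes, , drop = FALSE]
  if (!nrow(ed)) stop("induced subnetwork is empty")
  deg <- table(c(ed$source, ed$target))
  present <- intersect(genes, names(deg))
  if (!length(present)) stop("induced subnetwork is empty")
  out <- data.frame(gene = present,
                    degree = as.integer(deg[present]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  class(out) <- c("HubTable", "data.frame")
  out
}

#' Annotate hubs with candidate drugs
#'
#' Joins a `(gene, drug, status)` table onto the hub table, keeping at
#' most `max_per_gene` drugs per hub in stable input order.  Hubs without
#' any entry are annotated `"no data"`.
#'
#' @param hubs a [degree_hubs()] table.
#' @param drug_table data frame with columns `gene`, `drug` and optionally
#'   `status`.
#' @param max_per_gene drugs kept per hub (default 3).
#' @return The hub table with added `drugs` (comma-separated or
#'   `"no data"`) and `n_drugs` columns.
#' @export
map_drug_targets <- function(hubs, drug_table, max_per_gene = 3) {
  stopifnot(inherits(hubs, "data.frame"), max_per_gene >= 1)
  drug_table <- as.data.frame(drug_table, stringsAsFactors = FALSE)
  if (nrow(drug_table) &&
      !all(c("gene", "drug") %in% names(drug_table)))
    stop("drug table needs 'gene' and 'drug' columns")
  if (nrow(drug_table) &&
      (any(!nzchar(as.character(drug_table$gene))) ||
       any(!nzchar(as.character(drug_table$drug))))) {
    bad <- which(!nzchar(as.character(drug_table$gene)) |
                 !nzchar(as.character(drug_table$drug)))[1]
    stop("malformed drug table row ", bad, ": empty gene or drug")
  }
  drugs <- character(nrow(hubs)); nd <- integer(nrow(hubs))
  for (i in seq_len(nrow(hubs))) {
    hit <- if (nrow(drug_table))
      drug_table$drug[drug_table$gene == hubs$gene[i]] else character(0)
    hit <- utils::head(unique(hit), max_per_gene)
    nd[i] <- length(hit)
    drugs[i] <- if (length(hit)) paste(hit, collapse = ", ") else "no data"
  }
  hubs$drugs <- drugs
  hubs$n_drugs <- nd
  hubs
}

#' Read a drug-target table
#'
#' TSV with columns `gene`, `drug`, optional `status`.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_drug_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene", "drug") %in% names(tab)))
    stop("drug table needs 'gene' and 'drug' columns: ", path)
  tab
}
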