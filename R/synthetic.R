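# Synthetic cohorts with planted signal.  The generator states a world:
# log-normal expression with expression-dependent noise, a minority of
# differentially expressed genes with a fixed log2 shift, and a handful of
# "mediator" genes that are network hubs wired to the DEGs but carry almost
# no fold change themselves.  Recovery of those mediators by the path
# pipeline -- and their absence from DEG lists -- is the core validation.

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required for reproducibility")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults are a desk-scale version of a 64 vs 437 unbalanced tumour
#' cohort: 16 case and 48 control samples over 500 genes, 10% of genes
#' shifted by 2 log2 units (half up, half down), 5 planted mediators whose
#' own shift is bounded by `deg_noise`, and within-group noise whose sd
#' grows as baseline expression falls (so the loess expected-|log2FC| trend
#' is non-trivial).
#'
#' @param n_genes number of genes.
#' @param n_case,n_control samples per group (each >= 2).
#' @param baseline_range log2 baseline expression range (genes are uniform
#'   over it); the default spans 4 log2 units.
#' @param deg_fraction fraction of genes that are true DEGs.
#' @param deg_effect absolute case-mean shift of DEGs, log2 units.
#' @param mediator_count number of planted mediator genes.
#' @param deg_noise bound on the |shift| of mediator genes (log2 units).
#' @param noise_sd within-group log2 sd at the top of the baseline range;
#'   lower-expressed genes are up to twice as noisy.
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return A `SyntheticSpec` (validated list).
#' @export
synthetic_spec <- function(n_genes = 500, n_case = 16, n_control = 48,
                           baseline_range = c(4, 8), deg_fraction = 0.1,
                           deg_effect = 2, mediator_count = 5,
                           deg_noise = 0.1, noise_sd = 0.5, seed = 1) {
  stopifnot(n_genes >= 10, deg_fraction >= 0, deg_fraction <= 1,
            deg_effect >= 0, mediator_count >= 0, deg_noise >= 0,
            noise_sd >= 0, length(baseline_range) == 2,
            baseline_range[2] >= baseline_range[1])
  if (n_case < 2 || n_control < 2)
    stop("need >= 2 samples per group (fold-change baselines undefined)")
  n_deg <- round(deg_fraction * n_genes)
  if (n_deg + mediator_count > n_genes)
    stop("deg_fraction and mediator_count exceed n_genes")
  structure(list(n_genes = n_genes, n_case = n_case, n_control = n_control,
                 baseline_range = baseline_range, deg_fraction = deg_fraction,
                 deg_effect = deg_effect, mediator_count = mediator_count,
                 deg_noise = deg_noise, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic two-group expression cohort
#'
#' Expression of gene g in sample j is
#' `base_g + shift_g * 1[j is case] + N(0, sd_g)` on the log2 scale, with
#' `sd_g = noise_sd * (1 + (top - base_g) / span)` so low-expression genes
#' are noisier.  DEGs get `shift = +/- deg_effect` (half each); mediators
#' get a shift drawn uniformly from `[-deg_noise, deg_noise]`.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `expr` (an [expression_matrix()]) and `truth` (data
#'   frame: `gene`, `role` in mediator/deg/null, `shift`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed, {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    samples <- c(sprintf("case_%02d", seq_len(spec$n_case)),
                 sprintf("ctrl_%02d", seq_len(spec$n_control)))
    groups <- stats::setNames(rep(c("case", "control"),
                                  c(spec$n_case, spec$n_control)), samples)
    lo <- spec$baseline_range[1]; hi <- spec$baseline_range[2]
    base <- stats::runif(spec$n_genes, lo, hi)
    span <- max(hi - lo, 1e-9)
    sd_g <- spec$noise_sd * (1 + (hi - base) / span)

    n_deg <- round(spec$deg_fraction * spec$n_genes)
    roles <- rep("null", spec$n_genes)
    idx <- sample.int(spec$n_genes, n_deg + spec$mediator_count)
    deg_idx <- idx[seq_len(n_deg)]
    med_idx <- idx[seq_len(spec$mediator_count) + n_deg]
    roles[deg_idx] <- "deg"
    roles[med_idx] <- "mediator"
    shift <- numeric(spec$n_genes)
    if (n_deg) {
      n_up <- ceiling(n_deg / 2)
      shift[deg_idx] <- spec$deg_effect *
        rep(c(1, -1), c(n_up, n_deg - n_up))
    }
    if (spec$mediator_count)
      shift[med_idx] <- stats::runif(spec$mediator_count,
                                     -spec$deg_noise, spec$deg_noise)

    n <- length(samples)
    vals <- matrix(stats::rnorm(spec$n_genes * n, sd = rep(sd_g, n)),
                   nrow = spec$n_genes, ncol = n,
                   dimnames = list(genes, samples))
    vals <- vals + base
    is_case <- groups == "case"
    vals[, is_case] <- vals[, is_case] + shift

    list(expr = expression_matrix(vals, groups),
         truth = data.frame(gene = genes, role = roles, shift = shift,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a scale-free interaction network with mediator hubs
#'
#' A preferential-attachment backbone (`attach_m` edges per incoming node)
#' over all genes, plus dedicated wiring that makes each mediator a hub:
#' every mediator is connected to at least `wire_per_mediator` planted DEG
#' genes, so paths between differentially expressed genes tend to run
#' through mediators.
#'
#' @param genes character vector of gene IDs (network node set).
#' @param mediator_ids genes to wire as mediator hubs (subset of `genes`).
#' @param deg_ids planted DEG genes the mediators are wired to.
#' @param attach_m preferential-attachment edges per node (< number of
#'   genes).
#' @param wire_per_mediator DEG partners per mediator (>= 20 by default;
#'   capped at `length(deg_ids)`).
#' @param seed integer seed.
#' @return An [interaction_network()], confidence 1 throughout.
#' @export
generate_network <- function(genes, mediator_ids, deg_ids = character(0),
                             attach_m = 2, wire_per_mediator = 20,
                             seed = 1) {
  stopifnot(all(mediator_ids %in% genes), all(deg_ids %in% genes))
  n <- length(genes)
  if (attach_m >= n) stop("attach_m must be smaller than the gene count")
  with_seed(seed, {
    g <- igraph::sample_pa(n, m = attach_m, directed = FALSE)
    perm <- sample.int(n)  # decouple hub-ness of early PA nodes from gene order
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- data.frame(source = genes[perm[el[, 1]]],
                        target = genes[perm[el[, 2]]],
                        confidence = 1, stringsAsFactors = FALSE)
    if (length(mediator_ids) && length(deg_ids)) {
      k <- min(wire_per_mediator, length(deg_ids))
      extra <- do.call(rbind, lapply(mediator_ids, function(m)
        data.frame(source = m, target = sample(deg_ids, k),
                   confidence = 1, stringsAsFactors = FALSE)))
      edges <- rbind(edges, extra)
    }
    interaction_network(edges, directed = FALSE)
  })
}

#' Generate a synthetic cell x gene matrix with cell-type structure
#'
#' Counts are drawn from a negative binomial (over-dispersed) model with a
#' gene-specific baseline mean; marker genes have their mean multiplied by
#' `elevation` in their own cell type.  `elevation = 1` gives a null matrix
#' for calibration.
#'
#' @param n_cells_per_type named integer vector: cell type -> cell count
#'   (each >= 2).
#' @param genes character vector of gene IDs.
#' @param marker_sets named list (cell type -> marker genes); overlapping
#'   sets are allowed.  Names must be cell types.
#' @param elevation fold elevation of marker means in their own type
#'   (default 2).
#' @param base_mean mean count scale for background genes.
#' @param dispersion negative-binomial `size` parameter.
#' @param seed integer seed.
#' @return List with `counts` (cells x genes matrix, cell rownames),
#'   `labels` (named character vector cell -> type) and `markers` (the
#'   marker sets used).
#' @export
generate_single_cell <- function(n_cells_per_type, genes,
                                 marker_sets = list(), elevation = 2,
                                 base_mean = 20, dispersion = 4, seed = 1) {
  if (is.null(names(n_cells_per_type)) || any(!nzchar(names(n_cells_per_type))))
    stop("n_cells_per_type must be named by cell type")
  if (any(n_cells_per_type < 2)) stop("every cell type needs >= 2 cells")
  if (length(marker_sets)) {
    stopifnot(all(names(marker_sets) %in% names(n_cells_per_type)),
              all(unlist(marker_sets) %in% genes))
  }
  with_seed(seed, {
    types <- names(n_cells_per_type)
    labels <- rep(types, n_cells_per_type)
    cells <- sprintf("%s_c%03d", labels,
                     unlist(lapply(n_cells_per_type, seq_len)))
    names(labels) <- cells
    mu_gene <- stats::setNames(stats::rlnorm(length(genes),
                                             log(base_mean), 0.4), genes)
    counts <- matrix(0L, nrow = length(cells), ncol = length(genes),
                     dimnames = list(cells, genes))
    for (ty in types) {
      mu <- mu_gene
      mk <- marker_sets[[ty]]
      if (length(mk)) mu[mk] <- mu[mk] * elevation
      rows <- which(labels == ty)
      counts[rows, ] <- matrix(
        stats::rnbinom(length(rows) * length(genes), size = dispersion,
                       mu = rep(mu, each = length(rows))),
        nrow = length(rows))
    }
    list(counts = counts, labels = labels, markers = marker_sets)
  })
}
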