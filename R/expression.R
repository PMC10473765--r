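# Region-by-gene expression matrices are plain numeric matrices with
# regions in rows (rownames = canonical region keys) and genes in columns,
# carrying 'species' and 'zscored' attributes.

#' @keywords internal
#' @noRd
new_region_gene_matrix <- function(values, species, zscored = FALSE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite cells", call. = FALSE)
  structure(values, species = species, zscored = zscored,
            class = c("region_gene_matrix", class(values)))
}

#' @export
print.region_gene_matrix <- function(x, ...) {
  cat(sprintf("Region-by-gene expression matrix (%s): %d regions x %d genes%s\n",
              attr(x, "species"), nrow(x), ncol(x),
              if (isTRUE(attr(x, "zscored"))) ", z-scored across regions" else ""))
  invisible(x)
}

#' Aggregate sample-level expression into a region-by-gene matrix
#'
#' Collapses a sample-by-gene (or voxel-by-gene) expression matrix to one
#' row per region. Human microarray samples are combined by volume-weighted
#' averaging (samples from larger constituent structures contribute more);
#' mouse voxel data use uniform weights, i.e. a plain mean.
#'
#' @param samples Numeric matrix, samples x genes, with gene column names.
#' @param assignment Character vector (length `nrow(samples)`) assigning
#'   each sample to a region key.
#' @param weights Optional non-negative per-sample weights; `NULL` =
#'   uniform. Within each region the weights must not all be zero.
#' @param species `"human"` or `"mouse"` tag carried on the result.
#' @param regions Optional character vector of region keys that must all be
#'   represented; regions with no samples raise an error naming them.
#' @return A `region_gene_matrix` (regions x genes).
#' @export
aggregate_expression_by_region <- function(samples, assignment,
                                           weights = NULL,
                                           species = "human",
                                           regions = NULL) {
  samples <- as.matrix(samples)
  if (length(assignment) != nrow(samples))
    stop("'assignment' must have one entry per sample row", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(samples))
  if (length(weights) != nrow(samples) || any(weights < 0))
    stop("'weights' must be non-negative, one per sample", call. = FALSE)
  if (!is.null(regions)) {
    empty <- setdiff(regions, unique(assignment))
    if (length(empty) > 0)
      stop("region(s) with no samples: ", paste(empty, collapse = ", "),
           call. = FALSE)
  }
  keys <- if (is.null(regions)) sort(unique(assignment)) else regions
  out <- matrix(NA_real_, length(keys), ncol(samples),
                dimnames = list(keys, colnames(samples)))
  for (k in keys) {
    idx <- which(assignment == k)
    w <- weights[idx]
    if (sum(w) == 0)
      stop("all weights zero within region '", k, "'", call. = FALSE)
    out[k, ] <- colSums(samples[idx, , drop = FALSE] * w) / sum(w)
  }
  new_region_gene_matrix(out, species = species)
}

#' Fill missing right-hemisphere regions by reflecting the left
#'
#' Expression atlases sometimes lack samples for some right-hemisphere
#' structures; their rows are filled with the homotopic left-hemisphere
#' profile. The keys that were filled are recorded in the `reflected`
#' attribute.
#'
#' @param matrix A `region_gene_matrix`.
#' @param map A `homologous_region_map` defining the full region set.
#' @param donor_side Side donating data; only `"left"` is meaningful.
#' @return The matrix with all mapped right-hemisphere rows present.
#' @export
reflect_hemisphere <- function(matrix, map = load_homologous_regions(),
                               donor_side = "left") {
  donor_side <- match.arg(donor_side, "left")
  if ("expression_available" %in% names(map))
    map <- map[map$expression_available, , drop = FALSE]
  right <- map[map$hemisphere == "right", , drop = FALSE]
  missing_keys <- setdiff(right$key, rownames(matrix))
  if (length(missing_keys) == 0L) return(matrix)
  filled <- matrix
  for (k in missing_keys) {
    region <- right$region[right$key == k]
    donor <- region_key(region, donor_side)
    if (!donor %in% rownames(filled))
      stop("cannot reflect '", k, "': no ", donor_side,
           " counterpart '", donor, "' present", call. = FALSE)
    filled <- rbind(filled, filled[donor, , drop = FALSE])
    rownames(filled)[nrow(filled)] <- k
  }
  out <- new_region_gene_matrix(unclass(filled),
                                species = attr(matrix, "species"),
                                zscored = attr(matrix, "zscored"))
  attr(out, "reflected") <- missing_keys
  out
}

#' Restrict two species' matrices to homologous genes
#'
#' Intersects both matrices with a homologous-gene map (one-to-one pairs of
#' human and mouse gene symbols) and reorders columns so that column j of
#' the human matrix is the homolog of column j of the mouse matrix.
#'
#' @param human,mouse `region_gene_matrix` objects.
#' @param map Data frame with columns `human` and `mouse` (gene symbols);
#'   pairs must be one-to-one.
#' @return List with elements `human`, `mouse` (aligned matrices) and
#'   `map` (the retained pairs).
#' @export
intersect_homologous_genes <- function(human, mouse, map) {
  if (!all(c("human", "mouse") %in% names(map)))
    stop("homolog map needs 'human' and 'mouse' columns", call. = FALSE)
  if (anyDuplicated(map$human) || anyDuplicated(map$mouse))
    stop("homolog map must be one-to-one", call. = FALSE)
  keep <- map$human %in% colnames(human) & map$mouse %in% colnames(mouse)
  if (!any(keep))
    stop("empty homologous-gene intersection", call. = FALSE)
  kept <- map[keep, , drop = FALSE]
  h <- new_region_gene_matrix(unclass(human)[, kept$human, drop = FALSE],
                              attr(human, "species"), attr(human, "zscored"))
  m <- new_region_gene_matrix(unclass(mouse)[, kept$mouse, drop = FALSE],
                              attr(mouse, "species"), attr(mouse, "zscored"))
  list(human = h, mouse = m, map = kept)
}

#' Z-score each gene across brain regions
#'
#' Per gene column: subtract the mean over regions and divide by the SD
#' over regions, putting all genes on a comparable scale. Genes constant
#' across regions are dropped (their count is recorded in the `n_dropped`
#' attribute).
#'
#' @param matrix A `region_gene_matrix` with at least 3 regions.
#' @return The z-scored matrix (`zscored` attribute set).
#' @export
zscore_genes_across_regions <- function(matrix) {
  if (nrow(matrix) < 3L)
    stop("need at least 3 regions to z-score across regions", call. = FALSE)
  vals <- unclass(matrix)
  sds <- apply(vals, 2, stats::sd)
  constant <- sds == 0
  if (all(constant))
    stop("all genes are constant across regions", call. = FALSE)
  vals <- scale(vals[, !constant, drop = FALSE])
  attr(vals, "scaled:center") <- NULL
  attr(vals, "scaled:scale") <- NULL
  out <- new_region_gene_matrix(vals, attr(matrix, "species"),
                                zscored = TRUE)
  attr(out, "n_dropped") <- sum(constant)
  if (sum(constant) > 0)
    message(sum(constant), " constant gene(s) dropped before z-scoring")
  out
}

# Row-wise Pearson correlation between corresponding rows of two matrices.
#' @keywords internal
#' @noRd
row_cor <- function(a, b) {
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  rowSums(ac * bc) / sqrt(rowSums(ac^2) * rowSums(bc^2))
}

#' Per-region cross-species transcriptional similarity
#'
#' For each region shared by the two z-scored matrices, the Pearson
#' correlation between the human and mouse expression profiles across
#' homologous genes (optionally a named subset).
#'
#' @param human_z,mouse_z Z-scored `region_gene_matrix` objects with
#'   identical gene order (see [intersect_homologous_genes()]) and the same
#'   region set.
#' @param genes Optional character vector (human gene symbols) or column
#'   indices selecting a gene subset; minimum size 3.
#' @return Data frame with columns `key`, `transcriptional`, `n_genes`.
#' @export
transcriptional_similarity <- function(human_z, mouse_z, genes = NULL) {
  if (!isTRUE(attr(human_z, "zscored")) || !isTRUE(attr(mouse_z, "zscored")))
    stop("both matrices must be z-scored across regions", call. = FALSE)
  if (ncol(human_z) != ncol(mouse_z))
    stop("matrices must have the same (aligned) gene set", call. = FALSE)
  keys <- intersect(rownames(human_z), rownames(mouse_z))
  if (length(keys) == 0L)
    stop("no shared regions between the matrices", call. = FALSE)
  h <- unclass(human_z)[keys, , drop = FALSE]
  m <- unclass(mouse_z)[keys, , drop = FALSE]
  if (!is.null(genes)) {
    if (is.character(genes)) {
      bad <- setdiff(genes, colnames(h))
      if (length(bad) > 0)
        stop("subset gene(s) not in matrix: ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    h <- h[, genes, drop = FALSE]
    m <- m[, genes, drop = FALSE]
  }
  if (ncol(h) < 3L)
    stop("gene subset must contain at least 3 genes", call. = FALSE)
  data.frame(key = keys, transcriptional = unname(row_cor(h, m)),
             n_genes = ncol(h), stringsAsFactors = FALSE)
}

#' Attach transcriptional similarity to anatomical similarity scores
#'
#' Fills the `transcriptional` column of a [anatomical_similarity_scores()]
#' table by region key; regions without expression data keep `NA`.
#'
#' @param scores A `similarity_scores` data frame.
#' @inheritParams transcriptional_similarity
#' @return The scores table with `transcriptional` filled where available.
#' @export
add_transcriptional_similarity <- function(scores, human_z, mouse_z,
                                           genes = NULL) {
  ts <- transcriptional_similarity(human_z, mouse_z, genes)
  idx <- match(scores$key, ts$key)
  scores$transcriptional <- ts$transcriptional[idx]
  scores
}

#' Correlation between anatomical and transcriptional similarity
#'
#' Percentage-bend correlation, across regions, of the anatomical
#' sex-effect similarity score against the transcriptional similarity
#' score - the test of whether regions with more conserved volumetric sex
#' differences also have more conserved expression profiles.
#'
#' @param scores A `similarity_scores` data frame with both columns filled
#'   (regions with `NA` transcriptional scores are dropped).
#' @param compartment `"all"`, `"cortical"`, or `"non_cortical"`.
#' @param bend_constant Bending proportion, default 0.2.
#' @return A `cor_result`.
#' @export
similarity_vs_expression_correlation <- function(scores, compartment = "all",
                                                 bend_constant = 0.2) {
  sub <- filter_compartment(scores, compartment)
  sub <- sub[is.finite(sub$transcriptional), , drop = FALSE]
  if (nrow(sub) < 4L)
    stop("insufficient data: fewer than 4 regions with both scores",
         call. = FALSE)
  percentage_bend_correlation(sub$anatomical, sub$transcriptional,
                              bend_constant)
}

#' Gene-subset permutation null for the similarity correlation
#'
#' Tests whether the anatomical-transcriptional similarity correlation
#' obtained with a biologically defined gene subset (e.g. X-linked or sex
#' hormone signaling genes) differs from what same-sized random subsets of
#' the homologous gene universe produce. Each resample draws `length(genes)`
#' genes uniformly without replacement, recomputes the per-region
#' transcriptional similarity, and re-correlates it with the anatomical
#' scores.
#'
#' @param human_z,mouse_z Aligned z-scored `region_gene_matrix` objects.
#' @param scores A `similarity_scores` data frame (anatomical column used).
#' @param genes Character vector: the observed gene subset (human symbols).
#' @param n_resamples Number of random subsets, default 10000.
#' @param seed Integer seed controlling the draws.
#' @param compartment `"all"`, `"cortical"`, or `"non_cortical"`.
#' @param bend_constant Bending proportion for the score correlation.
#' @param direction Tail for the permutation p-value, default two-sided.
#' @return A list of class `null_distribution`: `values`, `observed`, `p`,
#'   `n_resamples`, `seed`, `subset_size`.
#' @export
gene_subset_null <- function(human_z, mouse_z, scores, genes,
                             n_resamples = 10000, seed = 1,
                             compartment = "all", bend_constant = 0.2,
                             direction = "two_sided") {
  if (n_resamples < 1L)
    stop("'n_resamples' must be at least 1", call. = FALSE)
  universe <- colnames(human_z)
  m <- length(genes)
  if (m > length(universe))
    stop("subset size exceeds the gene universe", call. = FALSE)
  sub <- filter_compartment(scores, compartment)
  keys <- intersect(sub$key, intersect(rownames(human_z), rownames(mouse_z)))
  anat <- sub$anatomical[match(keys, sub$key)]
  h <- unclass(human_z)[keys, , drop = FALSE]
  mz <- unclass(mouse_z)[keys, , drop = FALSE]
  stat_for <- function(cols) {
    ts <- row_cor(h[, cols, drop = FALSE], mz[, cols, drop = FALSE])
    percentage_bend_correlation(anat, ts, bend_constant)$r
  }
  observed <- stat_for(genes)
  values <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i)
      stat_for(sample(universe, m)), numeric(1))
  })
  structure(
    list(values = values, observed = observed,
         p = permutation_p_value(observed, values, direction),
         n_resamples = n_resamples, seed = seed, subset_size = m,
         direction = direction),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Gene-subset permutation null: %d resamples of size %d (seed %d)\n",
              x$n_resamples, x$subset_size, x$seed))
  cat(sprintf("  observed r = %.4f, null mean = %.4f, p (%s) = %.4g\n",
              x$observed, mean(x$values), x$direction, x$p))
  invisible(x)
}

#' @export
plot.null_distribution <- function(x, ...) {
  graphics::hist(x$values, breaks = 40, col = "grey80", border = "white",
                 main = "Gene-subset null distribution",
                 xlab = "correlation", ...)
  graphics::abline(v = x$observed, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Read a newline-delimited gene list
#'
#' @param path Text file with one gene symbol per line; blank lines and
#'   `#` comments are skipped.
#' @return Character vector of symbols.
#' @export
read_gene_subset <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
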