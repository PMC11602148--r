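## Pseudobulk accessibility trajectories across the NSC -> IPC -> PN1 ->
## PN2 -> PN3 neurogenic axis: aggregation, log2-CPM normalization,
## ANOVA-based invariance, binary trajectory templates and Pearson calls.

CELL_TYPES <- c("NSC", "IPC", "PN1", "PN2", "PN3")

#' PseudobulkMatrix: regions x pseudotime-ordered pseudobulk accessibility
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] whose
#' columns are pseudobulk samples ordered by pseudotime rank, each labelled
#' with a cell type, and whose single assay holds non-negative counts or
#' log2-CPM values (tagged in the metadata).
#'
#' @slot .Data see `SummarizedExperiment`; colData requires `cell_type` and
#'   `pseudotime_rank`; `metadata(x)$values` is "counts" or "log2cpm";
#'   a normalized object records `metadata(x)$pseudocount`.
#' @export
setClass("PseudobulkMatrix", contains = "SummarizedExperiment")

setValidity("PseudobulkMatrix", function(object) {
  cd <- colData(object)
  if (!all(c("cell_type", "pseudotime_rank") %in% colnames(cd)))
    return("colData must have 'cell_type' and 'pseudotime_rank'")
  if (is.unsorted(cd$pseudotime_rank))
    return("samples must be ordered by pseudotime_rank")
  if (!identical(S4Vectors::metadata(object)$values %in% c("counts", "log2cpm"), TRUE))
    return("metadata 'values' must be 'counts' or 'log2cpm'")
  if (S4Vectors::metadata(object)$values == "counts" &&
      any(assay(object) < 0))
    return("counts must be non-negative")
  TRUE
})

#' Construct a PseudobulkMatrix
#'
#' @param values Numeric matrix, regions x samples.
#' @param cell_type Character vector of per-sample cell-type labels.
#' @param pseudotime_rank Integer ranks ordering the samples (default 1..n).
#' @param kind "counts" or "log2cpm".
#' @param pseudocount Pseudocount used if `kind = "log2cpm"`.
#' @return A [PseudobulkMatrix-class] object.
#' @export
PseudobulkMatrix <- function(values, cell_type,
                             pseudotime_rank = seq_len(ncol(values)),
                             kind = c("counts", "log2cpm"), pseudocount = NA) {
  kind <- match.arg(kind)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("pb", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("region_", seq_len(nrow(values)))
  se <- SummarizedExperiment(
    assays = list(values = values),
    colData = DataFrame(cell_type = cell_type,
                        pseudotime_rank = as.integer(pseudotime_rank)))
  S4Vectors::metadata(se)$values <- kind
  S4Vectors::metadata(se)$pseudocount <- pseudocount
  new("PseudobulkMatrix", se)
}

setMethod("show", "PseudobulkMatrix", function(object) {
  cat("PseudobulkMatrix:", nrow(object), "regions x", ncol(object),
      "pseudobulks (", S4Vectors::metadata(object)$values, ")\n")
  tab <- table(factor(colData(object)$cell_type,
                      levels = unique(colData(object)$cell_type)))
  cat("  samples per cell type:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

#' Cell-type labels of pseudobulk samples
#' @param x A `PseudobulkMatrix`.
#' @return Character vector.
#' @export
cellTypes <- function(x) as.character(colData(x)$cell_type)

#' Aggregate single cells into pseudotime-ordered pseudobulks
#'
#' Within each cell type (in its order along the axis), cells are sorted by
#' pseudotime and summed in consecutive blocks of `group_size`.  A trailing
#' remainder forms its own group only if it holds at least half of
#' `group_size`; otherwise it is merged into the previous block.  A cell type
#' with fewer cells than one group contributes a single group, with a
#' warning.
#'
#' @param cell_counts Matrix, regions x cells.
#' @param cell_type Per-cell labels.
#' @param pseudotime Per-cell pseudotime values.
#' @param group_size Cells per pseudobulk (study default 175).
#' @param type_order Order of cell types along the axis.
#' @return A [PseudobulkMatrix-class] of summed counts.
#' @export
pseudobulkAggregate <- function(cell_counts, cell_type, pseudotime,
                                group_size = 175L,
                                type_order = CELL_TYPES) {
  stopifnot(group_size >= 1L, ncol(cell_counts) == length(cell_type),
            length(cell_type) == length(pseudotime))
  type_order <- intersect(type_order, unique(cell_type))
  blocks <- list(); labels <- character(0)
  for (ct in type_order) {
    idx <- which(cell_type == ct)
    idx <- idx[order(pseudotime[idx])]
    n <- length(idx)
    if (n < group_size)
      warning("cell type ", ct, " has fewer cells (", n,
              ") than one group; contributing a single group")
    ng <- max(1L, n %/% group_size)
    rem <- n - ng * group_size
    sizes <- rep(group_size, ng)
    if (ng == 1L && n < group_size) sizes <- n
    if (rem > 0) {
      if (rem >= group_size / 2) sizes <- c(sizes, rem)
      else sizes[length(sizes)] <- sizes[length(sizes)] + rem
    }
    off <- 0L
    for (s in sizes) {
      blocks[[length(blocks) + 1L]] <- idx[(off + 1L):(off + s)]
      labels <- c(labels, ct)
      off <- off + s
    }
  }
  vals <- vapply(blocks, function(i) rowSums(cell_counts[, i, drop = FALSE]),
                 numeric(nrow(cell_counts)))
  if (nrow(cell_counts) == 1L) vals <- matrix(vals, nrow = 1L)
  rownames(vals) <- rownames(cell_counts)
  PseudobulkMatrix(vals, cell_type = labels, kind = "counts")
}

#' log2 counts-per-million normalization
#'
#' `log2(count / column_sum * 1e6 + pseudocount)`; the pseudocount is
#' recorded in the object metadata.
#'
#' @param x A counts `PseudobulkMatrix` or plain matrix.
#' @param pseudocount Added inside the log (default 1).
#' @return Normalized object of the same shape.
#' @export
log2CPM <- function(x, pseudocount = 1) {
  m <- if (is(x, "PseudobulkMatrix")) assay(x) else x
  cs <- colSums(m)
  if (any(cs <= 0))
    stop("zero column sum in sample(s): ",
         paste(colnames(m)[cs <= 0], collapse = ", "))
  norm <- log2(sweep(m, 2, cs, "/") * 1e6 + pseudocount)
  if (is(x, "PseudobulkMatrix"))
    PseudobulkMatrix(norm, cell_type = cellTypes(x),
                     pseudotime_rank = colData(x)$pseudotime_rank,
                     kind = "log2cpm", pseudocount = pseudocount)
  else norm
}

#' Per-region one-way ANOVA across cell types
#'
#' Classical (equal-variance) one-way ANOVA of each region's normalized
#' accessibility grouped by cell type.  Regions with p >= `threshold` are
#' invariant; regions with zero variance everywhere are invariant by
#' convention.
#'
#' @param x A `PseudobulkMatrix` (log2-CPM recommended) or matrix.
#' @param cell_type Group labels (taken from `x` if a `PseudobulkMatrix`).
#' @param threshold Invariance p-value threshold (study value 1e-6).
#' @return `data.frame` with `F`, `p`, `invariant` per region.
#' @export
anovaInvariant <- function(x, cell_type = NULL, threshold = 1e-6) {
  m <- if (is(x, "PseudobulkMatrix")) assay(x) else x
  if (is.null(cell_type) && is(x, "PseudobulkMatrix")) cell_type <- cellTypes(x)
  g <- factor(cell_type)
  stopifnot(nlevels(g) >= 2L)
  res <- apply(m, 1, function(v) {
    if (sd(v) == 0) return(c(NA_real_, 1))
    fit <- tryCatch(oneway.test(v ~ g, var.equal = TRUE),
                    error = function(e) NULL)
    if (is.null(fit) || is.na(fit$p.value)) c(NA_real_, 1)
    else c(unname(fit$statistic), fit$p.value)
  })
  data.frame(F = res[1, ], p = res[2, ], invariant = res[2, ] >= threshold,
             row.names = rownames(m))
}

#' Binary trajectory templates for a pseudobulk layout
#'
#' Enumerates every binary vector with a single contiguous run of 1s whose
#' boundaries fall on cell-type block boundaries, excluding all-0 and all-1.
#' A run starting at the first sample is "falling", one ending at the last
#' sample is "neuronal", and an internal run is "transient".
#'
#' @param cell_type Per-sample cell-type labels in pseudotime order.
#' @return `data.frame` with `name`, `group`, `vector` (as a character of
#'   0/1) plus a `template` matrix attribute (`templateMatrix()`).
#' @export
buildTemplates <- function(cell_type) {
  r <- rle(as.character(cell_type))
  bounds <- c(0L, cumsum(r$lengths))        # block boundaries, 0-based
  n <- sum(r$lengths)
  K <- length(r$lengths)
  out <- list()
  for (i in seq_len(K)) {
    for (j in i:K) {
      if (i == 1L && j == K) next          # all-1
      v <- integer(n)
      v[(bounds[i] + 1L):bounds[j + 1L]] <- 1L
      group <- if (i == 1L) "falling" else if (j == K) "neuronal" else "transient"
      nm <- paste0(r$values[i], if (j > i) paste0("-", r$values[j]) else "")
      out[[length(out) + 1L]] <- list(name = nm, group = group, v = v)
    }
  }
  vecs <- do.call(rbind, lapply(out, `[[`, "v"))
  df <- data.frame(
    name = make.unique(vapply(out, `[[`, "", "name")),
    group = vapply(out, `[[`, "", "group"),
    vector = apply(vecs, 1, paste, collapse = ""),
    stringsAsFactors = FALSE)
  attr(df, "template") <- vecs
  df
}

#' Template 0/1 matrix from [buildTemplates] output
#' @param templates Result of [buildTemplates].
#' @return Integer matrix, templates x samples.
#' @export
templateMatrix <- function(templates) attr(templates, "template")

#' Assign accessibility trajectories to regions
#'
#' A region flagged invariant by the ANOVA (or with a zero-variance vector)
#' is labelled "invariant"; otherwise it takes the group of the template
#' whose binary vector has the highest Pearson correlation with its
#' accessibility vector (ties broken by template enumeration order).
#'
#' @param x `PseudobulkMatrix` (normalized) or matrix.
#' @param templates From [buildTemplates] (built from `x` if NULL).
#' @param anova From [anovaInvariant] (computed from `x` if NULL).
#' @param threshold Passed to [anovaInvariant] when computed here.
#' @return `data.frame` with `label`, `best_template`, `pearson_r`,
#'   `anova_p` per region.
#' @export
assignTrajectories <- function(x, templates = NULL, anova = NULL,
                               threshold = 1e-6) {
  m <- if (is(x, "PseudobulkMatrix")) assay(x) else x
  if (is.null(templates)) templates <- buildTemplates(cellTypes(x))
  if (is.null(anova)) anova <- anovaInvariant(x, threshold = threshold)
  tm <- templateMatrix(templates)
  stopifnot(ncol(tm) == ncol(m))
  tT <- t(tm)
  n <- nrow(m)
  label <- character(n); best <- rep(NA_character_, n); rbest <- rep(NA_real_, n)
  rvec <- apply(m, 1, sd)
  cors <- suppressWarnings(cor(t(m), tT))    # regions x templates
  for (i in seq_len(n)) {
    if (anova$invariant[i] || rvec[i] == 0) {
      label[i] <- "invariant"
    } else {
      k <- which.max(cors[i, ])
      label[i] <- templates$group[k]
      best[i] <- templates$name[k]
      rbest[i] <- cors[i, k]
    }
  }
  data.frame(label = label, best_template = best, pearson_r = rbest,
             anova_p = anova$p, row.names = rownames(m))
}

#' Correlate TF expression with region accessibility over pseudobulk groups
#'
#' Cells are sorted by expression and pooled into consecutive groups of
#' `group_size` (study value 50); per group the mean expression and mean
#' accessibility are computed and the per-region Pearson correlation across
#' groups is returned.
#'
#' @param expression Per-cell expression values.
#' @param cell_access Matrix, regions x cells.
#' @param group_size Cells per group.
#' @return Numeric vector of per-region correlations.
#' @export
exprAccessCorrelation <- function(expression, cell_access, group_size = 50L) {
  stopifnot(length(expression) == ncol(cell_access))
  ord <- order(expression)
  n <- length(ord)
  ng <- n %/% group_size
  if (ng < 2L) stop("fewer than 2 groups of size ", group_size)
  grp <- rep(seq_len(ng), each = group_size)
  rem <- n - ng * group_size
  if (rem > 0) {
    grp <- c(grp, rep(if (rem >= group_size / 2) ng + 1L else ng, rem))
  }
  idx <- ord
  me <- tapply(expression[idx], grp, mean)
  ma <- t(apply(cell_access[, idx, drop = FALSE], 1,
                function(v) tapply(v, grp, mean)))
  if (nrow(cell_access) == 1L) ma <- matrix(ma, nrow = 1L)
  as.numeric(suppressWarnings(cor(t(ma), as.numeric(me))))
}

#' Bound fraction across score quantile bins
#'
#' Regions are rank-sorted by score into `n_bins` equal-size bins; for each
#' bound set, the fraction of regions per bin overlapping it is reported,
#' with the top/bottom fold change (Inf when the bottom bin fraction is 0).
#'
#' @param regions `GRanges` of regions.
#' @param score Per-region scores (sorting key).
#' @param bound_sets Named list of `GRanges` of bound peaks.
#' @param n_bins Number of quantile bins (study value 50).
#' @return List with `fractions` (bins x sets matrix, bin 1 = lowest score)
#'   and `fold` (top bin / bottom bin per set).
#' @export
quantileOccupancy <- function(regions, score, bound_sets, n_bins = 50L) {
  stopifnot(n_bins >= 2L, length(score) == length(regions))
  ord <- order(score)
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bin <- pmin(bin, n_bins)
  frac <- sapply(bound_sets, function(bs) {
    hit <- overlapsAny(regions[ord], bs)
    tapply(hit, bin, mean)
  })
  frac <- matrix(frac, nrow = n_bins,
                 dimnames = list(NULL, names(bound_sets)))
  fold <- frac[n_bins, ] / frac[1L, ]
  list(fractions = frac, fold = fold)
}

#' Is a region accessible in a cell cluster?
#'
#' TRUE iff at least 3% (by default) of the cluster's cells have a non-zero
#' count for the region.
#'
#' @param counts Per-cell counts for the region (vector) or regions x cells
#'   matrix.
#' @param min_fraction Minimum fraction of cells with >= 1 count.
#' @return Logical (vector if `counts` is a matrix).
#' @export
accessibleInCluster <- function(counts, min_fraction = 0.03) {
  if (is.matrix(counts)) return(rowMeans(counts >= 1) >= min_fraction)
  mean(counts >= 1) >= min_fraction
}
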