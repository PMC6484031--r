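#' Filter sparse OTUs by total observation count
#'
#' Retains OTUs whose total count across all samples of the table is at
#' least `min_total` (boundary inclusive). The sample set is unchanged.
#'
#' @param table an `otu_table`.
#' @param min_total minimum total observation count (default 1200).
#' @return filtered `otu_table`.
#' @export
filter_otus <- function(table, min_total = 1200L) {
  stopifnot(inherits(table, "otu_table"), min_total >= 0)
  totals <- colSums(table$counts)
  keep <- totals >= min_total
  if (!any(keep)) warning("no OTUs pass the abundance filter")
  new_otu_table(table$counts[, keep, drop = FALSE], table$meta)
}

#' Rarefy an OTU table to a common depth
#'
#' Each sample's reads are subsampled uniformly without replacement
#' (multivariate hypergeometric) to exactly `depth` counts. Samples whose
#' total is below `depth` are dropped with a message; samples already at
#' `depth` are returned unchanged.
#'
#' @param table an `otu_table`.
#' @param depth target depth (default 10000).
#' @param seed RNG seed for the subsampling.
#' @return rarefied `otu_table`.
#' @export
rarefy <- function(table, depth = 10000L, seed = 1L) {
  stopifnot(inherits(table, "otu_table"), depth >= 1)
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  if (any(!keep))
    message(sum(!keep), " sample(s) below depth ", depth, " dropped")
  counts <- table$counts[keep, , drop = FALSE]
  totals <- totals[keep]
  # subsample in OTU-id order so the draw is invariant to column relabeling
  ord <- if (is.null(colnames(counts))) seq_len(ncol(counts)) else
    order(colnames(counts))
  inv <- order(ord)
  with_seed(seed, {
    for (i in seq_len(nrow(counts))) {
      if (totals[i] == depth) next
      x <- counts[i, ord]
      # draw `depth` reads without replacement from the sample's read pool
      picked <- sample.int(totals[i], depth)
      cum <- cumsum(x)
      counts[i, ] <- tabulate(findInterval(picked - 1L, c(0L, cum)),
                              nbins = length(x))[inv]
    }
  })
  new_otu_table(counts, table$meta[keep, , drop = FALSE])
}

#' Convert counts to relative abundances
#'
#' @param table an `otu_table`.
#' @return numeric matrix of per-sample compositions (rows sum to 1).
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  totals <- rowSums(table$counts)
  if (any(totals == 0)) stop("zero-total sample(s): ",
                             paste(rownames(table$counts)[totals == 0],
                                   collapse = ", "))
  sweep(table$counts, 1L, totals, "/")
}

#' Build the centered and scaled OTU design matrix W
#'
#' Column means and standard deviations are computed on the `reference`
#' samples only (the training fold in cross-validation use) and applied to
#' all samples, so no information leaks from test to train. Columns that are
#' constant on the reference are flagged and mapped to zero.
#'
#' @param table an `otu_table`.
#' @param reference character vector of sample ids defining the reference
#'   subset; default all samples.
#' @return list: `W` (samples x OTUs), `center`, `scale`, `zero_variance`
#'   (logical per OTU).
#' @export
build_W <- function(table, reference = NULL) {
  stopifnot(inherits(table, "otu_table"))
  ids <- rownames(table$counts)
  reference <- reference %||% ids
  ref_idx <- match(reference, ids)
  if (length(ref_idx) == 0L || anyNA(ref_idx))
    stop("reference must be a nonempty subset of the table's samples")
  ref <- table$counts[ref_idx, , drop = FALSE]
  ctr <- colMeans(ref)
  scl <- apply(ref, 2L, stats::sd)
  zero_var <- !is.finite(scl) | scl == 0
  scl[zero_var] <- 1
  W <- sweep(sweep(table$counts + 0, 2L, ctr, "-"), 2L, scl, "/")
  W[, zero_var] <- 0
  list(W = W, center = ctr, scale = scl, zero_variance = zero_var)
}

#' Good's coverage estimate per sample
#'
#' `1 - singletons / total reads`, where singletons are OTUs observed exactly
#' once in the sample.
#'
#' @param table an `otu_table`.
#' @return named numeric vector of coverages in \[0, 1\].
#' @export
goods_coverage <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  totals <- rowSums(table$counts)
  if (any(totals == 0)) stop("zero-total sample(s)")
  singletons <- rowSums(table$counts == 1L)
  stats::setNames(1 - singletons / totals, rownames(table$counts))
}
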