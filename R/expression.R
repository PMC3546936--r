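#' Relative expression from stem-loop RT-PCR Ct values
#'
#' Per replicate and tissue, the relative expression of a miRNA is
#' `2^-(Ct_miRNA - Ct_reference)` with the 5S rRNA rows as the reference;
#' the matrix entry is the mean over replicates (per-reaction
#' normalization; set `aggregate = "mean_dct"` to average `dCt` before
#' exponentiating instead).
#'
#' @param ct data.frame `mirna`, `tissue`, `replicate`, `ct` (all Ct > 0),
#'   containing reference rows keyed by `reference`
#' @param reference the normalizer's `mirna` key
#' @param aggregate replicate aggregation convention
#' @return numeric matrix, miRNAs x tissues, all entries > 0
#' @export
relative_expression <- function(ct, reference = "5S_rRNA",
                                aggregate = c("mean_expr", "mean_dct")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("mirna", "tissue", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("all Ct values must be positive")
  refrows <- ct[ct$mirna == reference, , drop = FALSE]
  x <- ct[ct$mirna != reference, , drop = FALSE]
  key <- function(d) paste(d$tissue, d$replicate, sep = "\r")
  ref_ct <- setNames(refrows$ct, key(refrows))
  r <- ref_ct[key(x)]
  if (anyNA(r)) {
    i <- which(is.na(r))[1L]
    stop(sprintf("missing %s Ct for tissue '%s' replicate %s",
                 reference, x$tissue[i], x$replicate[i]))
  }
  x$dct <- x$ct - as.numeric(r)
  mirnas <- unique(x$mirna); tissues <- unique(x$tissue)
  out <- matrix(NA_real_, length(mirnas), length(tissues),
                dimnames = list(mirnas, tissues))
  for (d in split(x, list(x$mirna, x$tissue), drop = TRUE)) {
    v <- if (aggregate == "mean_expr") mean(2^(-d$dct)) else 2^(-mean(d$dct))
    out[d$mirna[1L], d$tissue[1L]] <- v
  }
  if (anyNA(out)) stop("missing (mirna, tissue) combinations in the Ct table")
  out
}

#' Hierarchically cluster an expression matrix
#'
#' Average-linkage agglomeration on `1 - Pearson correlation` of log2
#' expression (Euclidean distance available as an option). Rows are sorted
#' by label before clustering so the result is invariant to input order;
#' constant rows, whose correlation is undefined, get distance 1 to
#' everything with a warning.
#'
#' @param mat expression matrix from [relative_expression()]
#' @param axis cluster miRNAs (rows) or tissues (columns)
#' @param method linkage passed to [stats::hclust()]
#' @param distance `"correlation"` (1 - Pearson on log2 values) or
#'   `"euclidean"` (on log2 values)
#' @return an `hclust` object
#' @export
cluster_expression <- function(mat, axis = c("mirna", "tissue"),
                               method = "average",
                               distance = c("correlation", "euclidean")) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  x <- if (axis == "tissue") t(mat) else mat
  if (nrow(x) < 2L) stop("need at least two items to cluster")
  x <- log2(x[order(rownames(x)), , drop = FALSE])
  if (distance == "correlation") {
    sds <- apply(x, 1L, stats::sd)
    cc <- suppressWarnings(cor(t(x)))
    if (any(sds == 0)) {
      warning("constant rows: correlation undefined, distance set to 1")
      cc[sds == 0, ] <- 0; cc[, sds == 0] <- 0
    }
    diag(cc) <- 1
    d <- as.dist(1 - cc)
  } else {
    d <- stats::dist(x)
  }
  hclust(d, method = method)
}

#' Write a dendrogram as a Newick string
#'
#' @param hc an `hclust` object
#' @return single Newick string (with branch lengths)
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Tissue-specificity report
#'
#' For each miRNA: the tissue with maximal relative expression, the
#' fraction of its total expression found there, and a flag set when that
#' fraction reaches `threshold`.
#'
#' @param mat expression matrix (miRNAs x tissues, >= 2 tissues)
#' @param threshold specificity flag cut-off on the expression fraction
#' @return data.frame `mirna`, `top_tissue`, `fraction`, `tissue_specific`
#' @export
tissue_specificity <- function(mat, threshold = 0.5) {
  if (ncol(mat) < 2L) stop("need at least two tissues")
  top <- apply(mat, 1L, which.max)
  frac <- mat[cbind(seq_len(nrow(mat)), top)] / rowSums(mat)
  data.frame(mirna = rownames(mat),
             top_tissue = colnames(mat)[top],
             fraction = as.numeric(frac),
             tissue_specific = as.numeric(frac) >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
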