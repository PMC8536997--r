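# Presence/absence similarity between samples: binary allele matrix,
# Jaccard index, agglomerative clustering (single and complete linkage
# with a deterministic tie-break), classical MDS, and logistic PCA.

#' Build the samples-by-alleles presence/absence matrix
#'
#' @param sample_sets named list: sample id -> character vector of retained
#'   allele peptides
#' @return binary matrix, rows = samples, columns = union of alleles in
#'   first-seen order
#' @export
build_binary_matrix <- function(sample_sets) {
  if (length(sample_sets) < 2L) stop("need at least 2 samples")
  if (any(lengths(sample_sets) == 0L)) stop("sample with zero alleles")
  alleles <- unique(unlist(sample_sets, use.names = FALSE))
  m <- vapply(sample_sets, function(s) as.integer(alleles %in% s),
              integer(length(alleles)))
  m <- t(m)
  colnames(m) <- alleles
  m
}

#' Jaccard similarity between sample rows of a binary matrix
#'
#' J(i, j) = |intersection| / |union| of the two samples' allele sets.
#'
#' @param mat binary presence/absence matrix (rows non-empty)
#' @return symmetric n x n similarity matrix with unit diagonal
#' @export
jaccard_matrix <- function(mat) {
  stopifnot(all(mat %in% c(0, 1)), all(rowSums(mat) > 0))
  inter <- mat %*% t(mat)
  sizes <- rowSums(mat)
  un <- outer(sizes, sizes, "+") - inter
  j <- inter / un
  dimnames(j) <- list(rownames(mat), rownames(mat))
  j
}

# traversal order of leaves for an hclust-style merge matrix
.merge_order <- function(merge) {
  walk <- function(i) {
    if (i < 0L) return(-i)
    c(walk(merge[i, 1]), walk(merge[i, 2]))
  }
  walk(nrow(merge))
}

#' Agglomerative clustering with single or complete linkage
#'
#' Naive O(n^3) agglomeration on a dissimilarity matrix.  Among pairs at
#' equal minimum distance the pair with the smallest (row, column) index is
#' merged, making dendrograms reproducible.  Returns an `hclust`-compatible
#' object so `plot()`, `cutree()` and `ape::as.phylo()` work directly.
#'
#' @param d square symmetric non-negative dissimilarity matrix with zero
#'   diagonal (or a `dist`)
#' @param method `"single"` or `"complete"`
#' @return object of class `hclust` with an extra `merges` data.frame
#'   (step, height, members of the new cluster)
#' @export
linkage_cluster <- function(d, method = c("single", "complete")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d)) || any(d < 0) || any(diag(d) != 0))
    stop("need a symmetric non-negative matrix with zero diagonal")
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active clusters carry hclust codes: -leaf or +merge-step
  code <- -seq_len(n)
  members <- as.list(seq_len(n))
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(code)
    best <- c(NA_integer_, NA_integer_)
    bestd <- Inf
    for (i in seq_len(m - 1L)) for (k in (i + 1L):m) {
      if (D[i, k] < bestd - 1e-15) {
        bestd <- D[i, k]
        best <- c(i, k)
      }
    }
    i <- best[1]; k <- best[2]
    a <- code[i]; b <- code[k]
    merge[step, ] <- sort(c(a, b))
    height[step] <- bestd
    new_members <- sort(c(members[[i]], members[[k]]))
    merges[[step]] <- data.frame(
      step = step, height = bestd,
      members = paste(labels[new_members], collapse = ","),
      stringsAsFactors = FALSE)
    upd <- if (method == "single") pmin(D[i, ], D[k, ])
           else pmax(D[i, ], D[k, ])
    keep <- setdiff(seq_len(m), c(i, k))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], upd[keep]),
               c(upd[keep], 0))
    code <- c(code[keep], step)
    members <- c(members[keep], list(new_members))
  }
  out <- structure(list(merge = merge, height = height,
                        order = .merge_order(merge), labels = labels,
                        method = method,
                        dist.method = "user",
                        merges = do.call(rbind, merges)),
                   class = "hclust")
  out
}

#' Serialize a clustering to Newick
#' @param hc an `hclust` (e.g. from [linkage_cluster()])
#' @return single Newick string (requires the ape package)
#' @export
linkage_newick <- function(hc) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for Newick export")
  ape::write.tree(ape::as.phylo(hc))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared dissimilarities and embeds on the top-k
#' eigenpairs.  When fewer than k positive eigenvalues exist, the missing
#' coordinates are zero-padded.
#'
#' @param d dissimilarity matrix (or `dist`)
#' @param k embedding dimension
#' @return n x k coordinate matrix (rows named after samples)
#' @export
classical_mds <- function(d, k = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(k >= 1L, k <= n - 1L)
  if (all(d == 0)) {
    co <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
    return(co)
  }
  co <- stats::cmdscale(d, k = k)
  if (ncol(co) < k)
    co <- cbind(co, matrix(0, n, k - ncol(co)))
  rownames(co) <- rownames(d)
  co
}

#' Logistic PCA of a binary matrix
#'
#' Low-rank decomposition of binary data under a Bernoulli likelihood in
#' natural-parameter space.  The saturated natural parameters are
#' represented as `m * (2X - 1)`; centered parameters are projected onto a
#' rank-k subspace and the fit is iterated by majorize-minimize with the
#' quadratic bound 1/4 on the logistic curvature, so the Bernoulli deviance
#' is non-increasing across iterations by construction.
#'
#' @param x binary matrix (samples x features)
#' @param k target rank (number of components), `0 < k < min(dim(x))`
#' @param m natural-parameter scale; larger values push fitted
#'   probabilities towards 0/1
#' @param max_iter iteration cap
#' @param tol convergence tolerance on the relative deviance change
#' @return list of class `logistic_pca`: `scores` (n x k), `loadings`
#'   (p x k, orthonormal), `mu` (feature offsets), `fitted_prob`,
#'   `deviance` (per-iteration trace), `iterations`, `converged`
#' @export
logistic_pca <- function(x, k = 2L, m = 4, max_iter = 500L, tol = 1e-7) {
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("matrix entries must be 0/1")
  n <- nrow(x); p <- ncol(x)
  if (k <= 0L || k >= min(n, p)) stop("need 0 < k < min(dim(x))")
  tt <- m * (2 * x - 1)                    # saturated natural parameters
  mu <- colMeans(tt)
  sv <- svd(sweep(tt, 2L, mu), nu = 0, nv = k)
  v <- sv$v

  deviance_of <- function(theta) {
    pr <- stats::plogis(theta)
    -2 * sum(x * log(pr) + (1 - x) * log1p(-pr))
  }
  theta_of <- function(mu, v) {
    proj <- sweep(tt, 2L, mu) %*% v %*% t(v)
    sweep(proj, 2L, mu, "+")
  }

  theta <- theta_of(mu, v)
  dev <- deviance_of(theta)
  trace <- dev
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    z <- theta + 4 * (x - stats::plogis(theta))   # working response
    mu <- colMeans(z - tt %*% v %*% t(v))
    a <- sweep(z, 2L, mu)
    b <- sweep(tt, 2L, mu)
    mm <- crossprod(b, a)
    mm <- mm + t(mm) - crossprod(b)
    v <- eigen(mm, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
    theta <- theta_of(mu, v)
    dev_new <- deviance_of(theta)
    trace <- c(trace, dev_new)
    if (abs(dev - dev_new) < tol * (abs(dev) + 1e-12)) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  scores <- sweep(tt, 2L, mu) %*% v
  rownames(scores) <- rownames(x)
  structure(list(scores = scores, loadings = v, mu = mu,
                 fitted_prob = stats::plogis(theta),
                 deviance = trace, iterations = it, converged = converged),
            class = "logistic_pca")
}

#' @export
print.logistic_pca <- function(x, ...) {
  cat("<logistic_pca> k =", ncol(x$scores),
      "| deviance", format(utils::tail(x$deviance, 1), digits = 6),
      "after", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}

#' Full presence/absence similarity analysis
#'
#' @param sample_sets named list of per-sample allele peptide vectors
#' @param k embedding dimension for MDS and logistic PCA
#' @param m logistic-PCA natural-parameter scale
#' @return list `matrix`, `jaccard`, `dissimilarity`, `single`, `complete`
#'   (linkage objects), `mds`, `lpca`
#' @export
sample_similarity <- function(sample_sets, k = 2L, m = 4) {
  bm <- build_binary_matrix(sample_sets)
  j <- jaccard_matrix(bm)
  dis <- 1 - j
  list(matrix = bm, jaccard = j, dissimilarity = dis,
       single = linkage_cluster(dis, "single"),
       complete = linkage_cluster(dis, "complete"),
       mds = classical_mds(dis, k = k),
       lpca = logistic_pca(bm, k = k, m = m))
}
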