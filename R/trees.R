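# Comparison of interaction-profile dendrograms with sequence-similarity
# dendrograms: Euclidean profile distances, identity-based sequence
# distances, hierarchical clustering, cophenetic correlation and a
# label-permutation significance test.

#' Euclidean distances between interaction profiles
#'
#' @param m Numeric matrix, rows = domain/bait variants, columns = preys
#'   (PCA scores). Missing values are imputed before the distance is taken.
#' @param impute Value standing in for missing entries (default 0, the
#'   plate background after normalization).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
profile_distance <- function(m, impute = 0) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least two profile rows")
  m[is.na(m)] <- impute
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Identity-based distances between aligned sequences
#'
#' d(a, b) = 1 - pairwise identity, using the package's gap rule
#' ([pairwise_identity()]).
#'
#' @param aln Named character vector of aligned rows, or a character matrix.
#' @return Symmetric distance matrix.
#' @export
sequence_distance <- function(aln) {
  if (is.matrix(aln)) {
    ids <- rownames(aln)
    rows <- lapply(seq_len(nrow(aln)), function(i) aln[i, ])
  } else {
    ids <- names(aln)
    rows <- as.list(aln)
  }
  n <- length(rows)
  if (n < 2L) stop("need at least two sequences")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- 1 - pairwise_identity(rows[[i]], rows[[j]])
    }
  }
  d
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with complete or average linkage. Ties in the
#' minimum linkage distance (equal within \code{tol}, which absorbs
#' floating-point noise in distances derived from coordinates) are broken
#' deterministically toward the pair containing the lowest leaf index, so
#' two numerically indistinguishable distance matrices always produce the
#' same tree. Returns a standard \code{hclust} object.
#'
#' @param d Symmetric distance matrix (zero diagonal) or \code{dist}.
#' @param linkage \code{"complete"} (default) or \code{"average"}.
#' @param tol Distances within \code{tol} of the step minimum count as
#'   tied.
#' @return An \code{hclust} tree.
#' @export
cluster_profiles <- function(d, linkage = c("complete", "average"),
                             tol = 1e-9) {
  linkage <- match.arg(linkage)
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (any(is.na(d))) stop("NaN/NA distances")
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  n <- nrow(d)
  if (n < 2L) stop("need at least two items")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # cluster state: leaf members, hclust merge code, size
  members <- as.list(seq_len(n))
  code <- -seq_len(n)
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  cd <- d
  diag(cd) <- Inf
  cd[!is.finite(d) & upper.tri(d)] <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- cd[idx, idx, drop = FALSE]
    mval <- min(sub[upper.tri(sub)])
    # all tied candidate pairs; break toward lowest leaf indices
    cand <- which(upper.tri(sub) & sub <= mval + tol, arr.ind = TRUE)
    key1 <- pmin(vapply(idx[cand[, 1L]], function(i) min(members[[i]]),
                        integer(1L)),
                 vapply(idx[cand[, 2L]], function(i) min(members[[i]]),
                        integer(1L)))
    key2 <- pmax(vapply(idx[cand[, 1L]], function(i) min(members[[i]]),
                        integer(1L)),
                 vapply(idx[cand[, 2L]], function(i) min(members[[i]]),
                        integer(1L)))
    pick <- order(key1, key2)[1L]
    i <- idx[cand[pick, 1L]]
    j <- idx[cand[pick, 2L]]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- cd[i, j]
    # merged cluster replaces slot i; slot j retired
    upd <- setdiff(idx, c(i, j))
    if (length(upd) > 0L) {
      new_d <- if (linkage == "complete") {
        pmax(cd[i, upd], cd[j, upd])
      } else {
        (sizes[i] * cd[i, upd] + sizes[j] * cd[j, upd]) /
          (sizes[i] + sizes[j])
      }
      cd[i, upd] <- new_d
      cd[upd, i] <- new_d
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    code[i] <- step
    active[j] <- FALSE
  }
  # leaf order by depth-first traversal of the merge tree
  dfs <- function(node) {
    if (node < 0L) return(-node)
    c(dfs(merge[node, 1L]), dfs(merge[node, 2L]))
  }
  structure(list(merge = merge, height = height, order = dfs(n - 1L),
                 labels = labels, method = linkage,
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

# cophenetic distance matrix with leaf labels on both dims
cophenetic_matrix <- function(h) {
  as.matrix(stats::cophenetic(h))
}

#' Cophenetic correlation between two dendrograms
#'
#' Pearson correlation of the two trees' cophenetic (merge-height) distances
#' over all unordered leaf pairs. Both trees must carry the same leaf set;
#' at least 3 leaves are required (a single pair has no defined
#' correlation), and a tree whose cophenetic distances are constant (e.g.
#' built from identical profiles) is an error.
#'
#' @param d1,d2 \code{hclust} trees over the same leaves.
#' @return Correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(d1, d2) {
  l1 <- d1$labels
  l2 <- d2$labels
  if (!setequal(l1, l2)) stop("dendrograms have different leaf sets")
  if (length(l1) < 3L) stop("need at least 3 leaves (>= 3 pairs)")
  c1 <- cophenetic_matrix(d1)[l1, l1]
  c2 <- cophenetic_matrix(d2)[l1, l1]
  v1 <- c1[lower.tri(c1)]
  v2 <- c2[lower.tri(c2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("constant cophenetic distances; correlation undefined")
  }
  stats::cor(v1, v2)
}

#' Permutation test of profile-tree vs sequence-tree concordance
#'
#' Builds the interaction-profile dendrogram (Euclidean distances, then
#' hierarchical clustering) and the sequence dendrogram (1 - identity
#' distances, same clustering), computes their cophenetic correlation, and
#' obtains a null by randomly permuting the assignment of domain labels to
#' profile rows and recomputing the correlation. Permuting the labels of a
#' fixed tree permutes its cophenetic matrix, so the null is computed
#' without re-clustering. One-tailed p with add-one smoothing:
#' p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm).
#'
#' @param profiles Profile matrix (rows = domains, named).
#' @param aln Aligned sequences named like the profile rows.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer RNG seed.
#' @param linkage Linkage method (default complete).
#' @param impute Missing-profile-entry imputation value.
#' @return Object of class \code{"cophenetic_test"}: \code{r},
#'   \code{n_pairs}, \code{p}, \code{n_perm}, \code{seed},
#'   \code{r_perm} (null sample).
#' @export
cophenetic_permutation_test <- function(profiles, aln, n_perm = 10000L,
                                        seed = 1L, linkage = "complete",
                                        impute = 0) {
  stopifnot(n_perm >= 1L)
  h_prof <- cluster_profiles(profile_distance(profiles, impute), linkage)
  h_seq <- cluster_profiles(sequence_distance(aln), linkage)
  labels <- h_seq$labels
  if (!setequal(h_prof$labels, labels)) stop("leaf sets do not match")
  c_prof <- cophenetic_matrix(h_prof)[labels, labels]
  c_seq <- cophenetic_matrix(h_seq)[labels, labels]
  lt <- lower.tri(c_prof)
  v_seq <- c_seq[lt]
  v_obs <- c_prof[lt]
  if (stats::sd(v_obs) == 0 || stats::sd(v_seq) == 0) {
    stop("constant cophenetic distances; correlation undefined")
  }
  r_obs <- stats::cor(v_obs, v_seq)
  n <- length(labels)
  rng <- local_rng(seed)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(n)
    stats::cor(c_prof[perm, perm][lt], v_seq)
  }, numeric(1L))
  restore_rng(rng)
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  structure(list(r = r_obs, n_pairs = sum(lt), p = p, n_perm = n_perm,
                 seed = seed, r_perm = r_perm),
            class = "cophenetic_test")
}

#' @export
print.cophenetic_test <- function(x, ...) {
  cat("Cophenetic comparison: r = ", signif(x$r, 3), " over ", x$n_pairs,
      " pairs; permutation p = ", signif(x$p, 3), " (n_perm = ", x$n_perm,
      ")\n", sep = "")
  invisible(x)
}

#' Write a dendrogram in Newick format
#'
#' @param h An \code{hclust} tree.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}
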