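# Structure-based phylogenetic clustering: the pairwise RMSD matrix, its
# row-correlation transform, hierarchical cluster assignment, and the
# per-residue Calpha positional-conservation profile computed against a
# cluster reference.

#' Pairwise RMSD matrix of a set of Calpha traces
#'
#' Every ordered pair is superposed with [align_structures()]; because
#' iterative outlier rejection makes the two directions slightly asymmetric,
#' cell (i, j) is the mean of the (i, j) and (j, i) RMSDs, giving a proper
#' symmetric distance matrix for linkage.
#'
#' @param traces A named list of `ca_trace` objects (names become labels;
#'   unnamed traces use their structure id).
#' @param params A [superposition_params()].
#' @return A symmetric numeric matrix of class `rmsd_matrix` with zero
#'   diagonal, dimnames = labels, and a `kept_pairs` matrix attribute.
#' @export
pairwise_rmsd_matrix <- function(traces, params = superposition_params()) {
  if (length(traces) < 2) abort("need at least 2 traces")
  labels <- names(traces) %||% vapply(traces, trace_id, character(1))
  if (is.null(names(traces))) names(traces) <- labels
  labels <- names(traces)
  n <- length(traces)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  kp <- matrix(NA_integer_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      fij <- tryCatch(align_structures(traces[[i]], traces[[j]], params),
                      error = function(e) abort(sprintf(
                        "alignment failed for pair (%s, %s): %s",
                        labels[i], labels[j], conditionMessage(e))))
      fji <- align_structures(traces[[j]], traces[[i]], params)
      m[i, j] <- m[j, i] <- (fij$rmsd + fji$rmsd) / 2
      kp[i, j] <- kp[j, i] <- min(fij$n_kept_pairs, fji$n_kept_pairs)
    }
  }
  attr(m, "kept_pairs") <- kp
  class(m) <- c("rmsd_matrix", class(m))
  m
}

#' Row-profile correlation of an RMSD matrix
#'
#' For each pair of structures, the Pearson correlation of their RMSD
#' profiles against all *other* structures (columns i and j are excluded so a
#' cell never correlates a structure's zero self-distance). Structures whose
#' structural distances to the rest of the set co-vary end up highly
#' correlated — the similarity on which the published archaeal/bacterial
#' split was drawn.
#'
#' @param m An `rmsd_matrix` (needs >= 4 labels so that each correlation has
#'   >= 2 points).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
rmsd_profile_correlation <- function(m) {
  n <- nrow(m)
  if (n < 4) abort("profile correlation needs >= 4 structures")
  labels <- rownames(m)
  out <- diag(1, n)
  dimnames(out) <- dimnames(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      keep <- setdiff(seq_len(n), c(i, j))
      xi <- m[i, keep]; xj <- m[j, keep]
      if (sd(xi) == 0 || sd(xj) == 0) {
        abort(paste0("zero-variance RMSD profile for '",
                     labels[if (sd(xi) == 0) i else j],
                     "': correlation undefined"))
      }
      out[i, j] <- out[j, i] <- cor(xi, xj)
    }
  }
  out
}

#' Hierarchical clustering of structures
#'
#' Agglomerative clustering on either the RMSD matrix itself (`mode =
#' "rmsd"`) or on `1 - ` its row-profile correlation (`mode =
#' "correlation"`, the default, following the published procedure), cut at
#' `k` clusters. Each cluster gets a reference structure: user-designated via
#' `references`, otherwise the cluster medoid (smallest mean within-cluster
#' RMSD).
#'
#' @param m An `rmsd_matrix`.
#' @param mode `"correlation"` or `"rmsd"`.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @param k Number of clusters.
#' @param references Optional character vector of structure labels to use as
#'   cluster references; each is assigned to the cluster it belongs to.
#' @return An object of class `structure_clusters` with `assignment` (tibble:
#'   `label`, `cluster`, `is_reference`), the `hclust` tree, and the mode /
#'   linkage used. `tidy()` returns the assignment; [cluster_dendrogram()]
#'   exports newick.
#' @export
cluster_structures <- function(m, mode = c("correlation", "rmsd"),
                               linkage = c("average", "complete", "single"),
                               k = 2, references = NULL) {
  mode <- match.arg(mode)
  linkage <- match.arg(linkage)
  labels <- rownames(m)
  if (k < 1 || k > length(labels)) {
    abort(sprintf("k = %d outside 1..%d", k, length(labels)))
  }
  dmat <- if (mode == "rmsd") unclass(m) else 1 - rmsd_profile_correlation(m)
  tree <- hclust(as.dist(dmat), method = linkage)
  cl <- cutree(tree, k = k)
  refs <- character(k)
  for (g in seq_len(k)) {
    members <- labels[cl == g]
    user_ref <- intersect(references %||% character(0), members)
    refs[g] <- if (length(user_ref) > 0) {
      user_ref[1]
    } else if (length(members) == 1) {
      members
    } else {
      sub <- unclass(m)[members, members, drop = FALSE]
      members[which.min(rowMeans(sub))]       # medoid fallback
    }
  }
  assignment <- tibble(label = labels, cluster = unname(cl),
                       is_reference = labels %in% refs)
  structure(list(assignment = assignment, tree = tree, mode = mode,
                 linkage = linkage, k = k,
                 references = setNames(refs, seq_len(k))),
            class = "structure_clusters")
}

#' @export
print.structure_clusters <- function(x, ...) {
  cat(sprintf("<structure_clusters> k = %d (%s distance, %s linkage)\n",
              x$k, x$mode, x$linkage))
  print(x$assignment, n = Inf)
  invisible(x)
}

#' @rdname cluster_structures
#' @param x A `structure_clusters` object.
#' @param ... Unused.
#' @method tidy structure_clusters
#' @export
tidy.structure_clusters <- function(x, ...) x$assignment

#' Export a clustering dendrogram as a newick string
#'
#' @param clusters A `structure_clusters` object.
#' @param path Optional file to write to.
#' @return The newick string, invisibly if written to file.
#' @export
cluster_dendrogram <- function(clusters, path = NULL) {
  phy <- ape::as.phylo(clusters$tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Per-residue Calpha positional-conservation profile
#'
#' For a cluster of structures, each member is superposed onto the reference
#' and, for every reference residue i and member j, the distance d_ij from
#' the reference Calpha to the *nearest* Calpha of the transformed member is
#' measured (nearest-neighbour over the whole member trace, not the
#' sequence-paired atom). The conservation value of residue i is the RMS of
#' those distances, `Ca_RMSD_i = sqrt(mean_j d_ij^2)`: small where the fold
#' is conserved across the cluster, large in structurally variable regions.
#'
#' @param reference A `ca_trace`, the cluster reference.
#' @param members List of `ca_trace` objects, the other cluster members
#'   (exclude the reference itself).
#' @param params A [superposition_params()].
#' @return A tibble of class `conservation_profile`: `resno`, `aa`,
#'   `ca_rmsd` (angstrom), `n` (member count).
#' @export
conservation_profile <- function(reference, members,
                                 params = superposition_params()) {
  if (length(members) == 0) abort("members must be non-empty")
  ref_xyz <- trace_xyz(reference)
  d2 <- matrix(0, nrow(reference), length(members))
  for (j in seq_along(members)) {
    fit <- align_structures(reference, members[[j]], params)
    mem_xyz <- apply_rigid(trace_xyz(members[[j]]), fit$rotation,
                           fit$translation)
    # nearest member Calpha for every reference Calpha: locate the argmin
    # with the fast expanded form, then recompute that one distance exactly
    # (the expansion loses ~1e-7 to cancellation)
    cross <- outer(rowSums(ref_xyz^2), rep(1, nrow(mem_xyz))) +
      outer(rep(1, nrow(ref_xyz)), rowSums(mem_xyz^2)) -
      2 * ref_xyz %*% t(mem_xyz)
    nearest <- apply(cross, 1, which.min)
    d2[, j] <- rowSums((ref_xyz - mem_xyz[nearest, , drop = FALSE])^2)
  }
  out <- tibble(
    resno = reference$resno, aa = reference$aa,
    ca_rmsd = sqrt(rowMeans(d2)), n = length(members)
  )
  class(out) <- c("conservation_profile", class(out))
  attr(out, "reference_id") <- trace_id(reference)
  out
}

#' Plot a conservation profile
#'
#' @param object A `conservation_profile`.
#' @param ... Unused.
#' @return A ggplot: Calpha RMSD per residue number.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$resno, y = .data$ca_rmsd)) +
    geom_line(colour = "grey40") +
    geom_point(aes(colour = .data$ca_rmsd), size = 1.2) +
    scale_colour_viridis_c(name = expression(C*alpha~RMSD~(ring(A)))) +
    labs(x = "residue number",
         y = expression(C*alpha~RMSD~(ring(A))),
         title = paste0("Calpha position conservation (n = ",
                        object$n[1], " members)")) +
    theme_minimal()
}
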