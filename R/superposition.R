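# Pairwise rigid-body superposition of Calpha traces: sequence-guided residue
# pairing, closed-form least-squares (Kabsch) fitting, and iterative rejection
# of outlier pairs beyond a distance cutoff — the pairwise-comparison stage
# behind the RMSD matrix and the conservation profiles.

#' Superposition parameters
#'
#' @param cycles Number of outlier-rejection refinement cycles (default 2).
#' @param cutoff Distance (angstrom) beyond which a pair is rejected after a
#'   fit (default 1.5).
#' @param pairing `"sequence"` (global alignment of one-letter sequences) or
#'   `"index"` (positional pairing, for equal-length synthetic families).
#' @return A list of class `superposition_params`.
#' @export
superposition_params <- function(cycles = 2, cutoff = 1.5,
                                 pairing = c("sequence", "index")) {
  pairing <- match.arg(pairing)
  stopifnot(cycles >= 0, cutoff > 0)
  structure(list(cycles = as.integer(cycles), cutoff = cutoff,
                 pairing = pairing),
            class = "superposition_params")
}

#' Pair residues between two Calpha traces
#'
#' Sequence mode runs a global protein alignment (BLOSUM62, affine gap
#' open 10 / extend 0.5) of the one-letter sequences and keeps the ungapped
#' columns; index mode pairs positions 1:1 up to the shorter trace. The
#' pairing is monotone (strictly increasing indices in both traces).
#'
#' @param a,b `ca_trace` objects from [extract_ca_trace()].
#' @param pairing `"sequence"` or `"index"`.
#' @return A tibble with columns `ia`, `ib` (row indices into `a` and `b`)
#'   and attribute `score` (alignment score; `NA` in index mode).
#' @export
pair_residues <- function(a, b, pairing = c("sequence", "index")) {
  pairing <- match.arg(pairing)
  if (nrow(a) == 0 || nrow(b) == 0) abort("cannot pair an empty trace")
  if (pairing == "index") {
    n <- min(nrow(a), nrow(b))
    out <- tibble(ia = seq_len(n), ib = seq_len(n))
    attr(out, "score") <- NA_real_
    return(out)
  }
  sa <- paste(a$aa, collapse = "")
  sb <- paste(b$aa, collapse = "")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5, type = "global"
  )
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-"
  out <- tibble(ia = ia[keep], ib = ib[keep])
  attr(out, "score") <- Biostrings::score(aln)
  out
}

#' Kabsch least-squares rigid-body fit
#'
#' Finds the rotation (proper, det +1) and translation minimizing the sum of
#' squared distances between paired points, via SVD of the covariance matrix
#' with reflection correction. The transform maps `coords_b` onto `coords_a`.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices of paired coordinates
#'   (angstrom), n >= 3 and non-collinear.
#' @return A list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd`; the fitted position of a point q is `rotation %*% q +
#'   translation`.
#' @export
kabsch_fit <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  n <- nrow(coords_a)
  if (n < 3 || nrow(coords_b) != n) {
    abort("kabsch_fit needs >= 3 paired points")
  }
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- crossprod(B, A)               # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) abort("degenerate geometry: covariance matrix is singular")
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- ca - as.vector(R %*% cb)
  fitted <- apply_rigid(coords_b, R, t_vec)
  rmsd <- sqrt(mean(rowSums((coords_a - fitted)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

apply_rigid <- function(coords, rotation, translation) {
  sweep(as.matrix(coords) %*% t(rotation), 2, translation, `+`)
}

#' Superpose two Calpha traces with iterative outlier rejection
#'
#' Pairs the residues, performs a Kabsch fit on all pairs, then for each of
#' `cycles` refinement cycles drops pairs whose post-fit distance exceeds
#' `cutoff` angstrom and refits on the survivors. If a rejection round would
#' leave fewer than 3 pairs, rejection stops and the last valid fit is kept.
#' The reported RMSD is over the retained pairs only.
#'
#' @param a,b `ca_trace` objects; `b` is fitted onto `a`.
#' @param params A [superposition_params()].
#' @return An object of class `superposition`: rotation, translation, `rmsd`
#'   (angstrom), `n_total_pairs`, `n_kept_pairs`, logical `kept` mask over
#'   the initial pairing, and the `pairs` tibble.
#' @export
align_structures <- function(a, b, params = superposition_params()) {
  pairs <- pair_residues(a, b, params$pairing)
  if (nrow(pairs) < 3) {
    abort(sprintf("only %d residue pair(s); >= 3 needed to superpose",
                  nrow(pairs)))
  }
  pa <- trace_xyz(a)[pairs$ia, , drop = FALSE]
  pb <- trace_xyz(b)[pairs$ib, , drop = FALSE]
  kept <- rep(TRUE, nrow(pairs))
  fit <- kabsch_fit(pa, pb)
  for (cycle in seq_len(params$cycles)) {
    fitted <- apply_rigid(pb, fit$rotation, fit$translation)
    d <- sqrt(rowSums((pa - fitted)^2))
    keep_next <- kept & d <= params$cutoff
    if (sum(keep_next) < 3 || identical(keep_next, kept)) break
    kept <- keep_next
    fit <- kabsch_fit(pa[kept, , drop = FALSE], pb[kept, , drop = FALSE])
  }
  structure(list(
    rotation = fit$rotation, translation = fit$translation,
    rmsd = fit$rmsd,
    n_total_pairs = nrow(pairs), n_kept_pairs = sum(kept),
    kept = kept, pairs = pairs,
    id_a = trace_id(a), id_b = trace_id(b), params = params
  ), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(
    "<superposition> %s onto %s: rmsd %.3f A over %d/%d pairs\n",
    x$id_b, x$id_a, x$rmsd, x$n_kept_pairs, x$n_total_pairs))
  invisible(x)
}

#' @rdname align_structures
#' @param x A `superposition` object.
#' @param ... Unused.
#' @method glance superposition
#' @export
glance.superposition <- function(x, ...) {
  tibble(id_a = x$id_a, id_b = x$id_b, rmsd = x$rmsd,
         n_total_pairs = x$n_total_pairs, n_kept_pairs = x$n_kept_pairs)
}

#' @rdname align_structures
#' @method tidy superposition
#' @export
tidy.superposition <- function(x, ...) {
  mutate(x$pairs, kept = x$kept)
}
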