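# Independent oracles used by the tests. Each is deliberately implemented by
# a different route than the package code it checks.

# Minimal RMSD between paired point sets via the quaternion (Horn) method:
# the largest eigenvalue of the 4x4 key matrix gives the maximal rotational
# overlap, from which the least-squares RMSD follows in closed form. No SVD.
quaternion_rmsd <- function(xa, xb) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  n <- nrow(xa)
  ac <- sweep(xa, 2, colMeans(xa))
  bc <- sweep(xb, 2, colMeans(xb))
  S <- t(bc) %*% ac
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ssd <- sum(ac^2) + sum(bc^2) - 2 * lam
  sqrt(max(ssd, 0) / n)
}

# Global affine-gap alignment score by Gotoh's three-matrix recursion
# (gap of length L costs open + L * ext, end gaps penalized), as an
# independent check of the sequence-pairing stage.
gotoh_score <- function(sa, sb, submat, open = 10, ext = 0.5) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  n <- length(a); m <- length(b)
  neg <- -1e18
  M <- X <- Y <- matrix(neg, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- -open - ext * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# adjusted Rand index of two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  e <- si * sj / comb2(sum(tab))
  (sij - e) / ((si + sj) / 2 - e)
}

# a ca_trace built directly from residue letters and coordinates
make_trace <- function(aa, xyz, id = "trace") {
  xyz <- as.matrix(xyz)
  out <- tibble::tibble(resno = seq_along(aa), ins = "", aa = aa,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  attr(out, "structure_id") <- id
  attr(out, "chain") <- "A"
  class(out) <- c("ca_trace", class(out))
  out
}

# single-atom-per-row structure model from a coordinate table
make_model <- function(df, id = "model") {
  defaults <- list(chain = "A", ins = "", het = FALSE, o = 1, b = 0)
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  }
  structure_model(df, id = id)
}

# exposed SASA of two identical spheres at centre distance d: closed-form
# spherical caps (radius already includes the probe)
two_sphere_sasa <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

random_rigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  list(R = R, t = runif(3, -15, 15))
}

transform_trace <- function(trace, rigid) {
  xyz <- as.matrix(trace[, c("x", "y", "z")]) %*% t(rigid$R)
  xyz <- sweep(xyz, 2, rigid$t, `+`)
  trace$x <- xyz[, 1]; trace$y <- xyz[, 2]; trace$z <- xyz[, 3]
  trace
}

transform_model <- function(model, rigid) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rigid$R)
  xyz <- sweep(xyz, 2, rigid$t, `+`)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}
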