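# Internal helpers shared across modules.

#' Evaluate an expression with a locally seeded RNG
#'
#' Saves and restores `.Random.seed` so that seeded generators (phantoms,
#' cohorts, perturbations) do not disturb the caller's RNG stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a master seed; keeps values < 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset) * 104729L) %% 2147483647L
}

stop_hq <- function(msg, class = "herniaquant_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Pairwise Euclidean cross-distances between two n x 3 / m x 3 matrices,
# computed in row chunks of A to bound memory.
cross_min_dist <- function(A, B, chunk = 2000L) {
  A <- as.matrix(A); B <- as.matrix(B)
  nA <- nrow(A)
  out <- numeric(nA)
  B2 <- rowSums(B^2)
  i <- 1L
  while (i <= nA) {
    j <- min(i + chunk - 1L, nA)
    Ai <- A[i:j, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), B2, "+") - 2 * tcrossprod(Ai, B)
    d2[d2 < 0] <- 0
    out[i:j] <- sqrt(apply(d2, 1L, min))
    i <- j + 1L
  }
  out
}

# Flood fill over a logical 3-D array from seed indices.
# connectivity: 6 or 26 (3-D) or 4 (in-plane only, used for axial hole fill).
flood_fill3d <- function(allowed, seeds, connectivity = 6L) {
  dm <- dim(allowed)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  visited <- logical(length(allowed))
  frontier <- seeds[allowed[seeds] & !visited[seeds]]
  visited[frontier] <- TRUE
  offs <- switch(as.character(connectivity),
    "4"  = cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1), c(0, 0, 0, 0)),
    "6"  = cbind(c(-1, 1, 0, 0, 0, 0), c(0, 0, -1, 1, 0, 0), c(0, 0, 0, 0, -1, 1)),
    "26" = {
      g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
      as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
    },
    stop_hq("unsupported connectivity"))
  while (length(frontier)) {
    i0 <- frontier - 1L
    ix <- i0 %% nx
    iy <- (i0 %/% nx) %% ny
    iz <- i0 %/% (nx * ny)
    nbr <- integer(0)
    for (k in seq_len(nrow(offs))) {
      jx <- ix + offs[k, 1]; jy <- iy + offs[k, 2]; jz <- iz + offs[k, 3]
      ok <- jx >= 0 & jx < nx & jy >= 0 & jy < ny & jz >= 0 & jz < nz
      if (any(ok)) nbr <- c(nbr, (jx[ok] + nx * (jy[ok] + ny * jz[ok])) + 1L)
    }
    nbr <- unique(nbr)
    nbr <- nbr[allowed[nbr] & !visited[nbr]]
    visited[nbr] <- TRUE
    frontier <- nbr
  }
  array(visited, dim = dm)
}

# Largest connected component of a logical 3-D mask.
largest_component <- function(mask, connectivity = 26L) {
  remaining <- mask
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1L]
    comp <- flood_fill3d(remaining, seed, connectivity)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  if (is.null(best)) mask else best
}

# Fill in-plane (axial) holes of a 3-D mask: complement voxels unreachable
# from the slice border via 4-connectivity are added to the mask.
fill_holes_axial <- function(mask) {
  dm <- dim(mask)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  comp <- !mask
  border <- array(FALSE, dm)
  border[1, , ] <- TRUE; border[nx, , ] <- TRUE
  border[, 1, ] <- TRUE; border[, ny, ] <- TRUE
  seeds <- which(border & comp)
  outside <- flood_fill3d(comp, seeds, connectivity = 4L)
  mask | (comp & !outside)
}

# Shoelace polygon area (vertices in order, not necessarily closed).
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Perimeter of an ellipse with semi-axes a, b (numeric quadrature).
ellipse_perimeter <- function(a, b) {
  f <- function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2)
  4 * integrate(f, 0, pi / 2, rel.tol = 1e-10)$value
}
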