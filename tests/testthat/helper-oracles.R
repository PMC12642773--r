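# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: the closed-form linear flow goes through
# Matrix::expm, and the cellular-automaton oracle is a naive double-loop
# engine with its own matcher.

# Closed-form flow of xdot = A (x - c): x(t) = c + expm(A t) (x0 - c).
linear_flow <- function(A, center, x0, t) {
  as.numeric(center + Matrix::expm(A * t) %*% (x0 - center))
}

# --- naive Game-of-Life oracle ---------------------------------------------

# One synchronous step by explicit double loop over a padded 0/1 matrix.
naive_step <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0L, nr, nc)
  for (r in 2:(nr - 1)) {
    for (cc in 2:(nc - 1)) {
      n <- mat[r - 1, cc - 1] + mat[r - 1, cc] + mat[r - 1, cc + 1] +
           mat[r,     cc - 1] +                  mat[r,     cc + 1] +
           mat[r + 1, cc - 1] + mat[r + 1, cc] + mat[r + 1, cc + 1]
      out[r, cc] <- if (n == 3L || (mat[r, cc] == 1L && n == 2L)) 1L else 0L
    }
  }
  out
}

# Live (row, col) set of a padded matrix, in global coordinates given the
# matrix's origin.
naive_live <- function(mat, origin) {
  idx <- which(mat == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(0), ncol = 2))
  cells <- cbind(idx[, 1] + origin[1] - 1L, idx[, 2] + origin[2] - 1L)
  cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
}

# Build a padded matrix from a global live-cell list.
naive_matrix <- function(cells, pad) {
  r0 <- min(cells[, 1]) - pad; c0 <- min(cells[, 2]) - pad
  nr <- max(cells[, 1]) - r0 + 1 + pad
  nc <- max(cells[, 2]) - c0 + 1 + pad
  mat <- matrix(0L, nr, nc)
  mat[cbind(cells[, 1] - r0 + 1, cells[, 2] - c0 + 1)] <- 1L
  list(mat = mat, origin = c(r0, c0))
}

# The oracle derives its own glider phases by stepping the textbook phase-0
# pattern (.O./..O/OOO) with the naive engine.
naive_glider_phases <- local({
  p0 <- rbind(c(0, 1), c(1, 2), c(2, 0), c(2, 1), c(2, 2))
  nm <- naive_matrix(sweep(p0, 2, c(10, 10), "+"), pad = 6)
  phases <- list()
  mat <- nm$mat
  for (k in 1:4) {
    live <- naive_live(mat, nm$origin)
    norm <- sweep(live, 2, c(min(live[, 1]), min(live[, 2])), "-")
    phases[[k]] <- norm[order(norm[, 1], norm[, 2]), , drop = FALSE]
    mat <- naive_step(mat)
  }
  phases
})

naive_membrane <- function(cells) {
  nb <- unique(do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    as.matrix(expand.grid(cells[i, 1] + (-1:1), cells[i, 2] + (-1:1)))
  })))
  key <- paste(cells[, 1], cells[, 2])
  nb[!paste(nb[, 1], nb[, 2]) %in% key, , drop = FALSE]
}

# Windowed glider identification: some translation of some phase has all
# on-cells live and an all-off membrane.
naive_has_glider <- function(live) {
  if (nrow(live) == 0) return(FALSE)
  key <- paste(live[, 1], live[, 2])
  for (ph in naive_glider_phases) {
    for (i in seq_len(nrow(live))) {
      off <- live[i, ] - ph[1, ]
      cand <- sweep(ph, 2, off, "+")
      if (!all(paste(cand[, 1], cand[, 2]) %in% key)) next
      memb <- naive_membrane(cand)
      if (any(paste(memb[, 1], memb[, 2]) %in% key)) next
      return(TRUE)
    }
  }
  FALSE
}

# Exhaustive-simulation classification of a glider + environment scene,
# entirely within the naive engine: identity checked at period-4 boundaries.
naive_classify <- function(cells, horizon = 64, pad = NULL) {
  pad <- pad %||% (horizon %/% 2 + 8)
  nm <- naive_matrix(cells, pad = pad)
  mat <- nm$mat
  if (!naive_has_glider(naive_live(mat, nm$origin))) return("nonmember")
  missed <- FALSE
  ok_final <- TRUE
  for (s in seq(4, horizon, by = 4)) {
    for (i in 1:4) mat <- naive_step(mat)
    ok_final <- naive_has_glider(naive_live(mat, nm$origin))
    if (!ok_final) missed <- TRUE
  }
  if (!missed || ok_final) "interior" else "boundary"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
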