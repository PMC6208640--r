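# Two-phase primal simplex with Bland's rule for the small dense LPs arising
# from toy metabolic models. Solves
#     maximize  c'x   subject to  A x = b,  0 <= x <= ub
# with finite upper bounds. Bland's anti-cycling rule guarantees termination;
# problem sizes here are tiny (tens of variables), so the dense tableau is
# both simple and fast.

.simplex_pivot_phase <- function(tb, basis, cost, n_enter, tol = 1e-9) {
  m <- nrow(tb)
  k <- ncol(tb) - 1L
  repeat {
    cb <- cost[basis]
    red <- cost[seq_len(n_enter)] -
      as.numeric(cb %*% tb[, seq_len(n_enter), drop = FALSE])
    ent <- which(red > tol)
    if (!length(ent)) break
    j <- ent[1L] # Bland: lowest eligible index enters
    col <- tb[, j]
    pos <- col > tol
    if (!any(pos)) stop("LP unbounded")
    ratio <- ifelse(pos, tb[, k + 1L] / col, Inf)
    mr <- min(ratio)
    cand <- which(ratio <= mr + 1e-12)
    i <- cand[which.min(basis[cand])] # Bland: lowest basis index leaves
    piv <- tb[i, ] / tb[i, j]
    tb <- tb - outer(tb[, j], piv)
    tb[i, ] <- piv
    basis[i] <- j
  }
  list(tb = tb, basis = basis)
}

# returns list(x, value) or stops on infeasible/unbounded
.simplex_box_eq <- function(cc, A, b, ub, tol = 1e-7) {
  m <- nrow(A)
  n <- ncol(A)
  # append slack rows for the upper bounds: x_j + s_j = ub_j
  aa <- rbind(cbind(A, matrix(0, m, n)), cbind(diag(n), diag(n)))
  bb <- c(b, ub)
  neg <- bb < 0
  if (any(neg)) {
    aa[neg, ] <- -aa[neg, , drop = FALSE]
    bb[neg] <- -bb[neg]
  }
  mm <- m + n
  nn <- 2L * n
  tb <- cbind(aa, diag(mm), bb)
  basis <- nn + seq_len(mm)
  # phase 1: maximize -sum(artificials)
  cost1 <- c(rep(0, nn), rep(-1, mm))
  r1 <- .simplex_pivot_phase(tb, basis, cost1, n_enter = nn)
  tb <- r1$tb
  basis <- r1$basis
  resid <- sum(tb[basis > nn, ncol(tb)])
  if (resid > tol) stop("LP infeasible (phase-1 residual ", format(resid), ")")
  # drive leftover zero-level artificials out of the basis with degenerate
  # pivots (rhs = 0, so feasibility is untouched); rows with no real entry
  # are redundant and dropped. Phase 2 then runs artificial-free.
  drop_rows <- integer()
  for (i in which(basis > nn)) {
    nonbasic <- setdiff(seq_len(nn), basis)
    j <- nonbasic[which(abs(tb[i, nonbasic]) > 1e-9)][1L]
    if (is.na(j)) {
      drop_rows <- c(drop_rows, i)
      next
    }
    piv <- tb[i, ] / tb[i, j]
    tb <- tb - outer(tb[, j], piv)
    tb[i, ] <- piv
    basis[i] <- j
  }
  if (length(drop_rows)) {
    tb <- tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  tb <- tb[, c(seq_len(nn), ncol(tb)), drop = FALSE]
  cost2 <- c(cc, rep(0, n))
  r2 <- .simplex_pivot_phase(tb, basis, cost2, n_enter = nn)
  x <- numeric(nn)
  x[r2$basis] <- r2$tb[, ncol(r2$tb)]
  list(x = x[seq_len(n)], value = sum(cc * x[seq_len(n)]))
}
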