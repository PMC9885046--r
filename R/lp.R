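# Dense two-phase simplex solver for the small linear programs arising in
# flux balance analysis of pathway-scale models.
#
# Bland's rule (smallest-index entering variable, smallest-basis-index tie
# break on the ratio test) guarantees termination on the highly degenerate
# steady-state systems (many zero right-hand sides) that FBA produces.
# Problems are minimised in standard form: all variables nonnegative,
# constraints <=, >= or = with nonnegative right-hand sides.

.lp_pivot_loop <- function(Tab, basis, cost, tol = 1e-9, maxit = 20000L) {
  m <- nrow(Tab); n <- ncol(Tab) - 1L
  for (it in seq_len(maxit)) {
    cb <- cost[basis]
    red <- cost[seq_len(n)] -
      as.vector(cb %*% Tab[, seq_len(n), drop = FALSE])
    enter <- which(red < -tol)
    if (!length(enter))
      return(list(Tab = Tab, basis = basis, status = "optimal"))
    j <- enter[1L]
    col <- Tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratios <- Tab[pos, n + 1L] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    i <- cand[which.min(basis[cand])]
    piv <- Tab[i, ] / Tab[i, j]
    Tab <- Tab - outer(Tab[, j], piv)
    Tab[i, ] <- piv
    basis[i] <- j
  }
  list(status = "maxit")
}

# obj: length-n objective; A, b, ops ("<=", ">=", "="): constraint system;
# variables implicitly >= 0. Returns list(status, x, value).
.lp_solve <- function(obj, A, b, ops, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A); b <- as.numeric(b)
  stopifnot(nrow(A) == length(b), nrow(A) == length(ops))
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    ops[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[ops[neg]]
  }
  m <- nrow(A); nst <- ncol(A)

  n_slack <- sum(ops != "=")
  slack_col <- integer(m); art_col <- integer(m)
  ncols <- nst + n_slack + m        # upper bound; unused artificials trimmed
  Tab <- matrix(0, m, ncols + 1L)
  Tab[, seq_len(nst)] <- A
  Tab[, ncols + 1L] <- b
  nxt <- nst
  for (i in seq_len(m)) {
    if (ops[i] != "=") {
      nxt <- nxt + 1L
      slack_col[i] <- nxt
      Tab[i, nxt] <- if (ops[i] == "<=") 1 else -1
    }
  }
  basis <- integer(m)
  for (i in seq_len(m)) {
    if (ops[i] == "<=") {
      basis[i] <- slack_col[i]
    } else {
      nxt <- nxt + 1L
      art_col[i] <- nxt
      Tab[i, nxt] <- 1
      basis[i] <- nxt
    }
  }
  used <- nxt
  Tab <- Tab[, c(seq_len(used), ncols + 1L), drop = FALSE]

  # phase 1: drive artificials to zero
  if (any(art_col > 0L)) {
    cost1 <- c(rep(0, used), 0)[seq_len(used)]
    cost1[art_col[art_col > 0L]] <- 1
    r1 <- .lp_pivot_loop(Tab, basis, cost1, tol = tol)
    if (!identical(r1$status, "optimal")) return(list(status = "infeasible"))
    Tab <- r1$Tab; basis <- r1$basis
    val1 <- sum(cost1[basis] * Tab[, used + 1L])
    if (val1 > 1e-7) return(list(status = "infeasible"))
    # pivot lingering zero-level artificials out of the basis
    arts <- art_col[art_col > 0L]
    for (i in which(basis %in% arts)) {
      row <- Tab[i, seq_len(used)]
      row[arts] <- 0
      j <- which(abs(row) > tol)[1]
      if (is.na(j)) next               # redundant row; harmless
      piv <- Tab[i, ] / Tab[i, j]
      Tab <- Tab - outer(Tab[, j], piv)
      Tab[i, ] <- piv
      basis[i] <- j
    }
    keep <- setdiff(seq_len(used), arts)
    col_map <- integer(used); col_map[keep] <- seq_along(keep)
    drop_rows <- which(basis %in% arts)  # still artificial: redundant rows
    if (length(drop_rows)) {
      Tab <- Tab[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
    }
    Tab <- Tab[, c(keep, used + 1L), drop = FALSE]
    basis <- col_map[basis]
    used <- length(keep)
  }

  cost2 <- numeric(used)
  cost2[seq_len(nst)] <- if (maximize) -obj else obj
  r2 <- .lp_pivot_loop(Tab, basis, cost2, tol = tol)
  if (identical(r2$status, "unbounded")) return(list(status = "unbounded"))
  if (!identical(r2$status, "optimal")) return(list(status = "maxit"))
  x <- numeric(used)
  x[r2$basis] <- r2$Tab[, used + 1L]
  x <- x[seq_len(nst)]
  val <- sum(obj * x)
  list(status = "optimal", x = x, value = val)
}
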