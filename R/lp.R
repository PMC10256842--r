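# Internal linear-programming layer.
#
# All constraint-based computations reduce to bounded-variable LPs
#   max/min c'v   s.t.  Aeq v = beq,  lb <= v <= ub
# solved by a dense two-phase primal simplex on the shifted variables
# x = v - lb >= 0. The solver uses Dantzig pricing with a switch to Bland's
# rule (which cannot cycle) once the iteration count suggests degeneracy.
# Problem sizes here are tens of variables, where a dense tableau is exact
# and fast.

LP_FEAS_TOL <- 1e-9

simplex_iterate <- function(state, cost, allowed, tol, max_iter = 50000L, bland_after = 2000L) {
  M <- state$M
  rhs <- state$rhs
  basis <- state$basis
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) {
      state$status <- "iteration_limit"
      break
    }
    red <- cost - as.vector(cost[basis] %*% M)
    red[basis] <- 0
    cand <- which(red < -tol & allowed)
    if (length(cand) == 0) {
      state$status <- "optimal"
      break
    }
    j <- if (it > bland_after) cand[1] else cand[which.min(red[cand])]
    col <- M[, j]
    pos <- which(col > tol)
    if (length(pos) == 0) {
      state$status <- "unbounded"
      break
    }
    ratios <- rhs[pos] / col[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + tol]
    i <- ties[which.min(basis[ties])]
    # pivot on (i, j)
    M[i, ] <- M[i, ] / col[i]
    rhs[i] <- max(rhs[i] / col[i], 0)
    fac <- M[, j]
    fac[i] <- 0
    M <- M - outer(fac, M[i, ])
    rhs <- pmax(rhs - fac * rhs[i], 0)
    basis[i] <- j
  }
  state$M <- M
  state$rhs <- rhs
  state$basis <- basis
  state
}

# min cc'x  s.t.  A x <= b, Aeq x = beq, x >= 0.
# Returns list(x, objective, status) with status in
# {"optimal", "infeasible", "unbounded", "iteration_limit"}.
simplex_core <- function(cc, A = NULL, b = NULL, Aeq = NULL, beq = NULL,
                         tol = LP_FEAS_TOL) {
  n <- length(cc)
  nA <- if (is.null(A)) 0L else nrow(A)
  nE <- if (is.null(Aeq)) 0L else nrow(Aeq)
  M <- rbind(
    if (nA > 0) cbind(A, diag(nA)) else NULL,
    if (nE > 0) cbind(Aeq, matrix(0, nE, nA)) else NULL
  )
  rhs <- c(b, beq)
  m <- nrow(M)
  neg <- rhs < 0
  if (any(neg)) {
    M[neg, ] <- -M[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
  }
  ncol0 <- n + nA
  # initial basis: slack of un-negated inequality rows, artificials elsewhere
  basis <- integer(m)
  slack_ok <- which(seq_len(m) <= nA & !neg)
  basis[slack_ok] <- n + slack_ok
  need_art <- which(basis == 0L)
  n_art <- length(need_art)
  if (n_art > 0) {
    Art <- matrix(0, m, n_art)
    Art[cbind(need_art, seq_len(n_art))] <- 1
    M <- cbind(M, Art)
    basis[need_art] <- ncol0 + seq_len(n_art)
  }
  ncols <- ncol(M)
  art_cols <- if (n_art > 0) ncol0 + seq_len(n_art) else integer(0)
  allowed <- rep(TRUE, ncols)
  state <- list(M = M, rhs = rhs, basis = basis, status = "optimal")

  fail <- function(status) list(x = rep(NA_real_, n), objective = NA_real_, status = status)
  if (n_art > 0) {
    phase1 <- c(rep(0, ncol0), rep(1, n_art))
    state <- simplex_iterate(state, phase1, allowed, tol)
    if (state$status != "optimal") {
      return(fail(state$status))
    }
    if (sum(state$rhs[state$basis %in% art_cols]) > 1e-7) {
      return(fail("infeasible"))
    }
    allowed[art_cols] <- FALSE
    # Drive leftover zero-level artificials out of the basis so they cannot
    # drift positive in phase 2. Rows with no eligible pivot are redundant
    # (all-zero in real columns) and harmless.
    for (i in which(state$basis %in% art_cols)) {
      elig <- which(allowed & abs(state$M[i, ]) > tol & !(seq_len(ncols) %in% state$basis))
      if (length(elig) == 0) next
      j <- elig[1]
      piv <- state$M[i, j]
      state$M[i, ] <- state$M[i, ] / piv
      state$rhs[i] <- 0
      fac <- state$M[, j]
      fac[i] <- 0
      state$M <- state$M - outer(fac, state$M[i, ])
      state$rhs <- pmax(state$rhs - fac * state$rhs[i], 0)
      state$basis[i] <- j
    }
  }
  state <- simplex_iterate(state, c(cc, rep(0, ncols - n)), allowed, tol)
  if (state$status != "optimal") {
    return(fail(state$status))
  }
  x <- rep(0, ncols)
  x[state$basis] <- state$rhs
  x <- x[seq_len(n)]
  list(x = x, objective = sum(cc * x), status = "optimal")
}

lp_solve <- function(obj, Aeq, beq, lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(ncol(Aeq) == n, length(lb) == n, length(ub) == n, length(beq) == nrow(Aeq))
  if (any(lb > ub + LP_FEAS_TOL)) {
    stop_metarescue("lower bound exceeds upper bound in LP", "metarescue_lp_bounds")
  }
  res <- simplex_core(
    cc = if (maximize) -obj else obj,
    A = diag(n), b = pmax(ub - lb, 0),
    Aeq = Aeq, beq = beq - as.vector(Aeq %*% lb)
  )
  if (res$status != "optimal") {
    return(list(v = rep(NA_real_, n), objective = NA_real_, status = res$status))
  }
  v <- res$x + lb
  list(v = v, objective = sum(obj * v), status = "optimal")
}

# Minimize total absolute flux subject to S v = 0, bounds, and the objective
# pinned at mu_star; auxiliary variables w_i >= |v_i|.
lp_min_total_flux <- function(S, lb, ub, obj, mu_star) {
  n <- ncol(S)
  Aeq <- rbind(
    cbind(S, matrix(0, nrow(S), n)),
    c(obj, rep(0, n))
  )
  beq <- c(-as.vector(S %*% lb), mu_star - sum(obj * lb))
  A <- rbind(
    cbind(diag(n), matrix(0, n, n)), # x <= ub - lb
    cbind(diag(n), -diag(n)), #  v - w <= 0  (shifted: x - w <= -lb)
    cbind(-diag(n), -diag(n)) # -v - w <= 0  (shifted: -x - w <= lb)
  )
  b <- c(pmax(ub - lb, 0), -lb, lb)
  res <- simplex_core(cc = c(rep(0, n), rep(1, n)), A = A, b = b, Aeq = Aeq, beq = beq)
  if (res$status != "optimal") {
    return(list(v = rep(NA_real_, n), status = res$status))
  }
  list(v = res$x[seq_len(n)] + lb, status = "optimal")
}
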