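#' Dense two-phase simplex for small constraint-based models
#'
#' Solves  max c'v  s.t.  Aeq v = beq,  Aineq v >= bineq,  lb <= v <= ub.
#' Written for the model sizes this package targets (tens of reactions);
#' Bland's rule guarantees termination. Infinite bounds are replaced by
#' +/- `big`; an optimum pinned at such a synthetic bound is reported as
#' unbounded. The solver contract used by the target layer is: build the LP,
#' solve, report a status string plus the primal point — never a silent
#' boolean on numerical failure.
#'
#' @param obj objective coefficients (length n), maximized; all zero for a
#'   pure feasibility check.
#' @param Aeq,beq equality rows (may have zero rows).
#' @param Aineq,bineq inequality rows `Aineq v >= bineq` (may be `NULL`).
#' @param lb,ub variable bounds, length n.
#' @param big replacement magnitude for infinite bounds.
#' @param tol pivot/feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objval`, and `x` (the primal point, `NULL` unless optimal).
#' @keywords internal
lp_solve <- function(obj, Aeq = NULL, beq = NULL, Aineq = NULL, bineq = NULL,
                     lb, ub, big = 1e6, tol = 1e-9) {
  n <- length(lb)
  stopifnot(length(ub) == n, length(obj) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  }
  inf_lb <- !is.finite(lb); inf_ub <- !is.finite(ub)
  lb[inf_lb] <- -big; ub[inf_ub] <- big
  d <- ub - lb

  Aeq <- if (is.null(Aeq)) matrix(0, 0, n) else as.matrix(Aeq)
  beq <- if (is.null(beq)) numeric(0) else as.numeric(beq)
  Aineq <- if (is.null(Aineq)) matrix(0, 0, n) else as.matrix(Aineq)
  bineq <- if (is.null(bineq)) numeric(0) else as.numeric(bineq)
  m1 <- nrow(Aeq); m2 <- nrow(Aineq)

  # shift v = lb + x, 0 <= x <= d; vars: x (n), surplus s (m2), ub-slack w (n)
  N <- n + m2 + n
  m <- m1 + m2 + n
  M <- matrix(0, m, N)
  rhs <- numeric(m)
  if (m1 > 0) {
    M[seq_len(m1), seq_len(n)] <- Aeq
    rhs[seq_len(m1)] <- beq - as.numeric(Aeq %*% lb)
  }
  if (m2 > 0) {
    r <- m1 + seq_len(m2)
    M[r, seq_len(n)] <- Aineq
    M[cbind(r, n + seq_len(m2))] <- -1
    rhs[r] <- bineq - as.numeric(Aineq %*% lb)
  }
  r <- m1 + m2 + seq_len(n)
  M[cbind(r, seq_len(n))] <- 1
  M[cbind(r, n + m2 + seq_len(n))] <- 1
  rhs[r] <- d

  neg <- rhs < 0
  M[neg, ] <- -M[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]

  # tableau with artificials; basis starts as the artificials
  Tm <- cbind(M, diag(m), rhs)
  basis <- N + seq_len(m)
  ncol_all <- N + m
  rhs_col <- ncol_all + 1L

  pivot <- function(Tm, zrow, pr, pc) {
    piv <- Tm[pr, pc]
    Tm[pr, ] <- Tm[pr, ] / piv
    for (i in seq_len(nrow(Tm))) {
      if (i != pr && abs(Tm[i, pc]) > tol) Tm[i, ] <- Tm[i, ] - Tm[i, pc] * Tm[pr, ]
    }
    zrow <- zrow - zrow[pc] * Tm[pr, ]
    list(Tm = Tm, zrow = zrow)
  }

  # minimize cost'vars with Bland's rule; returns updated state
  run_simplex <- function(Tm, basis, cost, allowed) {
    zrow <- c(cost, 0)
    for (i in seq_len(m)) {
      ci <- cost[basis[i]]
      if (ci != 0) zrow <- zrow - ci * Tm[i, ]
    }
    repeat {
      enter <- 0L
      for (j in seq_len(ncol_all)) {
        if (allowed[j] && zrow[j] < -1e-8 && !(j %in% basis)) { enter <- j; break }
      }
      if (enter == 0L) break
      best_i <- 0L; best_ratio <- Inf; best_var <- Inf
      for (i in seq_len(m)) {
        a <- Tm[i, enter]
        if (a > tol) {
          ratio <- Tm[i, rhs_col] / a
          if (ratio < best_ratio - 1e-12 ||
              (ratio < best_ratio + 1e-12 && basis[i] < best_var)) {
            best_i <- i; best_ratio <- ratio; best_var <- basis[i]
          }
        }
      }
      if (best_i == 0L) {
        return(list(Tm = Tm, basis = basis, zrow = zrow, unbounded = TRUE))
      }
      res <- pivot(Tm, zrow, best_i, enter)
      Tm <- res$Tm; zrow <- res$zrow
      basis[best_i] <- enter
    }
    list(Tm = Tm, basis = basis, zrow = zrow, unbounded = FALSE)
  }

  # phase 1: minimize sum of artificials
  cost1 <- c(rep(0, N), rep(1, m))
  st <- run_simplex(Tm, basis, cost1, allowed = rep(TRUE, ncol_all))
  Tm <- st$Tm; basis <- st$basis
  phase1 <- sum(Tm[basis > N, rhs_col])
  if (phase1 > 1e-7) {
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  }
  # drive residual zero-valued artificials out of the basis where possible
  for (i in which(basis > N)) {
    pc <- 0L
    for (j in seq_len(N)) {
      if (abs(Tm[i, j]) > 1e-7 && !(j %in% basis)) { pc <- j; break }
    }
    if (pc > 0L) {
      res <- pivot(Tm, rep(0, rhs_col), i, pc)
      Tm <- res$Tm
      basis[i] <- pc
    }
  }

  # phase 2: minimize -obj'x (maximize obj'v); artificials barred
  cost2 <- c(-obj, rep(0, m2 + n), rep(0, m))
  allowed <- c(rep(TRUE, N), rep(FALSE, m))
  st <- run_simplex(Tm, basis, cost2, allowed)
  Tm <- st$Tm; basis <- st$basis

  xfull <- numeric(ncol_all)
  xfull[basis] <- Tm[, rhs_col]
  v <- lb + xfull[seq_len(n)]
  objval <- sum(obj * v)

  if (st$unbounded) {
    return(list(status = "unbounded", objval = Inf, x = NULL))
  }
  # optimum leaning on a synthetic bound for a declared-infinite bound
  at_fake <- (inf_ub & obj > 0 & v > 0.5 * big) |
             (inf_lb & obj < 0 & v < -0.5 * big)
  if (any(at_fake)) {
    return(list(status = "unbounded", objval = Inf, x = NULL))
  }
  list(status = "optimal", objval = objval, x = v)
}
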