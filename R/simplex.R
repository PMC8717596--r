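# Dense two-phase tableau simplex with Bland's anti-cycling rule.
#
# The DEA envelopment and multiplier linear programs solved in this package
# are small (tens of variables, a handful of constraints), so a dense
# tableau method is both adequate and easy to make deterministic. Bland's
# rule guarantees termination under degeneracy, which matters because DEA
# envelopment problems are degenerate by construction (the unit under
# evaluation lies on several binding constraints).

# Solve: optimise c'x subject to A x (dir) b, x >= 0.
# dir is a character vector in {"<=", ">=", "="}.
# Returns list(status, x, value); status one of "optimal", "infeasible",
# "unbounded".
simplex_solve <- function(obj, A, dir, rhs, maximise = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m,
            all(dir %in% c("<=", ">=", "=")))

  # Minimisation internally.
  cost <- if (maximise) -as.numeric(obj) else as.numeric(obj)

  # Make rhs non-negative.
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    dir[neg] <- ifelse(dir[neg] == "<=", ">=",
                       ifelse(dir[neg] == ">=", "<=", "="))
  }

  n_slack <- sum(dir == "<=")
  n_surp <- sum(dir == ">=")
  n_art <- sum(dir != "<=")
  ncol_t <- n + n_slack + n_surp + n_art

  T <- matrix(0, m, ncol_t)
  T[, seq_len(n)] <- A
  basis <- integer(m)
  slack_i <- n
  surp_i <- n + n_slack
  art_i <- n + n_slack + n_surp
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      slack_i <- slack_i + 1L
      T[i, slack_i] <- 1
      basis[i] <- slack_i
    } else {
      if (dir[i] == ">=") {
        surp_i <- surp_i + 1L
        T[i, surp_i] <- -1
      }
      art_i <- art_i + 1L
      T[i, art_i] <- 1
      basis[i] <- art_i
      art_cols <- c(art_cols, art_i)
    }
  }
  b <- as.numeric(rhs)

  pivot <- function(T, b, basis, pr, pc) {
    piv <- T[pr, pc]
    T[pr, ] <- T[pr, ] / piv
    b[pr] <- b[pr] / piv
    for (i in seq_len(nrow(T))) {
      if (i != pr && abs(T[i, pc]) > 0) {
        f <- T[i, pc]
        T[i, ] <- T[i, ] - f * T[pr, ]
        b[i] <- b[i] - f * b[pr]
      }
    }
    basis[pr] <- pc
    list(T = T, b = b, basis = basis)
  }

  run_phase <- function(T, b, basis, cvec, allowed) {
    repeat {
      cb <- cvec[basis]
      # reduced costs
      rc <- cvec - drop(crossprod(T, cb))
      rc[!allowed] <- Inf
      enter_candidates <- which(rc < -tol)
      if (length(enter_candidates) == 0) {
        return(list(T = T, b = b, basis = basis, status = "optimal"))
      }
      pc <- min(enter_candidates)  # Bland: smallest index enters
      col <- T[, pc]
      pos <- which(col > tol)
      if (length(pos) == 0) {
        return(list(T = T, b = b, basis = basis, status = "unbounded"))
      }
      ratios <- b[pos] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      pr <- cand[which.min(basis[cand])]  # Bland: smallest basis index leaves
      st <- pivot(T, b, basis, pr, pc)
      T <- st$T; b <- st$b; basis <- st$basis
    }
  }

  allowed <- rep(TRUE, ncol_t)

  if (n_art > 0) {
    c1 <- rep(0, ncol_t)
    c1[art_cols] <- 1
    # Price out artificial basics so the phase-1 reduced costs start correct.
    ph1 <- run_phase(T, b, basis, c1, allowed)
    if (ph1$status != "optimal") {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    T <- ph1$T; b <- ph1$b; basis <- ph1$basis
    if (sum(b[basis %in% art_cols]) > 1e-7) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    # Drive any residual (degenerate) artificials out of the basis.
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        real_cols <- setdiff(seq_len(ncol_t), art_cols)
        nz <- real_cols[abs(T[i, real_cols]) > tol]
        if (length(nz) > 0) {
          st <- pivot(T, b, basis, i, min(nz))
          T <- st$T; b <- st$b; basis <- st$basis
        }
      }
    }
    allowed[art_cols] <- FALSE
  }

  c2 <- rep(0, ncol_t)
  c2[seq_len(n)] <- cost
  ph2 <- run_phase(T, b, basis, c2, allowed)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  T <- ph2$T; b <- ph2$b; basis <- ph2$basis

  x <- numeric(ncol_t)
  x[basis] <- b
  xout <- x[seq_len(n)]
  val <- sum(cost * xout)
  list(status = "optimal", x = xout, value = if (maximise) -val else val)
}
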