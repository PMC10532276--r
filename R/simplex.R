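# Internal dense two-phase simplex for the small flow LPs.
#
# Maximises c'x subject to  A x (dir) b,  x >= 0, where dir is "<=", ">=" or
# "==" per row. Every flow LP passed here is bounded (each variable carries
# an explicit capacity row), so unboundedness signals a modelling error and
# is still detected and reported. Bland's rule makes the pivot sequence
# deterministic and cycling-free; problem sizes are tens of rows, so the
# full-tableau method is entirely adequate.
lp_simplex <- function(obj, A, dir, rhs, tol = 1e-9, max_iter = 10000L) {
  n <- length(obj)
  stopifnot(ncol(A) == n, nrow(A) == length(dir), length(dir) == length(rhs))
  m <- nrow(A)
  # normalise RHS >= 0
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[neg]]
  }
  n_slack <- sum(dir == "<=")
  n_surp <- sum(dir == ">=")
  n_art <- sum(dir != "<=")
  N <- n + n_slack + n_surp + n_art
  Tb <- matrix(0, m, N)
  Tb[, seq_len(n)] <- A
  basis <- integer(m)
  s_i <- n; p_i <- n + n_slack; a_i <- n + n_slack + n_surp
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      s_i <- s_i + 1L; Tb[i, s_i] <- 1; basis[i] <- s_i
    } else if (dir[i] == ">=") {
      p_i <- p_i + 1L; Tb[i, p_i] <- -1
      a_i <- a_i + 1L; Tb[i, a_i] <- 1; basis[i] <- a_i
    } else {
      a_i <- a_i + 1L; Tb[i, a_i] <- 1; basis[i] <- a_i
    }
  }
  b <- rhs
  art_cols <- seq.int(n + n_slack + n_surp + 1L, length.out = n_art)

  pivot <- function(r, cc) {
    piv <- Tb[r, cc]
    Tb[r, ] <<- Tb[r, ] / piv
    b[r] <<- b[r] / piv
    for (i in seq_len(m)) {
      if (i != r && abs(Tb[i, cc]) > 0) {
        f <- Tb[i, cc]
        Tb[i, ] <<- Tb[i, ] - f * Tb[r, ]
        b[i] <<- b[i] - f * b[r]
      }
    }
    basis[r] <<- cc
  }

  run_phase <- function(cvec, allowed) {
    for (it in seq_len(max_iter)) {
      red <- cvec - as.numeric(cvec[basis] %*% Tb)   # reduced costs
      cand <- which(allowed & red > tol)
      if (!length(cand)) return("optimal")
      j <- cand[1L]                                  # Bland: smallest index
      rows <- which(Tb[, j] > tol)
      if (!length(rows)) return("unbounded")
      ratio <- b[rows] / Tb[rows, j]
      rmin <- rows[ratio <= min(ratio) + 1e-12]
      r <- rmin[order(basis[rmin])][1L]              # Bland on leaving var
      pivot(r, j)
    }
    stop("simplex iteration limit exceeded", call. = FALSE)
  }

  if (n_art > 0) {
    c1 <- rep(0, N); c1[art_cols] <- -1
    st <- run_phase(c1, allowed = rep(TRUE, N))
    infeas <- -sum(c1[basis] * b)
    if (st != "optimal" || infeas > 1e-7) {
      return(list(status = "infeasible", x = rep(0, n), value = -Inf))
    }
    # drive any degenerate basic artificial out of the basis
    for (r in which(basis %in% art_cols)) {
      repl <- which(abs(Tb[r, seq_len(n + n_slack + n_surp)]) > tol)
      if (length(repl)) pivot(r, repl[1L])
      # else: redundant row; the artificial stays basic at value 0 and is
      # barred from entering, so it can never become positive again
    }
  }
  c2 <- c(obj, rep(0, n_slack + n_surp), rep(0, n_art))
  allowed <- rep(TRUE, N); allowed[art_cols] <- FALSE
  st <- run_phase(c2, allowed)
  if (st == "unbounded") {
    return(list(status = "unbounded", x = rep(0, n), value = Inf))
  }
  x <- rep(0, n)
  in_x <- basis <= n
  x[basis[in_x]] <- b[in_x]
  list(status = "optimal", x = x, value = sum(obj * x))
}
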