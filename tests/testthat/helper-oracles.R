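# Independent numerical oracles used to cross-check the package's
# SVD-based routes. These deliberately use different machinery:
# pivoted-QR ranks and a least-squares null-space projector with
# random-vector sampling.

# Numerical rank via pivoted QR (LAPACK), independent of rank_tol()'s SVD.
oracle_rank <- function(M, tol = 1e-9) {
  M <- as.matrix(M)
  if (length(M) == 0L || all(M == 0)) return(0L)
  qr(M, tol = tol, LAPACK = FALSE)$rank
}

# Projector onto the null space of S, built from a QR basis of the row
# space: P = I - Q Q' with Q an orthonormal basis of span(rows of S).
oracle_null_projector <- function(S) {
  S <- as.matrix(S)
  n <- ncol(S)
  if (nrow(S) == 0L) return(diag(n))
  qrd <- qr(t(S))
  r <- qrd$rank
  if (r == 0L) return(diag(n))
  Q <- qr.Q(qrd)[, seq_len(r), drop = FALSE]
  diag(n) - Q %*% t(Q)
}

# Flux-coupling oracle by sampling: draw random vectors, project into the
# steady-state space, and test whether the (v_i, v_j) sample cloud is
# one-dimensional (fixed flux ratio) with neither coordinate identically 0.
oracle_fully_coupled <- function(S, i, j, n_samples = 64, seed = 42,
                                 tol = 1e-7) {
  P <- oracle_null_projector(S)
  set.seed(seed)
  X <- P %*% matrix(rnorm(ncol(P) * n_samples), ncol = n_samples)
  vi <- X[i, ]
  vj <- X[j, ]
  scale_ref <- max(abs(X))
  if (max(abs(vi)) <= tol * scale_ref || max(abs(vj)) <= tol * scale_ref) {
    return(NA)  # blocked reaction: coupling undefined
  }
  cloud <- rbind(vi, vj)
  d <- svd(cloud, nu = 0, nv = 0)$d
  d[2] <= 1e-7 * d[1]
}

oracle_blocked <- function(S, i, n_samples = 64, seed = 42, tol = 1e-7) {
  P <- oracle_null_projector(S)
  set.seed(seed)
  X <- P %*% matrix(rnorm(ncol(P) * n_samples), ncol = n_samples)
  max(abs(X[i, ])) <= tol * max(1, max(abs(X)))
}

# Full-coupling classes on all non-blocked reactions, by pairwise oracle.
oracle_coupling_classes <- function(S) {
  n <- ncol(S)
  ok <- which(!vapply(seq_len(n), function(i) oracle_blocked(S, i), logical(1)))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (a in ok) for (b in ok) {
    if (a < b && isTRUE(oracle_fully_coupled(S, a, b))) {
      parent[find(b)] <- find(a)
    }
  }
  roots <- vapply(ok, find, integer(1))
  unname(split(ok, roots))
}

# Upper-tail hypergeometric by Monte-Carlo resampling.
oracle_hypergeom_mc <- function(n_universe, n_A, n_B, n_overlap,
                                n_draws = 1e4, seed = 7) {
  set.seed(seed)
  hits <- replicate(n_draws, {
    draw <- sample.int(n_universe, n_B)
    sum(draw <= n_A) >= n_overlap
  })
  mean(hits)
}

# Model built directly from equation strings (test shorthand).
model_from_equations <- function(eqs, gprs = NULL) {
  rxns <- lapply(seq_along(eqs), function(k) {
    parsed <- metsubnet:::parse_reaction_equation(eqs[[k]], names(eqs)[k])
    list(id = names(eqs)[k],
         stoichiometry = parsed$stoichiometry,
         reversible = parsed$reversible,
         gpr = if (is.null(gprs)) NULL else parse_gpr(gprs[[k]]),
         subsystem = "")
  })
  new_metabolic_model(rxns)
}

# Small open chain: in -> A -> B -> out (A, B internal).
chain3_model <- function() {
  model_from_equations(c(
    R1 = "x_in[b] => A[c]",
    R2 = "A[c] => B[c]",
    R3 = "B[c] => x_out[b]"
  ))
}

# Diamond: two length-2 parallel branches between shared endpoints.
diamond_model <- function() {
  model_from_equations(c(
    EX_IN = "x_in[b] => A[c]",
    AB = "A[c] => B[c]",
    BD = "B[c] => D[c]",
    AC = "A[c] => C[c]",
    CD = "C[c] => D[c]",
    EX_OUT = "D[c] => x_out[b]"
  ))
}
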