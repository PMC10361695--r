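# Independent oracles used by the tests. These deliberately use different
# formulations/algorithms than the package implementation they check.

# ---------------------------------------------------------------------------
# 1D spherically-symmetric BVP oracle for the pressurized thick-walled sphere
# (inner radius a with internal pressure p, outer radius b fixed), same
# exponent-2 Ogden energy. Formulated in radial/tangential principal
# stretches and solved by ODE shooting (deSolve) on the inner displacement —
# a completely different discretization than the 3D FE solver.
sphere_oracle <- function(a, b, p, mu, kappa, n_grid = 400) {
  psi_hat <- function(lr, lt) {
    J <- lr * lt^2
    mu / 2 * (J^(-2 / 3) * (lr^2 + 2 * lt^2) - 3) + kappa / 4 * (J^2 - 1 - 2 * log(J))
  }
  h <- 1e-6
  P_r <- function(lr, lt) (psi_hat(lr + h, lt) - psi_hat(lr - h, lt)) / (2 * h)
  P_t <- function(lr, lt) (psi_hat(lr, lt + h) - psi_hat(lr, lt - h)) / (4 * h)  # per each of 2 lt
  dPr_dlr <- function(lr, lt) (P_r(lr + h, lt) - P_r(lr - h, lt)) / (2 * h)
  dPr_dlt <- function(lr, lt) (P_r(lr, lt + h) - P_r(lr, lt - h)) / (2 * h)
  rhs <- function(R, y, parms) {
    r <- y[1]; lr <- y[2]
    lt <- r / R
    num <- -2 * (P_r(lr, lt) - P_t(lr, lt)) / R - dPr_dlt(lr, lt) * (lr - lt) / R
    list(c(lr, num / dPr_dlr(lr, lt)))
  }
  # inner BC: sigma_rr(a) = -p  =>  P_r = -p * lt^2 ; solve lr given r(a)
  lr_inner <- function(ra) {
    lt <- ra / a
    stats::uniroot(function(lr) P_r(lr, lt) + p * lt^2, c(0.2, 3), tol = 1e-12)$root
  }
  shoot <- function(ra) {
    y0 <- c(ra, lr_inner(ra))
    out <- deSolve::ode(y0, seq(a, b, length.out = n_grid), rhs, NULL,
                        method = "ode45", atol = 1e-10, rtol = 1e-10)
    out
  }
  ra <- stats::uniroot(function(ra) { o <- shoot(ra); o[nrow(o), 2] - b },
                       c(a - 0.2 * a, a + 0.5 * a), tol = 1e-10)$root
  out <- shoot(ra)
  list(R = out[, 1], r = out[, 2], u = out[, 2] - out[, 1], u_inner = ra - a)
}

# ---------------------------------------------------------------------------
# semi-analytic homogeneous uniaxial-stress state: Cauchy axial stress s_ax
# prescribed (lateral free), solves for (lambda_ax, lambda_lat)
uniaxial_state <- function(s_ax, mu, kappa) {
  sig <- function(l) {  # principal Cauchy stresses for diag(l1,l2,l3)
    st <- decompose_deformation(diag(l))
    diag(cauchy_stress(st, ogden_params(mu, kappa)))
  }
  f <- function(x) {
    s <- sig(c(x[1], x[2], x[2]))
    c(s[1] - s_ax, s[2])
  }
  x <- c(1, 1)
  for (i in 1:60) {  # damped Newton with numeric Jacobian
    fx <- f(x)
    J <- matrix(0, 2, 2); h <- 1e-7
    for (j in 1:2) { xp <- x; xp[j] <- xp[j] + h; J[, j] <- (f(xp) - fx) / h }
    dx <- solve(J, -fx)
    x <- x + dx
    if (max(abs(fx)) < 1e-13) break
  }
  list(lambda_ax = x[1], lambda_lat = x[2])
}

# ---------------------------------------------------------------------------
# brute-force ray-marching thickness oracle: small steps along the normal,
# point-in-tet location at every step, stopping at the first step located in
# a non-WMH element. Location uses precomputed barycentric matrices (a
# marching algorithm, independent of the interval-clipping implementation).
tet_locator <- function(mesh) {
  M <- nrow(mesh$tets)
  inv <- vector("list", M)
  X1 <- mesh$nodes[mesh$tets[, 1], , drop = FALSE]
  for (e in seq_len(M)) {
    X <- mesh$nodes[mesh$tets[e, ], ]
    D <- cbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])
    inv[[e]] <- tryCatch(solve(D), error = function(err) NULL)
  }
  function(x, tol = 1e-9) {
    for (e in seq_len(M)) {
      if (is.null(inv[[e]])) next
      lam <- inv[[e]] %*% (x - X1[e, ])
      if (all(lam >= -tol) && sum(lam) <= 1 + tol) return(e)
    }
    0L
  }
}

thickness_oracle <- function(mesh, x0, dir, step = 0.05, max_dist = 50,
                             locate = tet_locator(mesh)) {
  last_wmh <- 0L
  t <- step / 2
  while (t < max_dist) {
    e <- locate(x0 + t * dir)
    if (e > 0) {
      if (mesh$region[e] == "WMH") last_wmh <- e else break
    }
    t <- t + step
  }
  if (last_wmh == 0L) return(0)
  verts <- mesh$nodes[mesh$tets[last_wmh, ], ]
  sqrt(max(rowSums((verts - matrix(x0, 4, 3, byrow = TRUE))^2)))
}

# ---------------------------------------------------------------------------
# breadth-first-search oracle for the WMH / adjacent wall-face ring expansion
bfs_rings_oracle <- function(tris, start_faces, rings) {
  # adjacency by shared edge, recomputed naively
  nfaces <- nrow(tris)
  share_edge <- function(f1, f2) length(intersect(tris[f1, ], tris[f2, ])) >= 2
  current <- start_faces
  seen <- rep(FALSE, nfaces)
  seen[start_faces] <- TRUE
  collected <- integer(0)
  for (r in seq_len(rings)) {
    nxt <- integer(0)
    for (f in seq_len(nfaces)) {
      if (seen[f]) next
      for (c in current) if (share_edge(f, c)) { nxt <- c(nxt, f); break }
    }
    if (!length(nxt)) break
    seen[nxt] <- TRUE
    collected <- c(collected, nxt)
    current <- nxt
  }
  collected
}

# ---------------------------------------------------------------------------
# triple-loop face-counting oracle for CSF-adjacent component removal
csf_removal_oracle <- function(mask, csf, frac = 0.5) {
  d <- dim(mask)
  lab <- label_components(mask, 26)   # labeling semantics pinned separately
  out <- mask
  for (cid in seq_len(max(lab, 0))) {
    nb <- 0; nc <- 0
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (lab[i, j, k] != cid) next
      for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) {
          nb <- nb + 1
        } else if (lab[ii, jj, kk] != cid) {
          nb <- nb + 1
          if (csf[ii, jj, kk]) nc <- nc + 1
        }
      }
    }
    if (nb > 0 && nc / nb > frac) out[lab == cid] <- FALSE
  }
  out
}
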