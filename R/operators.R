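# Discrete operators on the staggered (MAC) grid.
#
# Layout (index space i = axial xi, j = transverse eta):
#   p : cell centres,              i = 1..nz,   j = 1..nr
#   u : axial velocity, xi-faces,  i = 1..nz+1, j = 1..nr
#   v : transverse velocity,       i = 1..nz,   j = 1..nr+1 (eta-faces)
# Mapped kinds use r(z, eta) = Rin(z) + eta * gap(z); physical derivatives are
# composed by the chain rule  d/dz|_r = d/dxi - a d/deta  with a = s / gap,
# s = dr/dz|_eta = Rin'(z) (1 - eta)  (outer wall fixed), and
# d/dr = (1/gap) d/deta (exact, since gap depends on z only).
# The divergence is volume-integrated and conservative: cell fluxes use the
# exact slanted-face flux  integral of (v - s u) dA,  so the discrete Poisson
# operator D*G has left null-vector exactly 1 and the projection zeroes the
# divergence to solver precision.
#
# All assembled operators are in SI units (m, s, kg); the mesh stores mm.

MM <- 1e-3

ROLE_INT <- 0L # interior: gets a momentum equation
ROLE_DIR <- 1L # Dirichlet: wall (0) or tagged open boundary (time-varying)
ROLE_SOLID <- 2L # face fully inside solid / outside the domain

grid_roles <- function(mesh) {
  nz <- mesh$nz
  nr <- mesh$nr
  fl <- mesh$mask
  fluid_at <- function(i, j) {
    ok <- i >= 1 & i <= nz & j >= 1 & j <= nr
    out <- logical(length(i))
    out[ok] <- fl[cbind(i[ok], j[ok])]
    out
  }
  gu <- expand.grid(i = 1:(nz + 1), j = 1:nr)
  W <- fluid_at(gu$i - 1, gu$j)
  E <- fluid_at(gu$i, gu$j)
  role_u <- matrix(
    ifelse(W & E, ROLE_INT, ifelse(W | E, ROLE_DIR, ROLE_SOLID)),
    nz + 1, nr
  )
  gv <- expand.grid(i = 1:nz, j = 1:(nr + 1))
  S <- fluid_at(gv$i, gv$j - 1)
  N <- fluid_at(gv$i, gv$j)
  role_v <- matrix(
    ifelse(S & N, ROLE_INT, ifelse(S | N, ROLE_DIR, ROLE_SOLID)),
    nz, nr + 1
  )
  list(u = role_u, v = role_v)
}

# Same-grid stencil assembly with ghost handling. `terms` is a list of
# list(di, dj, coef) with coef a full-grid matrix (or scalar), evaluated at
# the row's point. References that leave the fluid region are reflected back
# to the row's own column/row with sign `refl_sign` (-1: antisymmetric ghost
# for no-slip velocity; +1: symmetric/Neumann mirror).
stencil_matrix <- function(NI, NJ, interior, role, terms, refl_sign = -1) {
  idx <- function(i, j) i + (j - 1L) * NI
  rows_ij <- which(interior, arr.ind = TRUE)
  ri <- rows_ij[, 1]
  rj <- rows_ij[, 2]
  rows <- idx(ri, rj)
  solid_at <- function(i, j) {
    ok <- i >= 1 & i <= NI & j >= 1 & j <= NJ
    out <- rep(TRUE, length(i)) # out of bounds counts as solid
    out[ok] <- role[cbind(i[ok], j[ok])] == ROLE_SOLID
    out
  }
  II <- vector("list", length(terms))
  JJ <- vector("list", length(terms))
  XX <- vector("list", length(terms))
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    ti <- ri + tm$di
    tj <- rj + tm$dj
    sgn <- rep(1, length(ri))
    if (tm$dj != 0) { # eta reflection about the intervening eta-face
      bad <- tj < 1 | tj > NJ | solid_at(ti, tj)
      tj[bad] <- rj[bad]
      sgn[bad] <- sgn[bad] * refl_sign
    }
    if (tm$di != 0) { # xi reflection about the intervening xi-face
      bad <- ti < 1 | ti > NI | solid_at(ti, tj)
      ti[bad] <- ri[bad]
      sgn[bad] <- sgn[bad] * refl_sign
    }
    cf <- tm$coef
    val <- if (is.matrix(cf)) cf[cbind(ri, rj)] else rep(cf, length(ri))
    II[[k]] <- rows
    JJ[[k]] <- idx(ti, tj)
    XX[[k]] <- sgn * val
  }
  Matrix::sparseMatrix(
    i = unlist(II), j = unlist(JJ), x = unlist(XX),
    dims = c(NI * NJ, NI * NJ)
  )
}

# Mapping coefficient fields at the points of one staggered grid (SI units).
# z_at: "f" for u-grid (xi-faces), "c" for v/p grids; eta values supplied.
map_fields <- function(mesh, z_at, eta) {
  if (z_at == "f") {
    Rin <- mesh$Rin_f
    dR <- mesh$dRin_f
    d2R <- mesh$d2Rin_f
    G <- mesh$gap_f
  } else {
    Rin <- mesh$Rin_c
    dR <- mesh$dRin_c
    d2R <- mesh$d2Rin_c
    G <- mesh$gap_c
  }
  nzp <- length(Rin)
  ne <- length(eta)
  one <- rep(1, ne)
  Rin_m <- outer(Rin * MM, one)
  G_m <- outer(G * MM, one)
  eta_m <- outer(rep(1, nzp), eta)
  r <- Rin_m + eta_m * G_m # m
  s <- outer(dR, one) * (1 - eta_m) # dimensionless dr/dz
  a <- s / G_m # 1/m
  a_eta <- -outer(dR, one) / G_m # 1/m (per unit eta)
  # d a / d xi = (1-eta) [Rin''/G + Rin'^2/G^2]; Rin'' in 1/mm -> 1/m
  a_xi <- (1 - eta_m) * (outer(d2R / MM, one) / G_m + outer(dR, one)^2 / G_m^2)
  list(r = r, s = s, a = a, a_eta = a_eta, a_xi = a_xi, G = G_m)
}

# Assemble all discrete operators and factorizations for a mesh + fluid +
# time step. Returns an environment used by the IPCS stepper.
assemble_ops <- function(mesh, props, dt, convection = TRUE) {
  nz <- mesh$nz
  nr <- mesh$nr
  NIu <- nz + 1L
  NJv <- nr + 1L
  Nu <- NIu * nr
  Nv <- nz * NJv
  Np <- nz * nr
  dxi <- mesh$dz * MM
  deta <- mesh$deta
  axisym <- mesh$coord == "axisym"
  depth <- if (axisym) NA_real_ else mesh$depth_mm * MM
  nu <- props$kinematic_viscosity
  rho <- props$density

  roles <- grid_roles(mesh)
  int_u <- roles$u == ROLE_INT
  int_v <- roles$v == ROLE_INT
  fluid <- mesh$mask
  # mark tagged open boundary faces (they are ROLE_DIR; remember which)
  open_u <- matrix(FALSE, NIu, nr)
  open_v <- matrix(FALSE, nz, NJv)
  for (b in mesh$boundaries) {
    if (b$comp == "u") open_u[cbind(b$i, b$j)] <- TRUE else open_v[cbind(b$i, b$j)] <- TRUE
  }

  mu_ <- map_fields(mesh, "f", mesh$eta_c) # u points
  mv_ <- map_fields(mesh, "c", mesh$eta_f) # v points
  mp_ <- map_fields(mesh, "c", mesh$eta_c) # cell centres
  mapped <- any(mesh$dRin_f != 0) || any(mesh$dRin_c != 0)

  idx_u <- function(i, j) i + (j - 1L) * NIu
  idx_v <- function(i, j) i + (j - 1L) * nz
  idx_p <- function(i, j) i + (j - 1L) * nz

  ## ---- same-grid derivative term sets ------------------------------------
  lap_terms <- function(mf, NI, NJ) {
    a <- mf$a
    G <- mf$G
    r <- mf$r
    cDxx <- 1 / dxi^2
    cDee <- (a^2 + 1 / G^2) / deta^2
    cDe <- (a * mf$a_eta - mf$a_xi) / (2 * deta)
    if (axisym) cDe <- cDe + 1 / (r * G) / (2 * deta)
    tms <- list(
      list(di = -1L, dj = 0L, coef = cDxx),
      list(di = 0L, dj = 0L, coef = -2 * cDxx - 2 * (a^2 + 1 / G^2) / deta^2),
      list(di = +1L, dj = 0L, coef = cDxx),
      list(di = 0L, dj = -1L, coef = cDee - cDe),
      list(di = 0L, dj = +1L, coef = cDee + cDe)
    )
    if (mapped) {
      cXE <- -2 * a / (4 * dxi * deta)
      tms <- c(tms, list(
        list(di = +1L, dj = +1L, coef = cXE),
        list(di = -1L, dj = -1L, coef = cXE),
        list(di = +1L, dj = -1L, coef = -cXE),
        list(di = -1L, dj = +1L, coef = -cXE)
      ))
    }
    tms
  }
  dz_terms <- function(mf) { # central d/dz = Dxi - a Deta
    a <- mf$a
    list(
      list(di = +1L, dj = 0L, coef = 1 / (2 * dxi)),
      list(di = -1L, dj = 0L, coef = -1 / (2 * dxi)),
      list(di = 0L, dj = +1L, coef = -a / (2 * deta)),
      list(di = 0L, dj = -1L, coef = a / (2 * deta))
    )
  }
  de_terms <- function(mf) { # d/dr = (1/G) Deta
    list(
      list(di = 0L, dj = +1L, coef = 1 / (mf$G * 2 * deta)),
      list(di = 0L, dj = -1L, coef = -1 / (mf$G * 2 * deta))
    )
  }

  Lap_u <- stencil_matrix(NIu, nr, int_u, roles$u, lap_terms(mu_, NIu, nr))
  Lap_v <- stencil_matrix(nz, NJv, int_v, roles$v, lap_terms(mv_, nz, NJv))
  if (axisym) { # extra -1/r^2 on the radial momentum
    dg <- numeric(Nv)
    ij <- which(int_v, arr.ind = TRUE)
    dg[idx_v(ij[, 1], ij[, 2])] <- -1 / mv_$r[ij]^2
    Lap_v <- Lap_v + Matrix::Diagonal(Nv, dg)
  }
  Dz_u <- stencil_matrix(NIu, nr, int_u, roles$u, dz_terms(mu_))
  De_u <- stencil_matrix(NIu, nr, int_u, roles$u, de_terms(mu_))
  Dz_v <- stencil_matrix(nz, NJv, int_v, roles$v, dz_terms(mv_))
  De_v <- stencil_matrix(nz, NJv, int_v, roles$v, de_terms(mv_))

  ## ---- pressure gradient (p -> u, v), zero rows at non-interior ----------
  gz_trip <- local({
    ij <- which(int_u, arr.ind = TRUE)
    i <- ij[, 1]
    j <- ij[, 2]
    rows <- idx_u(i, j)
    # compact part: (p_E - p_W)/dxi ; cells E=(i,j), W=(i-1,j)
    II <- c(rows, rows)
    JJ <- c(idx_p(i, j), idx_p(i - 1L, j))
    XX <- c(rep(1 / dxi, length(rows)), rep(-1 / dxi, length(rows)))
    if (mapped) {
      # cross part: -a * p_eta, p_eta from 4 cells with Neumann mirror
      au <- mu_$a[ij]
      for (dd in list(
        c(0L, +1L, +1), c(-1L, +1L, +1),
        c(0L, -1L, -1), c(-1L, -1L, -1)
      )) {
        ci <- i + dd[1]
        cj <- j + dd[2]
        sg <- dd[3]
        refl <- cj < 1 | cj > nr
        cj[refl] <- j[refl] # Neumann mirror (+1)
        II <- c(II, rows)
        JJ <- c(JJ, idx_p(ci, cj))
        XX <- c(XX, -au * sg / (4 * deta))
      }
    }
    list(i = II, j = JJ, x = XX)
  })
  Gz <- Matrix::sparseMatrix(
    i = gz_trip$i, j = gz_trip$j, x = gz_trip$x,
    dims = c(Nu, Np)
  )
  gr_trip <- local({
    ij <- which(int_v, arr.ind = TRUE)
    i <- ij[, 1]
    j <- ij[, 2]
    rows <- idx_v(i, j)
    cf <- 1 / (mv_$G[ij] * deta)
    list(
      i = c(rows, rows),
      j = c(idx_p(i, j), idx_p(i, j - 1L)),
      x = c(cf, -cf)
    )
  })
  Gr <- Matrix::sparseMatrix(
    i = gr_trip$i, j = gr_trip$j, x = gr_trip$x,
    dims = c(Nv, Np)
  )

  ## ---- conservative volume-integrated divergence -------------------------
  # xi-face areas at u points (m^2): axisym 2 pi r G deta, planar depth G deta
  Au <- if (axisym) 2 * pi * mu_$r * mu_$G * deta else depth * mu_$G * deta
  # eta-face areas at v points (m^2): axisym 2 pi r dz, planar depth dz
  Av <- if (axisym) 2 * pi * mv_$r * dxi else matrix(depth * dxi, nz, NJv)
  div_trip <- local({
    ij <- which(fluid, arr.ind = TRUE)
    i <- ij[, 1]
    j <- ij[, 2]
    rows <- idx_p(i, j)
    II <- JJ <- XX <- list()
    k <- 0
    add <- function(cols, vals) {
      k <<- k + 1
      II[[k]] <<- rows
      JJ[[k]] <<- cols
      XX[[k]] <<- vals
    }
    # xi faces: +E -W
    add(idx_u(i + 1L, j), Au[cbind(i + 1L, j)])
    add(idx_u(i, j), -Au[cbind(i, j)])
    # eta faces: v part (+N -S); wall and open faces: v value is the BC (0 at
    # walls), so including the v term is exact there too
    add(Nu + idx_v(i, j + 1L), Av[cbind(i, j + 1L)])
    add(Nu + idx_v(i, j), -Av[cbind(i, j)])
    if (mapped) {
      # slant correction -s*ubar on interior eta faces only (exactly zero on
      # walls by no-slip; open eta faces occur only in unmapped meshes)
      sN <- mv_$s[cbind(i, j + 1L)] * ifelse(j + 1L <= nr, 1, 0)
      sS <- mv_$s[cbind(i, j)] * ifelse(j >= 2, 1, 0)
      for (uo in list(c(0L, -1L), c(0L, 0L), c(1L, -1L), c(1L, 0L))) {
        # north face (i, j+1): ubar from u(i+uo1, j+1+uo2 with uo2 in {-1,0});
        # indices are clamped where the coefficient is zero (wall faces)
        add(
          idx_u(i + uo[1], pmin(j + 1L + uo[2], nr)),
          -sN * Av[cbind(i, j + 1L)] / 4
        )
        add(
          idx_u(i + uo[1], pmax(j + uo[2], 1L)),
          +sS * Av[cbind(i, j)] / 4
        )
      }
    }
    list(i = unlist(II), j = unlist(JJ), x = unlist(XX))
  })
  Dmat <- Matrix::sparseMatrix(
    i = div_trip$i, j = div_trip$j, x = div_trip$x,
    dims = c(Np, Nu + Nv)
  )

  ## ---- Poisson operator, implicit operators, factorizations --------------
  Gfull <- rbind(Gz, Gr)
  Ap <- Dmat %*% Gfull
  fluid_idx <- which(as.vector(fluid))
  solid_idx <- setdiff(seq_len(Np), fluid_idx)
  pin <- fluid_idx[1]
  fix <- c(solid_idx, pin)
  Ap <- Matrix::drop0(Ap)
  if (length(fix)) {
    Ap[fix, ] <- 0
    Ap[cbind(fix, fix)] <- 1
  }
  LUp <- Matrix::lu(Ap)

  diag_u <- ifelse(as.vector(int_u), 1 / dt, 1)
  A_u <- Matrix::Diagonal(Nu, diag_u) - nu * Lap_u
  diag_v <- ifelse(as.vector(int_v), 1 / dt, 1)
  A_v <- Matrix::Diagonal(Nv, diag_v) - nu * Lap_v
  LUu <- Matrix::lu(A_u)
  LUv <- Matrix::lu(A_v)

  ## ---- velocity interpolation matrices for convection --------------------
  Iv2u <- local({
    ij <- which(int_u, arr.ind = TRUE)
    i <- ij[, 1]
    j <- ij[, 2]
    rows <- rep(idx_u(i, j), 4)
    cols <- c(
      idx_v(i - 1L, j), idx_v(i - 1L, j + 1L),
      idx_v(i, j), idx_v(i, j + 1L)
    )
    Matrix::sparseMatrix(
      i = rows, j = cols, x = rep(0.25, length(rows)),
      dims = c(Nu, Nv)
    )
  })
  Iu2v <- local({
    ij <- which(int_v, arr.ind = TRUE)
    i <- ij[, 1]
    j <- ij[, 2]
    rows <- rep(idx_v(i, j), 4)
    cols <- c(
      idx_u(i, j - 1L), idx_u(i, j),
      idx_u(i + 1L, j - 1L), idx_u(i + 1L, j)
    )
    Matrix::sparseMatrix(
      i = rows, j = cols, x = rep(0.25, length(rows)),
      dims = c(Nv, Nu)
    )
  })

  ## ---- cell-centre interpolation and volumes -----------------------------
  Vol <- if (axisym) {
    2 * pi * mp_$r * mp_$G * deta * dxi
  } else {
    depth * mp_$G * deta * dxi
  }
  Vol[!fluid] <- 0

  list(
    mesh = mesh, props = props, dt = dt, convection = convection,
    nz = nz, nr = nr, NIu = NIu, NJv = NJv, Nu = Nu, Nv = Nv, Np = Np,
    dxi = dxi, deta = deta, axisym = axisym, depth = depth,
    roles = roles, int_u = int_u, int_v = int_v, open_u = open_u,
    open_v = open_v, fluid = fluid, fluid_idx = fluid_idx, pin = pin,
    map_u = mu_, map_v = mv_, map_p = mp_,
    Lap_u = Lap_u, Lap_v = Lap_v, Dz_u = Dz_u, De_u = De_u,
    Dz_v = Dz_v, De_v = De_v, Gz = Gz, Gr = Gr, Dmat = Dmat, Ap = Ap,
    LUp = LUp, A_u = A_u, A_v = A_v, LUu = LUu, LUv = LUv,
    Iv2u = Iv2u, Iu2v = Iu2v, Au = Au, Av = Av, Vol = Vol
  )
}

# Interpolate staggered velocities to cell centres; returns list(uc, vc)
# as nz x nr matrices (m/s), zero on solid cells.
cell_velocities <- function(ops, u, v) {
  nz <- ops$nz
  nr <- ops$nr
  um <- matrix(u, ops$NIu, nr)
  vm <- matrix(v, nz, ops$NJv)
  uc <- (um[1:nz, , drop = FALSE] + um[2:(nz + 1), , drop = FALSE]) / 2
  vc <- (vm[, 1:nr, drop = FALSE] + vm[, 2:(nr + 1), drop = FALSE]) / 2
  uc[!ops$fluid] <- 0
  vc[!ops$fluid] <- 0
  list(uc = uc, vc = vc)
}
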