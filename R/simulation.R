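# The simulation engine: mutable state registries, the per-step update loop
# (propagate -> boundaries -> pair sweep -> barostat -> reactions), and the
# reaction execution semantics.
#
# Step ordering: positions/orientations are updated first (using the forces
# accumulated in the previous step's sweep), then boundary conditions are
# applied, then one sweep over all neighbor pairs computes forces, the virial
# and the candidate bimolecular events, then expired unimolecular timers are
# collected, and finally reactions are executed in uniformly random order.
# Inter-particle distances and forces are NOT recomputed after reactions:
# newly created products diffuse force-free in their first step (binding
# bonds are the exception; the bond force acts from the next sweep on, with
# the rest length fixed at execution time).

PKEY <- 1024  # particle key = molecule id * PKEY + particle slot

#' Create a simulation
#'
#' @param box box edge lengths (3-vector or scalar, nm); the box is centered
#'   on the origin.
#' @param dt integration time step (ns).
#' @param boundary `"periodic"`, `"repulsive"` or `"fixed_concentration"`.
#' @param temperature solvent temperature (K).
#' @param viscosity solvent viscosity (kJ ns/(mol nm^3)), see
#'   [hydro_params()].
#' @param seed integer seed; [run_simulation()] seeds the RNG with it, so
#'   equal seeds give bit-identical trajectories.
#' @return an environment of class `rid_sim`.
#' @export
new_simulation <- function(box, dt, boundary = "periodic",
                           temperature = 293.15, viscosity = 0.6022,
                           seed = NULL) {
  stopifnot(dt > 0)
  sim <- new.env(parent = emptyenv())
  sim$box <- rep_len(as.numeric(box), 3)
  sim$dt <- dt
  sim$params <- hydro_params(temperature, viscosity)
  sim$kT <- sim$params$kT
  sim$boundary <- boundary_spec(boundary, sim$box)
  sim$seed <- seed
  sim$t <- 0

  sim$types <- list()          # molecule types by name (augmented)
  sim$ptype_names <- "void"    # particle type registry; "void" = inert
  sim$potentials <- list()     # "i|j" -> pair_potential
  sim$pot_dirty <- TRUE
  sim$bi <- list()             # "i|j" (ptype ids) -> list of paths
  sim$uni_mol <- list()        # molecule type name -> list of paths
  sim$uni_particle <- list()   # particle type name -> list of paths
  sim$bonds <- list()
  sim$next_bond <- 1L
  sim$compartments <- list()
  sim$barostat <- NULL
  sim$wall_k <- 100            # harmonic mesh/bead contact stiffness

  cap <- 256L
  sim$cap <- cap
  sim$n <- 0L
  sim$pos <- matrix(0, cap, 3)
  sim$quat <- matrix(0, cap, 4)
  sim$img <- matrix(0, cap, 3)
  sim$tid <- integer(cap)
  sim$ids <- integer(cap)
  sim$tri <- integer(cap)
  sim$comp <- integer(cap)
  sim$Fm <- matrix(0, cap, 3)
  sim$Tq <- matrix(0, cap, 3)
  sim$timer <- rep(Inf, cap)
  sim$ktot <- numeric(cap)
  sim$pov <- vector("list", cap)  # per-molecule particle type overrides
  sim$id2row <- integer(1024)
  sim$next_id <- 1L
  sim$count <- integer(0)
  sim$virial <- 0
  sim$energy <- 0
  sim$pressure <- NA_real_
  sim$events <- list()
  class(sim) <- "rid_sim"
  sim
}

#' @export
print.rid_sim <- function(x, ...) {
  cat(sprintf("<rid_sim> t = %.4g ns, %d molecule(s), box %s nm, %s boundary\n",
              x$t, x$n, paste(signif(x$box, 4), collapse = " x "),
              x$boundary$kind))
  for (ty in x$types)
    cat(sprintf("  %s: %d\n", ty$name, x$count[ty$id]))
  invisible(x)
}

pt_id <- function(sim, name) {
  i <- match(name, sim$ptype_names)
  if (is.na(i)) {
    sim$ptype_names <- c(sim$ptype_names, name)
    i <- length(sim$ptype_names)
    sim$pot_dirty <- TRUE
  }
  i
}

#' Register a molecule type with a simulation
#'
#' @param sim a [new_simulation()] object.
#' @param mtype a [define_molecule_type()] object.
#' @param mesh_collision how volume molecules of this type interact with
#'   compartment meshes: `"reflect"` (ray-traced specular reflection,
#'   suitable for small isotropic species) or `"contact"` (harmonic
#'   repulsion between beads and triangles, for large bead models).
#'   `"auto"` picks `"reflect"` for point-like types.
#' @param rotate whether to integrate orientations; by default rotation is
#'   skipped for point-like species with isotropic tensors, whose orientation
#'   is dynamically irrelevant (set `TRUE` to track it anyway, e.g. for
#'   rotational-correlation measurements).
#' @export
sim_register_type <- function(sim, mtype,
                              mesh_collision = c("auto", "reflect", "contact"),
                              rotate = NULL) {
  mesh_collision <- match.arg(mesh_collision)
  if (mtype$name %in% names(sim$types))
    stop("molecule type '", mtype$name, "' already registered")
  mtype$id <- length(sim$types) + 1L
  mtype$pt_ids <- vapply(mtype$ptypes, function(nm) pt_id(sim, nm), integer(1))
  mtype$mesh_collision <-
    if (mesh_collision == "auto") {
      if (mtype$point_like) "reflect" else "contact"
    } else mesh_collision
  # orientation updates matter only when the molecule has structure, an
  # anisotropic tensor, or lives on a surface
  iso <- max(abs(mtype$D_tt - diag(mtype$D_tt[1, 1], 3))) < 1e-14
  mtype$rotate <- if (is.null(rotate))
    !(mtype$point_like && iso) || mtype$surface else isTRUE(rotate)
  sim$types[[mtype$name]] <- mtype
  sim$count <- c(sim$count, 0L)
  sim$pot_dirty <- TRUE
  invisible(mtype$id)
}

#' Assign a pair potential to a particle type pair
#'
#' @param sim a [new_simulation()] object.
#' @param type1,type2 particle type names (bead types default to their
#'   molecule name).
#' @param pot a [pair_potentials] object (or `NULL` to remove).
#' @export
sim_set_potential <- function(sim, type1, type2, pot) {
  i <- pt_id(sim, type1); j <- pt_id(sim, type2)
  key <- paste(min(i, j), max(i, j), sep = "|")
  sim$potentials[[key]] <- pot
  sim$pot_dirty <- TRUE
  invisible(key)
}

#' Define a unimolecular reaction path
#'
#' Paths added for the same educt form a multi-path channel with total rate
#' `k_t = sum k_i`; waiting times are drawn once per molecule from
#' `Exp(k_t)` and the path is chosen with probability `k_i/k_t` at execution
#' (exact stochastic simulation, no per-step trials).
#'
#' Molecule-scope kinds: `"decay"` (molecule removed), `"conversion"`
#' (molecule swapped in place for `products[1]`), `"fission"` (molecule
#' replaced by two products placed `radius` apart along a uniform random
#' direction), `"production"` (molecule kept; `n_products` products placed
#' on a shell of `radius`).  Particle scope (`on_particle = TRUE`, educt is a
#' particle type): `"decay"` (particle retyped to the inert type `"void"`),
#' `"conversion"` (particle retyped to `products[1]`), `"release"` (a product
#' molecule emitted at the particle position plus `radius` along a random
#' direction).
#'
#' @param sim a [new_simulation()] object.
#' @param educt molecule type name (or particle type name with
#'   `on_particle = TRUE`).
#' @param kind,rate,products,radius,n_products see [reaction_path()].
#' @param on_particle whether the educt is a particle type.
#' @export
sim_add_unimolecular <- function(sim, educt, kind, rate,
                                 products = character(0), radius = NA,
                                 n_products = 1L, on_particle = FALSE) {
  kinds_mol <- c("decay", "conversion", "fission", "production")
  kinds_p <- c("decay", "conversion", "release")
  path <- reaction_path(kind, rate, products, radius, n_products)
  if (on_particle) {
    if (!kind %in% kinds_p) stop("unknown particle-scope kind ", kind)
    sim$uni_particle[[educt]] <- c(sim$uni_particle[[educt]], list(path))
  } else {
    if (!kind %in% kinds_mol) stop("unknown molecule-scope kind ", kind)
    if (!educt %in% names(sim$types)) stop("unknown molecule type ", educt)
    if (kind %in% c("fission", "production") && !is.finite(radius))
      stop("fission/production need a dissociation radius")
    sim$uni_mol[[educt]] <- c(sim$uni_mol[[educt]], list(path))
  }
  check_products(sim, kind, products, on_particle)
  invisible(sim)
}

check_products <- function(sim, kind, products, particle_scope) {
  if (kind %in% c("decay")) return(invisible())
  if (particle_scope && kind == "conversion") return(invisible())
  for (p in products)
    if (!particle_scope && !p %in% names(sim$types))
      stop("configuration error: product molecule type '", p, "' undefined")
  invisible()
}

#' Define a bimolecular reaction path
#'
#' Pairs of particles of types `educts[1]`, `educts[2]` closer than `radius`
#' fire with probability `1 - exp(-sum_i k_i dt)` per step (encounter-based
#' scheme); on success one eligible path is chosen with probability
#' proportional to its rate.  Kinds: `"fusion"` (both parent molecules
#' replaced by `products[1]` at the midpoint of the reacting particle pair,
#' orientation of the first educt), `"enzymatic"` (the molecule owning the
#' `educts[1]` particle is converted in place to `products[1]`; the partner
#' is untouched), `"enzymatic_particle"` (only the `educts[1]` particle is
#' retyped to `products[1]`), `"binding"` (a persistent harmonic bond of
#' stiffness `bond_k` between the two particles, rest length equal to their
#' distance at execution; `bond_unbind_rate` schedules unbinding).
#'
#' @param sim a [new_simulation()] object.
#' @param educts length-2 character vector of particle type names.
#' @param kind,rate,products,radius,bond_k,bond_unbind_rate see
#'   [reaction_path()].
#' @export
sim_add_bimolecular <- function(sim, educts, kind, rate, radius,
                                products = character(0), bond_k = 50,
                                bond_unbind_rate = 0) {
  stopifnot(length(educts) == 2L, radius > 0)
  if (!kind %in% c("fusion", "enzymatic", "enzymatic_particle", "binding"))
    stop("unknown bimolecular kind ", kind)
  if (kind %in% c("fusion", "enzymatic") && !products[1] %in% names(sim$types))
    stop("configuration error: product molecule type '", products[1],
         "' undefined")
  i <- pt_id(sim, educts[1]); j <- pt_id(sim, educts[2])
  key <- paste(min(i, j), max(i, j), sep = "|")
  path <- reaction_path(kind, rate, products, radius,
                        bond_k = bond_k, bond_unbind_rate = bond_unbind_rate)
  path$e1 <- i  # ordered semantics: e1 is the substrate/first educt side
  path$e2 <- j
  sim$bi[[key]] <- c(sim$bi[[key]], list(path))
  sim$pot_dirty <- TRUE
  invisible(sim)
}

# ---------------------------------------------------------------------------
# state management

grow_state <- function(sim, need) {
  while (sim$cap < need) {
    cap2 <- sim$cap * 2L
    pad_m <- function(m, k) rbind(m, matrix(0, cap2 - sim$cap, k))
    sim$pos <- pad_m(sim$pos, 3); sim$quat <- pad_m(sim$quat, 4)
    sim$img <- pad_m(sim$img, 3)
    sim$Fm <- pad_m(sim$Fm, 3); sim$Tq <- pad_m(sim$Tq, 3)
    sim$tid <- c(sim$tid, integer(cap2 - sim$cap))
    sim$ids <- c(sim$ids, integer(cap2 - sim$cap))
    sim$tri <- c(sim$tri, integer(cap2 - sim$cap))
    sim$comp <- c(sim$comp, integer(cap2 - sim$cap))
    sim$timer <- c(sim$timer, rep(Inf, cap2 - sim$cap))
    sim$ktot <- c(sim$ktot, numeric(cap2 - sim$cap))
    sim$pov <- c(sim$pov, vector("list", cap2 - sim$cap))
    sim$cap <- cap2
  }
}

mol_ktot <- function(sim, type, pov = NULL) {
  k <- 0
  for (p in sim$uni_mol[[type$name]]) k <- k + p$rate
  pts <- if (is.null(pov)) type$ptypes else sim$ptype_names[pov]
  for (pt in pts)
    for (p in sim$uni_particle[[pt]]) k <- k + p$rate
  k
}

sim_insert <- function(sim, type_name, pos, quat = c(1, 0, 0, 0), tri = 0L,
                       comp = 0L) {
  type <- sim$types[[type_name]]
  if (is.null(type)) stop("unknown molecule type ", type_name)
  grow_state(sim, sim$n + 1L)
  r <- sim$n + 1L
  sim$n <- r
  sim$pos[r, ] <- pos
  sim$quat[r, ] <- quat
  sim$img[r, ] <- 0
  sim$tid[r] <- type$id
  sim$tri[r] <- tri
  sim$comp[r] <- comp
  sim$Fm[r, ] <- 0; sim$Tq[r, ] <- 0
  sim$pov[r] <- list(NULL)
  id <- sim$next_id
  sim$next_id <- id + 1L
  if (id > length(sim$id2row))
    sim$id2row <- c(sim$id2row, integer(length(sim$id2row)))
  sim$id2row[id] <- r
  sim$ids[r] <- id
  kt <- mol_ktot(sim, type)
  sim$ktot[r] <- kt
  sim$timer[r] <- sim$t + sample_next_reaction_time(kt)
  sim$count[type$id] <- sim$count[type$id] + 1L
  id
}

sim_remove <- function(sim, row) {
  id <- sim$ids[row]
  sim$id2row[id] <- 0L
  sim$count[sim$tid[row]] <- sim$count[sim$tid[row]] - 1L
  last <- sim$n
  if (row != last) {
    sim$pos[row, ] <- sim$pos[last, ]
    sim$quat[row, ] <- sim$quat[last, ]
    sim$img[row, ] <- sim$img[last, ]
    sim$tid[row] <- sim$tid[last]
    sim$tri[row] <- sim$tri[last]
    sim$comp[row] <- sim$comp[last]
    sim$Fm[row, ] <- sim$Fm[last, ]
    sim$Tq[row, ] <- sim$Tq[last, ]
    sim$timer[row] <- sim$timer[last]
    sim$ktot[row] <- sim$ktot[last]
    sim$pov[row] <- sim$pov[last]
    sim$ids[row] <- sim$ids[last]
    sim$id2row[sim$ids[last]] <- row
  }
  sim$pov[last] <- list(NULL)
  sim$n <- last - 1L
  # drop bonds referencing the removed molecule
  if (length(sim$bonds)) {
    keep <- vapply(sim$bonds, function(b) b$id_a != id && b$id_b != id,
                   logical(1))
    sim$bonds <- sim$bonds[keep]
  }
  invisible(id)
}

# world positions of the particles of molecule at `row`
mol_particles <- function(sim, row) {
  ty <- sim$types[[sim$tid[row]]]
  if (ty$point_like) return(matrix(sim$pos[row, ], 1, 3))
  sweep(quat_rotate(sim$quat[row, , drop = FALSE][rep(1, nrow(ty$local)), ],
                    ty$local), 2, sim$pos[row, ], "+")
}

mol_ptypes <- function(sim, row) {
  ov <- sim$pov[[row]]
  if (is.null(ov)) sim$types[[sim$tid[row]]]$pt_ids else ov
}

# ---------------------------------------------------------------------------
# potential / cutoff tables (rebuilt when types, potentials or bimolecular
# channels changed)

rebuild_tables <- function(sim) {
  np <- length(sim$ptype_names)
  kindM <- matrix(0L, np, np)
  kM <- matrix(0, np, np); sigM <- matrix(0, np, np)
  p3M <- matrix(0, np, np); rcM <- matrix(0, np, np)
  custom <- list()
  for (key in names(sim$potentials)) {
    pot <- sim$potentials[[key]]
    if (is.null(pot)) next
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    kindM[ij[1], ij[2]] <- kindM[ij[2], ij[1]] <- pot$kind_id
    rcM[ij[1], ij[2]] <- rcM[ij[2], ij[1]] <- pot$cutoff
    if (pot$kind_id > 0L) {
      kM[ij[1], ij[2]] <- kM[ij[2], ij[1]] <- pot$k
      sigM[ij[1], ij[2]] <- sigM[ij[2], ij[1]] <- pot$sigma
      p3M[ij[1], ij[2]] <- p3M[ij[2], ij[1]] <- pot$p3
    } else custom[[key]] <- pot
  }
  biM <- matrix(0L, np, np)
  biR <- matrix(0, np, np)
  for (key in names(sim$bi)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    biM[ij[1], ij[2]] <- biM[ij[2], ij[1]] <- 1L
    rmax <- max(vapply(sim$bi[[key]], `[[`, numeric(1), "radius"))
    biR[ij[1], ij[2]] <- biR[ij[2], ij[1]] <- rmax
  }
  reach <- pmax(rcM, biR)
  typecut <- apply(reach, 1, max)      # per-ptype interaction diameter
  typecut[typecut <= 0] <- 1e-6
  sim$tab <- list(kind = kindM, k = kM, sig = sigM, p3 = p3M, rc = rcM,
                  custom = custom, bi = biM, biR = biR, typecut = typecut)
  sim$pot_dirty <- FALSE
  invisible()
}

# build flat particle arrays for the sweep
particle_arrays <- function(sim) {
  n <- sim$n
  tids <- sim$tid[seq_len(n)]
  rows_by_type <- split(seq_len(n), tids)
  ppos <- NULL; pmol <- NULL; ptyp <- NULL; pslot <- NULL
  for (tch in names(rows_by_type)) {
    rows <- rows_by_type[[tch]]
    ty <- sim$types[[as.integer(tch)]]
    P <- nrow(ty$local)
    if (ty$point_like) {
      ppos <- rbind(ppos, sim$pos[rows, , drop = FALSE])
      pmol <- c(pmol, rows)
      ptyp <- c(ptyp, rep(ty$pt_ids[1], length(rows)))
      pslot <- c(pslot, rep(1L, length(rows)))
    } else {
      q <- sim$quat[rows, , drop = FALSE]
      base <- sim$pos[rows, , drop = FALSE]
      for (s in seq_len(P)) {
        ppos <- rbind(ppos, base + quat_rotate(q, ty$local[s, , drop = FALSE]))
        pmol <- c(pmol, rows)
        ptyp <- c(ptyp, rep(ty$pt_ids[s], length(rows)))
        pslot <- c(pslot, rep(s, length(rows)))
      }
    }
  }
  # apply per-molecule particle retype overrides (rare)
  ov_rows <- if (isTRUE(sim$any_pov))
    which(!vapply(sim$pov[seq_len(n)], is.null, logical(1))) else integer(0)
  if (length(ov_rows)) {
    for (r in ov_rows) {
      sel <- which(pmol == r)
      ptyp[sel[order(pslot[sel])]] <- sim$pov[[r]]
    }
  }
  list(pos = ppos, mol = pmol, typ = ptyp, slot = pslot)
}

# one full force/virial/pair sweep; stores forces and returns candidate pairs
sim_sweep <- function(sim) {
  n <- sim$n
  sim$Fm[seq_len(max(n, 1)), ] <- 0
  sim$Tq[seq_len(max(n, 1)), ] <- 0
  sim$virial <- 0; sim$energy <- 0
  if (n == 0L) { sim$pressure <- 0; return(NULL) }
  if (sim$pot_dirty) rebuild_tables(sim)
  tab <- sim$tab
  if (!any(tab$bi > 0L) && !any(tab$kind > 0L) && !length(tab$custom) &&
      !length(sim$bonds) && !length(sim$compartments)) {
    # ideal system: no pair machinery needed
    sim$pressure <- virial_pressure(n, sim$kT, 0, prod(sim$box))
    return(NULL)
  }
  pa <- particle_arrays(sim)
  pcut <- tab$typecut[pa$typ]
  want_pairs <- any(tab$bi > 0L) || length(tab$custom) > 0L
  have_pot <- any(tab$kind > 0L)
  periodic <- sim$boundary$kind == "periodic"
  lv <- sort(unique(pcut), decreasing = TRUE)
  if (length(lv) > MAX_HGRID_LEVELS)
    lv <- exp(seq(log(max(lv)), log(min(lv)), length.out = MAX_HGRID_LEVELS))
  if (length(lv) == 1L) {
    assignment <- rep(1L, length(pcut))
  } else {
    # smallest level whose cell size covers the particle's cutoff
    assignment <- length(lv) + 1L -
      (findInterval(pcut * (1 - 1e-12), rev(lv)) + 1L)
    assignment[assignment < 1L] <- 1L
  }
  res <- cpp_pair_sweep(pa$pos, pcut, assignment, length(lv), lv, lv,
                        sim$box, periodic,
                        pa$typ, pa$mol, sim$pos[seq_len(n), , drop = FALSE],
                        tab$kind, tab$k, tab$sig, tab$p3, tab$rc,
                        want_pairs, TRUE)
  if (have_pot || TRUE) {
    sim$Fm[seq_len(n), ] <- res$F
    sim$Tq[seq_len(n), ] <- res$Tq
    sim$virial <- res$virial
    sim$energy <- res$energy
  }
  # custom potentials evaluated in R over the returned pair list
  if (length(tab$custom) && length(res$i)) {
    for (key in names(tab$custom)) {
      pot <- tab$custom[[key]]
      ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      ti <- pa$typ[res$i]; tj <- pa$typ[res$j]
      sel <- which((ti == ij[1] & tj == ij[2]) | (ti == ij[2] & tj == ij[1]))
      sel <- sel[res$r[sel] < pot$cutoff]
      if (!length(sel)) next
      ev <- evaluate_pair(pot, res$r[sel])
      add_pair_forces(sim, pa, res$i[sel], res$j[sel], res$r[sel], ev)
    }
  }
  # persistent bonds
  if (length(sim$bonds)) {
    now <- sim$t
    drop <- logical(length(sim$bonds))
    for (bi in seq_along(sim$bonds)) {
      b <- sim$bonds[[bi]]
      if (b$unbind_time <= now) { drop[bi] <- TRUE; next }
      ra <- sim$id2row[b$id_a]; rb <- sim$id2row[b$id_b]
      if (ra == 0L || rb == 0L) { drop[bi] <- TRUE; next }
      p1 <- mol_particles(sim, ra)[b$slot_a, ]
      p2 <- mol_particles(sim, rb)[b$slot_b, ]
      dvec <- p1 - p2
      if (sim$boundary$kind == "periodic") dvec <- minimum_image(dvec, sim$box)
      r <- sqrt(sum(dvec^2))
      if (r < 1e-12) next
      f <- -b$k * (r - b$r0) * dvec / r   # force on a
      sim$Fm[ra, ] <- sim$Fm[ra, ] + f
      sim$Fm[rb, ] <- sim$Fm[rb, ] - f
      la <- p1 - sim$pos[ra, ]; lb <- p2 - sim$pos[rb, ]
      sim$Tq[ra, ] <- sim$Tq[ra, ] + cross3(la, f)
      sim$Tq[rb, ] <- sim$Tq[rb, ] - cross3(lb, f)
      rm <- sim$pos[ra, ] - sim$pos[rb, ]
      if (sim$boundary$kind == "periodic") rm <- minimum_image(rm, sim$box)
      sim$virial <- sim$virial + sum(f * rm)
      sim$energy <- sim$energy + 0.5 * b$k * (r - b$r0)^2
    }
    if (any(drop)) sim$bonds <- sim$bonds[!drop]
  }
  # harmonic bead/triangle contact forces for "contact" collision types
  if (length(sim$compartments)) mesh_contact_forces(sim, pa)
  sim$pressure <- virial_pressure(n, sim$kT, sim$virial, prod(sim$box))
  if (want_pairs) list(i = res$i, j = res$j, r = res$r, pa = pa) else NULL
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

add_pair_forces <- function(sim, pa, ii, jj, r, ev) {
  fmag <- -ev$dUdr
  for (kk in seq_along(ii)) {
    i <- ii[kk]; j <- jj[kk]
    dvec <- pa$pos[i, ] - pa$pos[j, ]
    if (sim$boundary$kind == "periodic") dvec <- minimum_image(dvec, sim$box)
    f <- fmag[kk] * dvec / max(r[kk], 1e-12)
    mi <- pa$mol[i]; mj <- pa$mol[j]
    sim$Fm[mi, ] <- sim$Fm[mi, ] + f
    sim$Fm[mj, ] <- sim$Fm[mj, ] - f
    li <- pa$pos[i, ] - sim$pos[mi, ]
    lj <- pa$pos[j, ] - sim$pos[mj, ]
    sim$Tq[mi, ] <- sim$Tq[mi, ] + cross3(li, f)
    sim$Tq[mj, ] <- sim$Tq[mj, ] - cross3(lj, f)
    rmv <- sim$pos[mi, ] - sim$pos[mj, ]
    if (sim$boundary$kind == "periodic") rmv <- minimum_image(rmv, sim$box)
    sim$virial <- sim$virial + sum(f * rmv)
    sim$energy <- sim$energy + ev$U[kk]
  }
}

mesh_contact_forces <- function(sim, pa) {
  for (cmp in sim$compartments) {
    mesh <- cmp$mesh
    for (k in seq_len(nrow(pa$pos))) {
      row <- pa$mol[k]
      ty <- sim$types[[sim$tid[row]]]
      if (ty$mesh_collision != "contact" || ty$surface) next
      slot <- pa$slot[k]
      if (slot > ty$nbeads) next
      rad <- ty$pradii[slot]
      if (rad <= 0) next
      p <- pa$pos[k, ]
      tris <- mesh_tris_near(mesh, p, rad)
      for (tr in tris) {
        pt <- point_triangle_distance(p, mesh$V[mesh$F[tr, ], ])
        if (pt$distance < rad && pt$distance > 1e-12) {
          dir <- (p - pt$closest) / pt$distance
          f <- sim$wall_k * (rad - pt$distance) * dir
          sim$Fm[row, ] <- sim$Fm[row, ] + f
          sim$Tq[row, ] <- sim$Tq[row, ] + cross3(p - sim$pos[row, ], f)
          sim$energy <- sim$energy + 0.5 * sim$wall_k * (rad - pt$distance)^2
        }
      }
    }
  }
}

mesh_tris_near <- function(mesh, p, range) {
  vx <- mesh$voxel
  lo <- pmax(1L, pmin(vx$nc, as.integer(floor((p - range - vx$lo) / vx$cs)) + 1L))
  hi <- pmax(1L, pmin(vx$nc, as.integer(floor((p + range - vx$lo) / vx$cs)) + 1L))
  if (any(p + range < vx$lo) || any(p - range > vx$hi)) return(integer(0))
  out <- integer(0)
  for (cx in lo[1]:hi[1]) for (cy in lo[2]:hi[2]) for (cz in lo[3]:hi[3])
    out <- c(out, vx$cells[[((cz - 1L) * vx$nc[2] + (cy - 1L)) * vx$nc[1] + cx]])
  unique(out)
}

#' Add a mesh compartment
#'
#' @param sim a [new_simulation()] object.
#' @param mesh a [build_mesh()] object.
#' @param name compartment name.
#' @export
sim_add_compartment <- function(sim, mesh, name = "compartment") {
  # triangles reaching outside the simulation box are transparent
  h <- sim$box / 2
  vout <- abs(mesh$V) > matrix(h, nrow(mesh$V), 3, byrow = TRUE)
  tri_out <- which(apply(matrix(rowSums(vout)[mesh$F] > 0, nrow(mesh$F)), 1, any))
  mesh$transparent <- tri_out
  sim$compartments[[name]] <- list(mesh = mesh, name = name)
  invisible(sim)
}

#' Set the Berendsen barostat
#'
#' @param sim a [new_simulation()] object.
#' @param params a [berendsen_barostat()] object.
#' @export
sim_set_barostat <- function(sim, params) {
  stopifnot(inherits(params, "barostat_params"), params$tau_P > sim$dt)
  sim$barostat <- params
  invisible(sim)
}

#' Set outside concentrations for fixed-concentration boundaries
#'
#' @param sim a [new_simulation()] object.
#' @param concentrations named vector, molecule type -> concentration
#'   (nm^-3).
#' @export
sim_set_concentrations <- function(sim, concentrations) {
  stopifnot(sim$boundary$kind == "fixed_concentration")
  sim$boundary$concentrations <- concentrations
  invisible(sim)
}

#' Insert molecules at given or random positions
#'
#' @param sim a [new_simulation()] object.
#' @param type molecule type name.
#' @param n number of molecules (ignored when `positions` given).
#' @param positions optional n x 3 matrix; default uniform in the box.
#' @param quats optional n x 4 matrix; default uniform random orientations.
#' @param compartment optional compartment name; uniform positions are then
#'   rejection-sampled inside its mesh.
#' @return the inserted molecule ids.
#' @export
sim_place_molecules <- function(sim, type, n = NULL, positions = NULL,
                                quats = NULL, compartment = NULL) {
  if (is.null(positions)) {
    stopifnot(!is.null(n))
    if (is.null(compartment)) {
      positions <- cbind(stats::runif(n, -sim$box[1] / 2, sim$box[1] / 2),
                         stats::runif(n, -sim$box[2] / 2, sim$box[2] / 2),
                         stats::runif(n, -sim$box[3] / 2, sim$box[3] / 2))
    } else {
      mesh <- sim$compartments[[compartment]]$mesh
      positions <- matrix(0, 0, 3)
      while (nrow(positions) < n) {
        m <- 4L * (n - nrow(positions))
        cand <- cbind(stats::runif(m, mesh$voxel$lo[1], mesh$voxel$hi[1]),
                      stats::runif(m, mesh$voxel$lo[2], mesh$voxel$hi[2]),
                      stats::runif(m, mesh$voxel$lo[3], mesh$voxel$hi[3]))
        cand <- cand[mesh_contains(mesh, cand), , drop = FALSE]
        positions <- rbind(positions, cand)
      }
      positions <- positions[seq_len(n), , drop = FALSE]
    }
  }
  positions <- matrix(positions, ncol = 3)
  n <- nrow(positions)
  if (is.null(quats)) quats <- quat_random(n)
  ids <- integer(n)
  for (k in seq_len(n))
    ids[k] <- sim_insert(sim, type, positions[k, ], quats[k, ])
  invisible(ids)
}

#' Place surface molecules on a compartment mesh
#'
#' @param sim a [new_simulation()] object.
#' @param type a surface molecule type name.
#' @param n number of molecules.
#' @param compartment compartment name.
#' @param group optional face group restriction.
#' @param min_dist optional pairwise minimum distance (blue-noise sampling,
#'   see [sample_surface()]).
#' @return inserted molecule ids.
#' @export
sim_place_surface <- function(sim, type, n, compartment, group = NULL,
                              min_dist = 0) {
  mesh <- sim$compartments[[compartment]]$mesh
  sm <- sample_surface(mesh, n, min_dist = min_dist, group = group)
  ids <- integer(nrow(sm$positions))
  for (k in seq_along(ids)) {
    tr <- sm$tri[k]
    # orientation: body z-axis along the triangle normal
    b <- triangle_basis(mesh, tr)
    R <- cbind(b$u[1, ], b$v[1, ], mesh$normals[tr, ])
    q <- quat_from_matrix(R)
    ids[k] <- sim_insert(sim, type, sm$positions[k, ], q, tri = tr,
                         comp = match(compartment, names(sim$compartments)))
  }
  invisible(ids)
}

quat_from_matrix <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    k <- which.max(diag(R))
    i <- k; j <- i %% 3 + 1; l <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[l, l] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[l, j] - R[j, l]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[l + 1] <- (R[l, i] + R[i, l]) / s
  }
  q / sqrt(sum(q^2))
}
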