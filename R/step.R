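# The integration loop: propagation, boundary handling, force/pair sweep,
# barostat, reaction scheduling and execution.

#' Advance the simulation one step
#'
#' Executes, in order: (1) Brownian update of all molecule positions and
#' orientations (volume molecules by [propagate_step()] with mesh collision
#' response, surface molecules by tangent-plane steps with
#' [surface_ray_march()]), including boundary handling; (2) one neighbor
#' sweep that accumulates forces, torques and the virial and collects the
#' in-range bimolecular candidate pairs; (3) the Berendsen barostat when
#' active; (4) expired unimolecular timers are gathered and (5) all reaction
#' events are executed in uniformly random order, events of consumed educts
#' being invalidated.  Forces are not recomputed after reactions.
#'
#' @param sim a [new_simulation()] object.
#' @export
simulation_step <- function(sim) {
  dt <- sim$dt
  tnew <- sim$t + dt
  n <- sim$n
  if (n > 0L) {
    tids <- sim$tid[seq_len(n)]
    for (t_id in unique(tids)) {
      rows <- which(tids == t_id)
      ty <- sim$types[[t_id]]
      if (ty$surface) propagate_surface(sim, rows, ty)
      else propagate_volume(sim, rows, ty)
    }
  }
  apply_boundary(sim)
  pairs <- sim_sweep(sim)
  if (!is.null(sim$barostat) && sim$t >= sim$barostat$start_time &&
      sim$n > 0L) {
    bs <- berendsen_step(sim$pos[seq_len(sim$n), , drop = FALSE], sim$box,
                         sim$pressure, sim$barostat, dt)
    sim$pos[seq_len(sim$n), ] <- bs$centers
    sim$box <- bs$box
    sim$boundary$box <- sim$box
  }
  if (length(sim$bi) || length(sim$uni_mol) || length(sim$uni_particle))
    sim_reactions(sim, pairs, tnew)
  sim$t <- tnew
  invisible(sim)
}

propagate_volume <- function(sim, rows, ty) {
  old <- sim$pos[rows, , drop = FALSE]
  pr <- propagate_step(old, sim$quat[rows, , drop = FALSE],
                       sim$Fm[rows, , drop = FALSE],
                       sim$Tq[rows, , drop = FALSE],
                       ty, sim$dt, sim$kT, rotate = ty$rotate)
  newpos <- pr$pos
  if (length(sim$compartments) && ty$mesh_collision == "reflect") {
    for (cmp in sim$compartments) {
      mesh <- cmp$mesh
      vx <- mesh$voxel
      for (k in seq_along(rows)) {
        lo <- pmin(old[k, ], newpos[k, ]); hi <- pmax(old[k, ], newpos[k, ])
        if (any(hi < vx$lo) || any(lo > vx$hi)) next
        res <- ray_trace_reflect(old[k, ], newpos[k, ] - old[k, ], mesh)
        newpos[k, ] <- res$position
      }
    }
  }
  sim$pos[rows, ] <- newpos
  sim$quat[rows, ] <- pr$quat
  invisible()
}

propagate_surface <- function(sim, rows, ty) {
  D <- ty$D_scalar
  dt <- sim$dt
  comp_ids <- sim$comp[rows]
  for (ci in unique(comp_ids)) {
    mesh <- sim$compartments[[ci]]$mesh
    sel <- rows[comp_ids == ci]
    tri <- sim$tri[sel]
    b <- triangle_basis(mesh, tri)
    nrm <- mesh$normals[tri, , drop = FALSE]
    d1 <- stats::rnorm(length(sel), sd = sqrt(2 * D * dt))
    d2 <- stats::rnorm(length(sel), sd = sqrt(2 * D * dt))
    disp <- d1 * b$u + d2 * b$v
    # in-plane drift from the tangential force component
    Fm <- sim$Fm[sel, , drop = FALSE]
    Ft <- Fm - rowSums(Fm * nrm) * nrm
    disp <- disp + Ft * (D * dt / sim$kT)
    pos <- sim$pos[sel, , drop = FALSE]
    target <- pos + disp
    # vectorized barycentric test against the current triangle
    a <- mesh$V[mesh$F[tri, 1], , drop = FALSE]
    vp <- target - a
    dd1 <- rowSums(vp * mesh$e1[tri, , drop = FALSE])
    dd2 <- rowSums(vp * mesh$e2[tri, , drop = FALSE])
    v <- (mesh$d22[tri] * dd1 - mesh$d12[tri] * dd2) * mesh$inv_det[tri]
    w <- (mesh$d11[tri] * dd2 - mesh$d12[tri] * dd1) * mesh$inv_det[tri]
    inside <- (1 - v - w) >= -1e-12 & v >= -1e-12 & w >= -1e-12
    if (any(inside)) {
      ii <- which(inside)
      sim$pos[sel[ii], ] <- target[ii, , drop = FALSE]
    }
    for (k in which(!inside)) {
      res <- surface_ray_march(mesh, tri[k], pos[k, ], disp[k, ],
                               quat = sim$quat[sel[k], ])
      sim$pos[sel[k], ] <- res$position
      sim$tri[sel[k]] <- res$tri
      sim$quat[sel[k], ] <- res$quat
    }
  }
  invisible()
}

#' Apply the boundary condition to current positions
#'
#' Periodic boxes wrap positions (tracking image counts for trajectory
#' unwrapping); repulsive boxes reflect at the walls; fixed-concentration
#' boundaries delete molecules that crossed out and then draw Poisson influx
#' insertions per species from the outside concentrations.
#'
#' @param sim a [new_simulation()] object.
#' @export
apply_boundary <- function(sim) {
  n <- sim$n
  if (n == 0L && sim$boundary$kind != "fixed_concentration") return(invisible(sim))
  kind <- sim$boundary$kind
  if (kind == "periodic") {
    p <- sim$pos[seq_len(n), , drop = FALSE]
    w <- minimum_image(p, sim$box)
    shift <- round(sweep(p - w, 2, sim$box, "/"))
    sim$img[seq_len(n), ] <- sim$img[seq_len(n), , drop = FALSE] + shift
    sim$pos[seq_len(n), ] <- w
  } else if (kind == "repulsive") {
    sim$pos[seq_len(n), ] <- reflect_box(sim$pos[seq_len(n), , drop = FALSE],
                                         sim$box)
  } else {
    if (n > 0L) {
      p <- abs(sim$pos[seq_len(n), , drop = FALSE])
      out <- which(p[, 1] > sim$box[1] / 2 | p[, 2] > sim$box[2] / 2 |
                   p[, 3] > sim$box[3] / 2)
      for (row in rev(sort(out))) {
        sim$events[[length(sim$events) + 1L]] <-
          list(t = sim$t, kind = "outflux", type = sim$tid[row])
        sim_remove(sim, row)
      }
    }
    conc <- sim$boundary$concentrations
    for (nm in names(conc)) {
      if (conc[[nm]] <= 0) next
      ty <- sim$types[[nm]]
      # insertions are not collision-checked against meshes; warn once when a
      # compartment reaches into the influx layer at the box faces
      if (length(sim$compartments) && !isTRUE(sim$influx_mesh_warned)) {
        layer <- sqrt(4 * ty$D_scalar * sim$dt)
        for (cmp in sim$compartments) {
          vx <- cmp$mesh$voxel
          if (any(vx$hi > sim$box / 2 - layer) ||
              any(vx$lo < -sim$box / 2 + layer)) {
            warning("compartment '", cmp$name, "' lies within sqrt(4 D dt) = ",
                    signif(layer, 3), " nm of a fixed-concentration boundary; ",
                    "influx insertions are not collision-checked against it")
            sim$influx_mesh_warned <- TRUE
            break
          }
        }
        if (!isTRUE(sim$influx_mesh_warned)) sim$influx_mesh_warned <- TRUE
      }
      ins <- fixed_conc_influx(sim$boundary, conc[[nm]], ty$D_scalar, sim$dt)
      for (k in seq_len(nrow(ins$positions))) {
        sim_insert(sim, nm, ins$positions[k, ], ins$quats[k, ])
        sim$events[[length(sim$events) + 1L]] <-
          list(t = sim$t, kind = "influx", type = ty$id)
      }
    }
  }
  invisible(sim)
}

# ---------------------------------------------------------------------------
# reaction scheduling and execution

sim_reactions <- function(sim, pairs, tnew) {
  rl <- reaction_list()
  dt <- sim$dt
  sim$t <- tnew  # events execute at the end-of-step time; product timers
                 # and bond unbinding clocks start from here
  # bimolecular candidates from the pair sweep
  if (!is.null(pairs) && length(pairs$i) && any(sim$tab$bi > 0L)) {
    pa <- pairs$pa
    ti <- pa$typ[pairs$i]; tj <- pa$typ[pairs$j]
    cand <- which(sim$tab$bi[cbind(ti, tj)] > 0L &
                    pairs$r < sim$tab$biR[cbind(ti, tj)])
    for (kk in cand) {
      i <- pairs$i[kk]; j <- pairs$j[kk]
      a <- ti[kk]; b <- tj[kk]
      key <- paste(min(a, b), max(a, b), sep = "|")
      paths <- sim$bi[[key]]
      rates <- vapply(paths, function(p)
        if (pairs$r[kk] < p$radius) p$rate else 0, numeric(1))
      keff <- sum(rates)
      if (keff <= 0) next
      if (stats::runif(1) >= doi_probability(keff, dt)) next
      mi <- pa$mol[i]; mj <- pa$mol[j]
      idi <- sim$ids[mi]; idj <- sim$ids[mj]
      pk_i <- idi * PKEY + pa$slot[i]
      pk_j <- idj * PKEY + pa$slot[j]
      rl_add(rl, c(idi, idj, pk_i, pk_j),
             list(type = "bi", key = key, rates = rates,
                  id_i = idi, slot_i = pa$slot[i], pt_i = a,
                  id_j = idj, slot_j = pa$slot[j], pt_j = b,
                  r = pairs$r[kk]))
    }
  }
  # expired unimolecular timers
  if (sim$n > 0L) {
    fired <- which(sim$timer[seq_len(sim$n)] <= tnew)
    for (row in fired)
      rl_add(rl, sim$ids[row], list(type = "uni", id = sim$ids[row]))
  }
  # execute in uniformly random order; consumed educts invalidate later events
  while (length(rl) > 0L) {
    ev <- rl_pick_random(rl)
    pl <- rl_get(rl, ev)
    rl_remove(rl, ev)
    consumed <- execute_event(sim, pl, tnew)
    for (key in consumed) rl_clear_educt(rl, key)
  }
  invisible()
}

# keys invalidating all events of molecule `id` of type `ty`
mol_keys <- function(id, ty) c(id, id * PKEY + seq_len(nrow(ty$local)))

runit <- function(n = 1L) {
  u <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(1 - u^2)
  cbind(st * cos(phi), st * sin(phi), u)
}

wrap_pos <- function(sim, p) {
  if (sim$boundary$kind == "periodic") minimum_image(p, sim$box) else p
}

log_event <- function(sim, kind, t, educts = character(0),
                      products = character(0)) {
  sim$events[[length(sim$events) + 1L]] <-
    list(t = t, kind = kind, educts = educts, products = products)
}

sim_retype <- function(sim, row, new_name, tnew) {
  new_ty <- sim$types[[new_name]]
  if (is.null(new_ty)) stop("configuration error: product type '", new_name,
                            "' undefined")
  old <- sim$tid[row]
  sim$count[old] <- sim$count[old] - 1L
  sim$count[new_ty$id] <- sim$count[new_ty$id] + 1L
  sim$tid[row] <- new_ty$id
  sim$pov[row] <- list(NULL)
  kt <- mol_ktot(sim, new_ty)
  sim$ktot[row] <- kt
  sim$timer[row] <- tnew + sample_next_reaction_time(kt)
  invisible()
}

sim_retype_particle <- function(sim, row, slot, new_ptype, tnew) {
  ty <- sim$types[[sim$tid[row]]]
  ov <- sim$pov[[row]]
  if (is.null(ov)) ov <- ty$pt_ids
  ov[slot] <- pt_id(sim, new_ptype)
  sim$pov[[row]] <- ov
  kt <- mol_ktot(sim, ty, ov)
  sim$ktot[row] <- kt
  sim$timer[row] <- tnew + sample_next_reaction_time(kt)
  invisible()
}

execute_event <- function(sim, pl, tnew) {
  if (pl$type == "bi") return(execute_bi(sim, pl, tnew))
  execute_uni(sim, pl, tnew)
}

execute_bi <- function(sim, pl, tnew) {
  ri <- if (pl$id_i <= length(sim$id2row)) sim$id2row[pl$id_i] else 0L
  rj <- if (pl$id_j <= length(sim$id2row)) sim$id2row[pl$id_j] else 0L
  if (ri == 0L || rj == 0L) return(numeric(0))
  paths <- sim$bi[[pl$key]]
  w <- pl$rates
  pick <- if (length(w) == 1L) 1L else
    sample.int(length(w), 1L, prob = w)
  p <- paths[[pick]]
  # orient the pair: substrate side = the educt whose particle type is p$e1
  if (pl$pt_i == p$e1) {
    sub <- list(row = ri, slot = pl$slot_i, id = pl$id_i)
    oth <- list(row = rj, slot = pl$slot_j, id = pl$id_j)
  } else {
    sub <- list(row = rj, slot = pl$slot_j, id = pl$id_j)
    oth <- list(row = ri, slot = pl$slot_i, id = pl$id_i)
  }
  ty_i <- sim$types[[sim$tid[ri]]]
  ty_j <- sim$types[[sim$tid[rj]]]
  switch(p$kind,
    fusion = {
      p1 <- mol_particles(sim, ri)[pl$slot_i, ]
      p2 <- mol_particles(sim, rj)[pl$slot_j, ]
      dvec <- p2 - p1
      if (sim$boundary$kind == "periodic") dvec <- minimum_image(dvec, sim$box)
      mid <- wrap_pos(sim, matrix(p1 + dvec / 2, 1, 3))[1, ]
      qnew <- sim$quat[ri, ]  # orientation of the first educt
      consumed <- c(mol_keys(pl$id_i, ty_i), mol_keys(pl$id_j, ty_j))
      sim_remove(sim, max(ri, rj))
      sim_remove(sim, min(ri, rj))
      sim_insert(sim, p$products[1], mid, qnew)
      log_event(sim, "fusion", tnew, c(pl$id_i, pl$id_j), p$products[1])
      consumed
    },
    enzymatic = {
      ty_sub <- sim$types[[sim$tid[sub$row]]]
      consumed <- c(mol_keys(sub$id, ty_sub), oth$id * PKEY + oth$slot)
      sim_retype(sim, sub$row, p$products[1], tnew)
      log_event(sim, "enzymatic", tnew, c(sub$id, oth$id), p$products[1])
      consumed
    },
    enzymatic_particle = {
      consumed <- c(sub$id * PKEY + sub$slot, oth$id * PKEY + oth$slot)
      sim_retype_particle(sim, sub$row, sub$slot, p$products[1], tnew)
      log_event(sim, "enzymatic_particle", tnew, c(sub$id, oth$id),
                p$products[1])
      consumed
    },
    binding = {
      for (b in sim$bonds)
        if ((b$id_a == pl$id_i && b$id_b == pl$id_j) ||
            (b$id_a == pl$id_j && b$id_b == pl$id_i)) return(numeric(0))
      p1 <- mol_particles(sim, ri)[pl$slot_i, ]
      p2 <- mol_particles(sim, rj)[pl$slot_j, ]
      dvec <- p2 - p1
      if (sim$boundary$kind == "periodic") dvec <- minimum_image(dvec, sim$box)
      unbind <- if (p$bond_unbind_rate > 0)
        tnew + sample_next_reaction_time(p$bond_unbind_rate) else Inf
      sim$bonds[[length(sim$bonds) + 1L]] <-
        list(id_a = pl$id_i, slot_a = pl$slot_i,
             id_b = pl$id_j, slot_b = pl$slot_j,
             k = p$bond_k, r0 = sqrt(sum(dvec^2)), unbind_time = unbind)
      log_event(sim, "binding", tnew, c(pl$id_i, pl$id_j))
      c(pl$id_i * PKEY + pl$slot_i, pl$id_j * PKEY + pl$slot_j)
    },
    stop("unknown bimolecular kind ", p$kind))
}

execute_uni <- function(sim, pl, tnew) {
  row <- if (pl$id <= length(sim$id2row)) sim$id2row[pl$id] else 0L
  if (row == 0L) return(numeric(0))
  ty <- sim$types[[sim$tid[row]]]
  # assemble the current channel set: molecule-scope paths, then
  # particle-scope paths per particle slot
  paths <- list(); owner_slot <- integer(0)
  for (p in sim$uni_mol[[ty$name]]) {
    paths <- c(paths, list(p)); owner_slot <- c(owner_slot, 0L)
  }
  pts <- mol_ptypes(sim, row)
  for (s in seq_along(pts)) {
    for (p in sim$uni_particle[[sim$ptype_names[pts[s]]]]) {
      paths <- c(paths, list(p)); owner_slot <- c(owner_slot, s)
    }
  }
  if (!length(paths)) return(numeric(0))
  w <- vapply(paths, `[[`, numeric(1), "rate")
  pick <- if (length(w) == 1L) 1L else sample.int(length(w), 1L, prob = w)
  p <- paths[[pick]]
  slot <- owner_slot[pick]
  pos0 <- sim$pos[row, ]
  if (slot == 0L) {
    switch(p$kind,
      decay = {
        consumed <- mol_keys(pl$id, ty)
        sim_remove(sim, row)
        log_event(sim, "decay", tnew, pl$id)
        return(consumed)
      },
      conversion = {
        consumed <- mol_keys(pl$id, ty)
        sim_retype(sim, row, p$products[1], tnew)
        log_event(sim, "conversion", tnew, pl$id, p$products[1])
        return(consumed)
      },
      fission = {
        u <- runit(1)[1, ]
        consumed <- mol_keys(pl$id, ty)
        sim_remove(sim, row)
        sim_insert(sim, p$products[1],
                   wrap_pos(sim, matrix(pos0 - p$radius / 2 * u, 1, 3))[1, ],
                   quat_random(1)[1, ])
        sim_insert(sim, p$products[2],
                   wrap_pos(sim, matrix(pos0 + p$radius / 2 * u, 1, 3))[1, ],
                   quat_random(1)[1, ])
        log_event(sim, "fission", tnew, pl$id, p$products)
        return(consumed)
      },
      production = {
        u <- runit(p$n_products)
        prods <- rep_len(p$products, p$n_products)
        for (k in seq_len(p$n_products))
          sim_insert(sim, prods[k],
                     wrap_pos(sim, matrix(pos0 + p$radius * u[k, ], 1, 3))[1, ],
                     quat_random(1)[1, ])
        sim$timer[row] <- tnew + sample_next_reaction_time(sim$ktot[row])
        log_event(sim, "production", tnew, pl$id, prods)
        return(numeric(0))
      })
  } else {
    switch(p$kind,
      decay = {
        consumed <- pl$id * PKEY + slot
        sim_retype_particle(sim, row, slot, "void", tnew)
        log_event(sim, "particle_decay", tnew, pl$id)
        return(consumed)
      },
      conversion = {
        consumed <- pl$id * PKEY + slot
        sim_retype_particle(sim, row, slot, p$products[1], tnew)
        log_event(sim, "particle_conversion", tnew, pl$id, p$products[1])
        return(consumed)
      },
      release = {
        pw <- mol_particles(sim, row)[slot, ]
        u <- runit(1)[1, ]
        sim_insert(sim, p$products[1],
                   wrap_pos(sim, matrix(pw + p$radius * u, 1, 3))[1, ],
                   quat_random(1)[1, ])
        sim$timer[row] <- tnew + sample_next_reaction_time(sim$ktot[row])
        log_event(sim, "release", tnew, pl$id, p$products[1])
        return(numeric(0))
      })
  }
  numeric(0)
}

# ---------------------------------------------------------------------------

#' Run a simulation
#'
#' Seeds the RNG (when the simulation has a seed), redraws all unimolecular
#' timers from the current channel sets (valid by memorylessness), computes
#' initial forces, and advances `steps` steps, recording trajectory frames
#' every `record_every` steps plus scalar traces (pressure, energy, box
#' volume, molecule counts) every step.
#'
#' @param sim a [new_simulation()] object.
#' @param steps number of integration steps.
#' @param record_every frame recording stride (0 = only the initial frame).
#' @return a `rid_trajectory` object; see [msd()], [rotational_correlation()],
#'   [rdf()].
#' @export
run_simulation <- function(sim, steps, record_every = 1L) {
  if (!is.null(sim$seed)) set.seed(sim$seed)
  if (sim$pot_dirty) rebuild_tables(sim)
  n <- sim$n
  for (row in seq_len(n)) {
    ty <- sim$types[[sim$tid[row]]]
    kt <- mol_ktot(sim, ty, sim$pov[[row]])
    sim$ktot[row] <- kt
    sim$timer[row] <- sim$t + sample_next_reaction_time(kt)
  }
  sim_sweep(sim)  # forces for the first propagation
  ntr <- steps + 1L
  traces <- list(time = numeric(ntr), pressure = numeric(ntr),
                 energy = numeric(ntr), volume = numeric(ntr),
                 counts = matrix(0L, ntr, length(sim$types),
                                 dimnames = list(NULL, names(sim$types))))
  frames <- list()
  snap <- function() {
    nn <- sim$n
    idx <- seq_len(nn)
    list(time = sim$t, ids = sim$ids[idx], type = sim$tid[idx],
         pos = sim$pos[idx, , drop = FALSE] +
           sim$img[idx, , drop = FALSE] %*% diag(sim$box),
         quat = sim$quat[idx, , drop = FALSE],
         tri = sim$tri[idx], box = sim$box)
  }
  rec <- function(k) {
    traces$time[k] <<- sim$t
    traces$pressure[k] <<- sim$pressure
    traces$energy[k] <<- sim$energy
    traces$volume[k] <<- prod(sim$box)
    traces$counts[k, ] <<- sim$count
  }
  rec(1L)
  frames[[1L]] <- snap()
  for (s in seq_len(steps)) {
    simulation_step(sim)
    rec(s + 1L)
    if (record_every > 0L && s %% record_every == 0L)
      frames[[length(frames) + 1L]] <- snap()
  }
  structure(list(frames = frames,
                 times = vapply(frames, `[[`, numeric(1), "time"),
                 traces = traces, type_names = names(sim$types),
                 dt = sim$dt, record_every = record_every),
            class = "rid_trajectory")
}

#' @export
print.rid_trajectory <- function(x, ...) {
  cat(sprintf("<rid_trajectory> %d frames, t = %.4g .. %.4g ns\n",
              length(x$frames), x$times[1], x$times[length(x$times)]))
  invisible(x)
}
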