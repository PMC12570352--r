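# Declarative configuration (YAML), trajectory/event persistence (CSV), the
# reaction-network export (JSON), and provenance records.

#' Read and validate a simulation configuration
#'
#' The configuration is a YAML document with blocks `box`, `dt`, `boundary`,
#' `molecule_types`, `potentials`, `reactions`, `placement`, `integrator`,
#' and optional `barostat`, `concentrations`, `seed`, `temperature`,
#' `viscosity`.  Cross-references (product types, potential types) are
#' resolved at build time; violations are reported with their config path.
#'
#' @param path YAML file path.
#' @return the validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- function(field) {
    if (is.null(cfg[[field]]))
      stop("config error at /", field, ": required field missing")
  }
  for (f in c("box", "dt", "molecule_types", "integrator")) need(f)
  if (is.null(cfg$integrator$steps))
    stop("config error at /integrator/steps: required field missing")
  for (nm in names(cfg$molecule_types)) {
    mt <- cfg$molecule_types[[nm]]
    if (is.null(mt$beads) || is.null(mt$radii))
      stop("config error at /molecule_types/", nm,
           ": beads and radii are required")
  }
  for (i in seq_along(cfg$reactions)) {
    rx <- cfg$reactions[[i]]
    if (is.null(rx$kind) || is.null(rx$rate))
      stop("config error at /reactions/", i, ": kind and rate are required")
  }
  cfg
}

#' Build a simulation from a configuration
#'
#' @param cfg a configuration list from [read_config()].
#' @return a ready-to-run [new_simulation()] object.
#' @export
build_simulation <- function(cfg) {
  sim <- new_simulation(box = unlist(cfg$box), dt = cfg$dt,
                        boundary = cfg$boundary %||% "periodic",
                        temperature = cfg$temperature %||% 293.15,
                        viscosity = cfg$viscosity %||% 0.6022,
                        seed = cfg$seed)
  for (nm in names(cfg$molecule_types)) {
    mt <- cfg$molecule_types[[nm]]
    beads <- do.call(rbind, lapply(mt$beads, as.numeric))
    ty <- define_molecule_type(nm, beads, unlist(mt$radii),
                               bead_types = unlist(mt$bead_types) %||% NULL,
                               params = sim$params,
                               surface = isTRUE(mt$surface),
                               D = mt$D, D_rot = mt$D_rot)
    sim_register_type(sim, ty, mesh_collision = mt$mesh_collision %||% "auto")
  }
  for (mh in cfg$meshes)
    sim_add_compartment(sim, read_obj(mh$file), name = mh$name %||% mh$file)
  for (pt in cfg$potentials) {
    pot <- switch(pt$kind,
      harmonic_repulsion = harmonic_repulsion(pt$k, pt$sigma),
      weak_piecewise_harmonic = weak_piecewise_harmonic(pt$k, pt$sigma,
                                                        pt$depth, pt$cutoff),
      csw = csw(pt$eps, pt$rw, pt$delta),
      phs = phs(pt$eps, pt$sigma),
      stop("config error: unknown potential kind ", pt$kind))
    sim_set_potential(sim, pt$types[[1]], pt$types[[2]], pot)
  }
  for (rx in cfg$reactions) {
    if (!is.null(rx$educts) && length(rx$educts) == 2L) {
      sim_add_bimolecular(sim, unlist(rx$educts), rx$kind, rx$rate, rx$radius,
                          products = unlist(rx$products) %||% character(0),
                          bond_k = rx$bond_k %||% 50,
                          bond_unbind_rate = rx$bond_unbind_rate %||% 0)
    } else {
      sim_add_unimolecular(sim, rx$educt, rx$kind, rx$rate,
                           products = unlist(rx$products) %||% character(0),
                           radius = rx$radius %||% NA,
                           n_products = rx$n_products %||% 1L,
                           on_particle = isTRUE(rx$on_particle))
    }
  }
  if (!is.null(cfg$barostat))
    sim_set_barostat(sim, berendsen_barostat(cfg$barostat$P0,
                                             cfg$barostat$tau,
                                             cfg$barostat$start %||% 0))
  if (!is.null(cfg$concentrations))
    sim$boundary$concentrations <- unlist(cfg$concentrations)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  for (pl in cfg$placement) {
    # key "count" preferred: a bare "n" is a YAML 1.1 boolean unless quoted
    n <- pl$count %||% pl[["n"]]
    if (is.null(n))
      stop("config error at /placement: each block needs a 'count'")
    if (isTRUE(pl$surface)) {
      sim_place_surface(sim, pl$type, n, pl$compartment %||% 1L,
                        group = pl$group)
    } else {
      sim_place_molecules(sim, pl$type, n = n, compartment = pl$compartment)
    }
  }
  sim
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a simulation from a configuration file
#'
#' Deterministic given the config seed; writes the trajectory, the per-step
#' traces, the event log and a provenance record (config checksum, package
#' version, seed) into `out_dir`.
#'
#' @param path config file path.
#' @param out_dir output directory (`NULL` = no files written).
#' @param overrides named list overriding top-level config fields (e.g.
#'   `list(seed = 7)`).
#' @return list with the simulation, the trajectory, and output paths.
#' @export
run_config <- function(path, out_dir = NULL, overrides = NULL) {
  cfg <- read_config(path)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  sim <- build_simulation(cfg)
  traj <- run_simulation(sim, cfg$integrator$steps,
                         record_every = cfg$integrator$record_every %||% 1L)
  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tf <- file.path(out_dir, "trajectory.csv")
    write_trajectory_csv(traj, tf)
    trf <- file.path(out_dir, "traces.csv")
    utils::write.csv(traces(traj), trf, row.names = FALSE)
    evf <- file.path(out_dir, "events.csv")
    utils::write.csv(event_log(sim), evf, row.names = FALSE)
    pv <- file.path(out_dir, "provenance.json")
    jsonlite::write_json(list(
      config = path,
      config_md5 = unname(tools::md5sum(path)),
      package_version = as.character(utils::packageVersion("ridsim")),
      seed = cfg$seed, steps = cfg$integrator$steps,
      r_version = R.version.string), pv, auto_unbox = TRUE, pretty = TRUE)
    outputs <- c(trajectory = tf, traces = trf, events = evf,
                 provenance = pv)
  }
  list(sim = sim, trajectory = traj, outputs = outputs)
}

#' Trajectory persistence (CSV and XYZ)
#'
#' The CSV container has one row per molecule per frame with columns
#' `frame, time, id, type, x, y, z, qw, qx, qy, qz` (positions unwrapped);
#' the XYZ export writes one block per frame for generic molecular viewers.
#'
#' @param traj a trajectory from [run_simulation()].
#' @param file output path.
#' @export
write_trajectory_csv <- function(traj, file) {
  rows <- lapply(seq_along(traj$frames), function(f) {
    fr <- traj$frames[[f]]
    if (!length(fr$ids)) return(NULL)
    data.frame(frame = f, time = fr$time, id = fr$ids,
               type = traj$type_names[fr$type],
               x = fr$pos[, 1], y = fr$pos[, 2], z = fr$pos[, 3],
               qw = fr$quat[, 1], qx = fr$quat[, 2], qy = fr$quat[, 3],
               qz = fr$quat[, 4])
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  utils::read.csv(file)
}

#' @rdname write_trajectory_csv
#' @export
write_trajectory_xyz <- function(traj, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    writeLines(as.character(length(fr$ids)), con)
    writeLines(sprintf("t=%.9g", fr$time), con)
    if (length(fr$ids))
      writeLines(sprintf("%s %.6f %.6f %.6f", traj$type_names[fr$type],
                         fr$pos[, 1], fr$pos[, 2], fr$pos[, 3]), con)
  }
  invisible(file)
}

#' Event log of a simulation
#'
#' @param sim a [new_simulation()] object after running.
#' @return data frame with `time`, `kind`, `educts`, `products`.
#' @export
event_log <- function(sim) {
  if (!length(sim$events))
    return(data.frame(time = numeric(0), kind = character(0),
                      educts = character(0), products = character(0)))
  data.frame(
    time = vapply(sim$events, `[[`, numeric(1), 1),
    kind = vapply(sim$events, `[[`, character(1), 2),
    educts = vapply(sim$events, function(e)
      paste(e$educts, collapse = "+"), character(1)),
    products = vapply(sim$events, function(e)
      paste(e$products, collapse = "+"), character(1)))
}

#' Export the reaction network as a JSON node/edge list
#'
#' Nodes are molecule and particle types; one edge per reaction path,
#' annotated with kind, rate and radius.
#'
#' @param sim a [new_simulation()] object with reactions defined.
#' @param file optional output path; when `NULL` the list is returned.
#' @export
export_reaction_graph <- function(sim, file = NULL) {
  nodes <- list(); edges <- list()
  add_node <- function(name, kind) {
    if (!name %in% vapply(nodes, `[[`, character(1), "id"))
      nodes[[length(nodes) + 1L]] <<- list(id = name, kind = kind)
  }
  for (ty in names(sim$types)) add_node(ty, "molecule")
  for (nm in names(sim$uni_mol)) {
    for (p in sim$uni_mol[[nm]]) {
      for (pr in p$products) add_node(pr, "molecule")
      edges[[length(edges) + 1L]] <-
        list(educts = I(nm), products = I(p$products),
             kind = p$kind, rate = p$rate, radius = p$radius)
    }
  }
  for (nm in names(sim$uni_particle)) {
    add_node(nm, "particle")
    for (p in sim$uni_particle[[nm]]) {
      for (pr in p$products) add_node(pr, "particle")
      edges[[length(edges) + 1L]] <-
        list(educts = I(nm), products = I(p$products),
             kind = p$kind, rate = p$rate, radius = p$radius)
    }
  }
  for (key in names(sim$bi)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    for (p in sim$bi[[key]]) {
      e1 <- sim$ptype_names[p$e1]; e2 <- sim$ptype_names[p$e2]
      add_node(e1, "particle"); add_node(e2, "particle")
      for (pr in p$products) add_node(pr, "molecule")
      edges[[length(edges) + 1L]] <-
        list(educts = I(c(e1, e2)), products = I(p$products),
             kind = p$kind, rate = p$rate, radius = p$radius)
    }
  }
  g <- list(nodes = nodes, edges = edges)
  if (!is.null(file)) {
    jsonlite::write_json(g, file, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(g))
  }
  g
}
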