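# Readers and writers for the package's plain-text formats: sweep CSVs with
# JSON annotation sidecars, multi-model PDB trajectories, and JSON kinetic
# scheme/protocol configurations.

.sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read gating-current sweeps from CSV
#'
#' Expects columns `time_ms`, `current`, `voltage_mV` (header-driven; column
#' order is irrelevant) and an optional `sweep_id` column separating several
#' sweeps in one file. Annotations (depolarisation window etc.) are read
#' from a JSON sidecar with the same basename if present: either a single
#' annotation object or a list keyed by sweep id.
#'
#' @param path CSV file path.
#' @return List of `gating_sweep` objects.
#' @export
read_sweep_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("time_ms", "current", "voltage_mV")) {
    if (!col %in% names(df)) {
      stop(sprintf("missing required column `%s` in %s", col, path))
    }
  }
  side <- .sidecar_path(path)
  ann_all <- if (side != path && file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else NULL

  ids <- if ("sweep_id" %in% names(df)) unique(df$sweep_id) else list(NULL)
  lapply(ids, function(id) {
    sub <- if (is.null(id)) df else df[df$sweep_id == id, , drop = FALSE]
    if (any(diff(sub$time_ms) <= 0)) {
      stop("`time_ms` must be strictly increasing within a sweep")
    }
    ann <- list()
    if (!is.null(ann_all)) {
      ann <- if (!is.null(id) && !is.null(ann_all[[as.character(id)]])) {
        ann_all[[as.character(id)]]
      } else if (is.null(id)) ann_all else list()
    }
    gating_sweep(sub$time_ms, sub$current, sub$voltage_mV,
                 annotations = lapply(ann, unlist))
  })
}

#' Write gating-current sweeps to CSV (+ JSON annotation sidecar)
#'
#' Inverse of [read_sweep_table()]: writes all sweeps into one CSV with a
#' `sweep_id` column and their annotations into a JSON sidecar keyed by
#' sweep id. Values round-trip exactly (15 significant digits).
#'
#' @param sweeps A `gating_sweep` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(sweeps, path) {
  if (inherits(sweeps, "gating_sweep")) sweeps <- list(sweeps)
  df <- do.call(rbind, lapply(seq_along(sweeps), function(i) {
    sw <- sweeps[[i]]
    data.frame(sweep_id = i, time_ms = sw$times, current = sw$current,
               voltage_mV = sw$voltage)
  }))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  anns <- lapply(sweeps, `[[`, "annotations")
  names(anns) <- as.character(seq_along(sweeps))
  if (any(lengths(anns) > 0)) {
    jsonlite::write_json(anns, .sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a multi-model PDB file as a frame series
#'
#' Parses MODEL/ENDMDL-delimited coordinate sets into a [frame_series],
#' requiring a consistent atom count and ordering across models. A
#' single-model PDB yields one frame.
#'
#' @param path PDB file path.
#' @param frame_interval Frame spacing in ns (metadata).
#' @return A [frame_series].
#' @export
read_structure_frames <- function(path, frame_interval = NA_real_) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- nrow(pdb$atom)
  if (ncol(xyz) != 3 * n_atoms) {
    stop("inconsistent atom count across models")
  }
  coords <- lapply(seq_len(nrow(xyz)), function(k) {
    matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  })
  atoms <- data.frame(resno = pdb$atom$resno, resid = pdb$atom$resid,
                      elety = pdb$atom$elety, chain = pdb$atom$chain,
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  frame_series(coords, atoms, frame_interval)
}

#' Write a frame series as a multi-model PDB file
#'
#' Emits standard MODEL/ATOM/ENDMDL/END records with fixed-width fields;
#' output bytes are a deterministic function of the input, so fixed-seed
#' synthetic trajectories serialise reproducibly.
#'
#' @param traj A [frame_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_frames <- function(traj, path) {
  stopifnot(inherits(traj, "frame_series"))
  at <- traj$atoms
  lines <- character(0)
  for (k in seq_along(traj$coords)) {
    xyz <- traj$coords[[k]]
    lines <- c(lines, sprintf("MODEL     %4d", k),
               vapply(seq_len(nrow(at)), function(i) {
                 nm <- at$elety[i]
                 nm_field <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
                 sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                         i, nm_field, at$resid[i], at$chain[i], at$resno[i],
                         xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0)
               }, character(1)),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a kinetic scheme (and optional protocol) from a JSON config
#'
#' Schema: `{"states": [...], "transitions": [{"alpha0":..., "beta0":...,
#' "x":..., "z_delta":...}, ...], "n_channels":..., "temperature_K":...,
#' "protocol": {"durations_ms": [...], "voltages_mV": [...],
#' "sample_interval_ms":...}}`. `states` and `protocol` are optional.
#'
#' @param path JSON file path.
#' @return List with `scheme` (a [kinetic_scheme]) and `protocol` (a
#'   [voltage_protocol] or `NULL`).
#' @export
read_scheme_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- cfg$transitions
  if (is.null(tr)) stop("config lacks `transitions`")
  if (is.data.frame(tr)) tr <- split(tr, seq_len(nrow(tr)))
  pick <- function(v, default) {
    if (is.null(v) || is.na(v)) default else v
  }
  transitions <- lapply(tr, function(p) {
    transition_params(p$alpha0, p$beta0, pick(p$x, 0.5), pick(p$z_delta, 1))
  })
  scheme <- kinetic_scheme(
    transitions = unname(transitions),
    state_names = cfg$states,
    n_channels = if (is.null(cfg$n_channels)) 1e7 else cfg$n_channels,
    temperature = if (is.null(cfg$temperature_K)) 295.15 else cfg$temperature_K
  )
  protocol <- NULL
  if (!is.null(cfg$protocol)) {
    pr <- cfg$protocol
    protocol <- voltage_protocol(pr$durations_ms, pr$voltages_mV,
                                 if (is.null(pr$sample_interval_ms)) 0.05
                                 else pr$sample_interval_ms)
  }
  list(scheme = scheme, protocol = protocol)
}
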