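#' Write a trajectory to the internal `.lgt` container
#'
#' Chunked binary container: 4-byte magic `LGT1`, a little-endian int32
#' header length, a JSON header (bead count, frame count, box, periodicity,
#' topology table), then fixed-size frame records --- float64 time, 3 x
#' float64 box, 3N float32 positions in row order x,y,z per bead. Positions
#' therefore round-trip within float32 precision; times and box exactly.
#'
#' @param traj `lg_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "lg_trajectory"))
  n_beads <- dim(traj$positions)[1]
  nf <- n_frames(traj)
  topo <- as.data.frame(unclass(traj$topology), stringsAsFactors = FALSE)
  header <- jsonlite::toJSON(list(
    format = "LGT1", n_beads = n_beads, n_frames = nf,
    box = traj$box, periodic_z = traj$periodic_z,
    topology = topo), auto_unbox = TRUE, digits = NA, na = "null")
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("LGT1"), con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (f in seq_len(nf)) {
    writeBin(as.double(traj$times_ns[f]), con, size = 8L, endian = "little")
    writeBin(as.double(traj$box), con, size = 8L, endian = "little")
    writeBin(as.vector(t(traj$positions[, , f])), con, size = 4L,
             endian = "little")
  }
  invisible(path)
}

#' Read a `.lgt` trajectory container
#'
#' Rejects silently-corrupt input: a malformed header, a bead-count
#' mismatch between header and topology, or a file truncated mid-frame all
#' raise a format error naming the frame index.
#'
#' @param path `.lgt` file.
#' @return `lg_trajectory` (without generator metadata).
#' @export
read_trajectory <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "LGT1"))
    stop_lg("not an LGT container: bad magic '%s'", magic,
            class = "lipidgate_format_error")
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(hlen) || hlen <= 0)
    stop_lg("malformed header length", class = "lipidgate_format_error")
  hraw <- readBin(con, "raw", hlen)
  if (length(hraw) < hlen)
    stop_lg("truncated header", class = "lipidgate_format_error")
  header <- jsonlite::fromJSON(rawToChar(hraw))
  n_beads <- header$n_beads; nf <- header$n_frames
  topo <- header$topology
  if (nrow(topo) != n_beads)
    stop_lg("header says %d beads but topology has %d rows", n_beads,
            nrow(topo), class = "lipidgate_format_error")
  topo$resid <- as.integer(topo$resid)
  topo$subunit <- as.integer(topo$subunit)
  topology <- as_lg_topology(topo)
  positions <- array(NA_real_, c(n_beads, 3, nf))
  times <- numeric(nf)
  box <- as.numeric(header$box)
  for (f in seq_len(nf)) {
    t_f <- readBin(con, "double", 1L, size = 8L, endian = "little")
    b_f <- readBin(con, "double", 3L, size = 8L, endian = "little")
    p_f <- readBin(con, "double", 3L * n_beads, size = 4L, endian = "little")
    if (!length(t_f) || length(b_f) < 3L || length(p_f) < 3L * n_beads)
      stop_lg("file truncated at frame %d of %d", f, nf,
              class = "lipidgate_format_error")
    times[f] <- t_f
    positions[, , f] <- matrix(p_f, ncol = 3, byrow = TRUE)
  }
  structure(list(times_ns = times, positions = positions, box = box,
                 topology = topology,
                 periodic_z = isTRUE(header$periodic_z),
                 leaflet = NULL, bound_site = NULL,
                 schedule = NULL, binding = NULL, seed = NA_integer_),
            class = "lg_trajectory")
}

#' Export one frame as a GRO coordinate file
#'
#' Fixed-width GROMACS coordinate format; lipids are written one residue per
#' molecule with the species as residue name, protein beads as residue
#' `PROT`. Positions in nm.
#'
#' @param frame `lg_frame`.
#' @param topology `lg_topology`.
#' @param path output path.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, topology, path, title = "lipidgate frame") {
  n <- nrow(topology)
  resname <- ifelse(topology$species == "PROTEIN", "PROT", topology$species)
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     topology$molecule_id %% 100000L, resname, "BB",
                     topology$bead_id %% 100000L,
                     frame$positions[, 1], frame$positions[, 2],
                     frame$positions[, 3]),
             sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                     frame$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Import a single-frame GRO coordinate file
#'
#' Residue names are mapped to the package's species vocabulary via
#' `species_map`; unmapped names raise an error.
#'
#' @param path GRO file.
#' @param species_map named character vector, residue name -> species (e.g.
#'   `c(POPC = "PC", PROT = "PROTEIN")`).
#' @return list with `frame` (`lg_frame`) and `topology` (`lg_topology`).
#' @export
read_gro <- function(path, species_map) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop_lg("GRO file too short", class = "lipidgate_format_error")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || length(lines) < n + 3)
    stop_lg("GRO atom count mismatch", class = "lipidgate_format_error")
  at <- lines[3:(n + 2)]
  resid <- as.integer(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  if (any(is.na(c(x, y, z))))
    stop_lg("malformed GRO coordinates", class = "lipidgate_format_error")
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1:3]
  unmapped <- setdiff(unique(resname), names(species_map))
  if (length(unmapped))
    stop_lg("no species mapping for residue name(s): %s",
            paste(unmapped, collapse = ", "), class = "lipidgate_format_error")
  species <- unname(species_map[resname])
  check_species(species, allow_protein = TRUE)
  topology <- as_lg_topology(data.frame(
    bead_id = seq_len(n), molecule_id = resid, species = species,
    resid = ifelse(species == "PROTEIN", resid, NA_integer_),
    subunit = NA_integer_, leaflet0 = NA_character_,
    stringsAsFactors = FALSE))
  list(frame = lg_frame(0, unname(cbind(x, y, z)), box), topology = topology)
}

#' Write / read a topology as TSV
#' @param topology `lg_topology`.
#' @param path TSV path.
#' @return `path` / `lg_topology`.
#' @export
write_topology <- function(topology, path) {
  utils::write.table(as.data.frame(unclass(topology)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$resid <- as.integer(df$resid)
  df$subunit <- as.integer(df$subunit)
  as_lg_topology(df)
}

#' Read a recorded trace from CSV
#'
#' Expects a time column and a value column (defaults `time_s`, `value`);
#' time must be strictly increasing. When an epoch-table sidecar is given it
#' is attached as the trace's illumination protocol.
#'
#' @param path CSV with the trace samples.
#' @param time_col,value_col column names.
#' @param kind `"current"` or `"fluorescence"`.
#' @param units unit string (default pA/pF for current, F/F0 otherwise).
#' @param protocol_path optional epoch-table CSV sidecar, see
#'   [read_epochs_csv()].
#' @return `lg_trace`.
#' @export
read_trace_csv <- function(path, time_col = "time_s", value_col = "value",
                           kind = c("current", "fluorescence"), units = NULL,
                           protocol_path = NULL) {
  kind <- match.arg(kind)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(time_col, value_col), names(df))
  if (length(missing_cols))
    stop_lg("missing column(s): %s", paste(missing_cols, collapse = ", "),
            class = "lipidgate_format_error")
  tm <- df[[time_col]]; val <- df[[value_col]]
  if (is.unsorted(tm, strictly = TRUE))
    stop_lg("time column is not strictly increasing",
            class = "lipidgate_format_error")
  protocol <- if (!is.null(protocol_path)) read_epochs_csv(protocol_path) else NULL
  lg_trace(tm, val, kind = kind,
           units = units %||% if (kind == "current") "pA/pF" else "F/F0",
           protocol = protocol)
}

#' Write a trace to CSV (`time_s`, `value`)
#' @param trace `lg_trace`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$time_s, value = trace$value), path,
            row.names = FALSE)
  invisible(path)
}

#' Read / write an illumination epoch table
#'
#' CSV with columns `start_s`, `duration_s`, `wavelength_nm`,
#' `intensity_pct`.
#'
#' @param path CSV path.
#' @return `lg_protocol` / `path`.
#' @export
read_epochs_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "duration_s", "wavelength_nm", "intensity_pct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_lg("epoch table missing column(s): %s",
            paste(missing_cols, collapse = ", "),
            class = "lipidgate_format_error")
  illumination_protocol(df$start_s, df$duration_s, df$wavelength_nm,
                        df$intensity_pct)
}

#' @rdname read_epochs_csv
#' @param protocol `lg_protocol` to write.
#' @export
write_epochs_csv <- function(protocol, path) {
  write.csv(as.data.frame(unclass(protocol)), path, row.names = FALSE)
  invisible(path)
}
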