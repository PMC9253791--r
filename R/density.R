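#' Accumulate a species-resolved 3D voxel density
#'
#' Each selected bead adds one count to its containing voxel per frame,
#' positions wrapped into the primary box; voxels are half-open intervals
#' `[origin + k*edge, origin + (k+1)*edge)`. No alignment is performed: the
#' protein is positionally fixed in both the reference systems (restrained
#' backbone) and the generator. Raw histogram only --- no Gaussian smearing.
#'
#' @param trajectories list of `lg_trajectory` (or one).
#' @param species lipid species to map (e.g. `"DAG"`).
#' @param edge voxel edge, nm (default 0.1, the reference map resolution).
#' @param frames optional frame indices (default all).
#' @param normalize `"counts"` (default) or `"density"` (counts per voxel
#'   volume per frame, nm^-3).
#' @return `lg_density_grid`: list with `values` (nx x ny x nz array),
#'   `origin`, `edge`, `dims`, `species`, `n_frames`, `normalize`.
#' @export
accumulate_density <- function(trajectories, species = "DAG", edge = 0.1,
                               frames = NULL,
                               normalize = c("counts", "density")) {
  normalize <- match.arg(normalize)
  if (inherits(trajectories, "lg_trajectory")) trajectories <- list(trajectories)
  stopifnot(edge > 0)
  check_species(species, allow_protein = TRUE)
  box <- trajectories[[1]]$box
  dims <- pmax(1L, as.integer(ceiling(box / edge - 1e-9)))
  vals <- array(0, dims)
  total_frames <- 0L
  for (tr in trajectories) {
    sel <- which(tr$topology$species == species)
    if (!length(sel))
      stop_lg("species %s absent from topology", species,
              class = "lipidgate_species_error")
    fr <- frames %||% seq_len(n_frames(tr))
    if (!length(fr)) stop_lg("empty frame range", class = "lipidgate_window_error")
    for (f in fr) {
      p <- matrix(tr$positions[sel, , f], ncol = 3)
      vox <- matrix(0L, nrow(p), 3)
      for (k in 1:3) {
        w <- p[, k] %% box[k]
        vox[, k] <- pmin(as.integer(floor(w / edge)), dims[k] - 1L)
      }
      idx <- vox[, 1] + dims[1] * (vox[, 2] + dims[2] * vox[, 3]) + 1L
      tb <- tabulate(idx, nbins = prod(dims))
      vals <- vals + array(tb, dims)
      total_frames <- total_frames + 1L
    }
  }
  if (normalize == "density") vals <- vals / (edge^3 * total_frames)
  structure(list(values = vals, origin = c(0, 0, 0), edge = edge,
                 dims = dims, species = species, n_frames = total_frames,
                 normalize = normalize),
            class = "lg_density_grid")
}

#' @export
print.lg_density_grid <- function(x, ...) {
  cat(sprintf("<lg_density_grid> %s: %d x %d x %d voxels @ %.3g nm, %d frames (%s)\n",
              x$species, x$dims[1], x$dims[2], x$dims[3], x$edge,
              x$n_frames, x$normalize))
  invisible(x)
}

#' Integrate a density grid over a sphere
#'
#' Sum of voxel values whose centers lie within `radius` of `center`; used
#' to compare site-proximal and bulk densities.
#'
#' @param grid `lg_density_grid`.
#' @param center length-3 point, nm.
#' @param radius sphere radius, nm.
#' @return numeric total.
#' @export
integrate_density_sphere <- function(grid, center, radius) {
  d <- grid$dims; e <- grid$edge; o <- grid$origin
  cx <- o[1] + (seq_len(d[1]) - 0.5) * e
  cy <- o[2] + (seq_len(d[2]) - 0.5) * e
  cz <- o[3] + (seq_len(d[3]) - 0.5) * e
  # bounding sub-box to avoid a full 3D mask on fine grids
  ix <- which(abs(cx - center[1]) <= radius)
  iy <- which(abs(cy - center[2]) <= radius)
  iz <- which(abs(cz - center[3]) <= radius)
  if (!length(ix) || !length(iy) || !length(iz)) return(0)
  sub <- grid$values[ix, iy, iz, drop = FALSE]
  dx2 <- (cx[ix] - center[1])^2
  dy2 <- (cy[iy] - center[2])^2
  dz2 <- (cz[iz] - center[3])^2
  mask <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
  sum(sub[mask])
}

#' Write a density grid in OpenDX format
#'
#' Plain-text OpenDX scalar field (`gridpositions`/`gridconnections`/array),
#' readable by standard molecular viewers; data values run with Z fastest.
#' Round-trips exactly through [read_dx()].
#'
#' @param grid `lg_density_grid`.
#' @param path output path (`.dx`).
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims; e <- grid$edge; o <- grid$origin
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# OpenDX density map: species %s, %d frames, %s",
            grid$species, grid$n_frames, grid$normalize),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.17g %.17g %.17g", o[1], o[2], o[3]),
    sprintf("delta %.17g 0 0", e),
    sprintf("delta 0 %.17g 0", e),
    sprintf("delta 0 0 %.17g", e),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  v <- aperm(grid$values, c(3, 2, 1))  # write with z fastest
  vv <- as.vector(v)
  pad <- (-length(vv)) %% 3
  if (pad) vv <- c(vv, rep(NA_real_, pad))
  m <- matrix(vv, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.17g", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX density grid written by [write_dx()]
#'
#' @param path `.dx` file path.
#' @return `lg_density_grid` (with `species`/`n_frames` recovered from the
#'   header comment when present).
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  gp <- grep("class gridpositions", lines, value = TRUE)[1]
  if (is.na(gp)) stop_lg("not an OpenDX grid: %s", path,
                         class = "lipidgate_format_error")
  d <- as.integer(strsplit(sub(".*counts +", "", gp), " +")[[1]])
  org <- as.numeric(strsplit(sub("^origin +", "", grep("^origin", lines,
                                                       value = TRUE)[1]), " +")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dm <- t(vapply(deltas, function(l)
    as.numeric(strsplit(sub("^delta +", "", l), " +")[[1]]), numeric(3)))
  ed <- unname(diag(dm))
  if (diff(range(ed)) > 1e-12 * max(ed))
    stop_lg("anisotropic voxels not supported", class = "lipidgate_format_error")
  edge <- ed[1]
  hdr <- grep("data follows", lines)
  n <- prod(d)
  data_lines <- lines[(hdr + 1):length(lines)]
  data_lines <- data_lines[!grepl("^(attribute|object|component)", data_lines)]
  vv <- as.numeric(unlist(strsplit(trimws(data_lines), " +")))
  vv <- vv[!is.na(vv)]
  if (length(vv) != n)
    stop_lg("expected %d values, found %d", n, length(vv),
            class = "lipidgate_format_error")
  vals <- aperm(array(vv, rev(d)), c(3, 2, 1))
  meta <- regmatches(lines[1],
                     regexec("species (\\S+), (\\d+) frames, (\\S+)", lines[1]))[[1]]
  structure(list(values = vals, origin = org, edge = edge, dims = d,
                 species = if (length(meta)) meta[2] else NA_character_,
                 n_frames = if (length(meta)) as.integer(meta[3]) else NA_integer_,
                 normalize = if (length(meta)) meta[4] else "counts"),
            class = "lg_density_grid")
}
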