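#' Specify an asymmetric bilayer composition
#'
#' A `membrane_spec` fixes the geometry and per-leaflet composition of the
#' bilayer the generator builds. Compositions are mole percentages per
#' leaflet; DAG is normally confined to the inner leaflet, mirroring its
#' generation there by phospholipase C.
#'
#' @param box numeric length-3, box edges in nm (x, y, z). Default
#'   `c(24, 24, 12)`, the size of the simulated TRPC3 systems.
#' @param lipids_per_leaflet integer, lipids in each leaflet. The default
#'   650 per leaflet gives ~1300 lipids in total.
#' @param inner,outer named numeric vectors of mole percent per species
#'   (names from `PC, PE, PS, Chol, DAG`); each must sum to 100.
#' @param area_per_lipid nm^2 of membrane area one lipid occupies
#'   (default 0.64).
#' @return An object of class `lg_membrane_spec`.
#' @seealso [membrane_composition()] for the shipped compositions at a given
#'   inner-leaflet DAG percentage, [build_membrane()].
#' @export
membrane_spec <- function(box = c(24, 24, 12),
                          lipids_per_leaflet = 650,
                          inner = membrane_composition(10)$inner,
                          outer = membrane_composition(10)$outer,
                          area_per_lipid = 0.64) {
  stopifnot(length(box) == 3, all(is.finite(box)), all(box > 0),
            length(lipids_per_leaflet) == 1, lipids_per_leaflet >= 0,
            is.finite(area_per_lipid), area_per_lipid > 0)
  lipids_per_leaflet <- as.integer(lipids_per_leaflet)
  for (comp in list(inner = inner, outer = outer)) {
    check_species(names(comp))
    if (any(comp < 0)) stop_lg("negative mole percent", class = "lipidgate_spec_error")
    if (abs(sum(comp) - 100) > 1e-9)
      stop_lg("leaflet composition sums to %.12g, not 100", sum(comp),
              class = "lipidgate_spec_error")
  }
  # sanity: the leaflet must plausibly fit in the box at the stated APL
  need <- lipids_per_leaflet * area_per_lipid
  avail <- box[1] * box[2]
  if (need > avail * 1.10)
    stop_lg("box cross-section %.1f nm^2 cannot hold %d lipids at %.2f nm^2 each",
            avail, lipids_per_leaflet, area_per_lipid,
            class = "lipidgate_sizing_error")
  structure(list(box = as.numeric(box),
                 lipids_per_leaflet = lipids_per_leaflet,
                 inner = inner, outer = outer,
                 area_per_lipid = area_per_lipid),
            class = "lg_membrane_spec")
}

#' Shipped leaflet compositions at a given inner-leaflet DAG fraction
#'
#' Outer leaflet: PC/PE/Chol; inner leaflet: PC/PE/PS/Chol with `dag_inner_pct`
#' percent DAG displacing the other species proportionally. With equal leaflet
#' sizes, 2% and 10% inner-leaflet DAG correspond to 1% and 5% of all lipids.
#'
#' @param dag_inner_pct DAG mole percent of the inner leaflet (0, 2 or 10 in
#'   the shipped scenarios; any value in \[0, 100\] is accepted).
#' @return list with `inner` and `outer` named percent vectors.
#' @export
membrane_composition <- function(dag_inner_pct = 10) {
  stopifnot(dag_inner_pct >= 0, dag_inner_pct <= 100)
  base_inner <- c(PC = 40, PE = 25, PS = 10, Chol = 25)
  inner <- c(base_inner * (100 - dag_inner_pct) / 100, DAG = dag_inner_pct)
  if (dag_inner_pct == 0) inner <- base_inner
  outer <- c(PC = 55, PE = 15, Chol = 30)
  list(inner = inner, outer = outer)
}

#' Integer species counts from percentages by largest-remainder rounding
#'
#' Guarantees the counts sum exactly to `total`. Ties in the fractional
#' remainders are broken by the order of `pct`.
#'
#' @param pct named numeric percentages (summing to 100).
#' @param total integer total count.
#' @return named integer vector summing to `total`.
#' @export
largest_remainder <- function(pct, total) {
  stopifnot(abs(sum(pct) - 100) < 1e-9, total >= 0)
  raw <- pct / 100 * total
  counts <- floor(raw)
  short <- round(total - sum(counts))
  if (short > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Build the initial frame and topology of a protein-containing bilayer
#'
#' Lipids are placed on a jittered square lattice in each leaflet, excluding
#' the protein footprint; per-species counts follow the spec's percentages by
#' largest-remainder rounding, so per-leaflet totals are exact. The protein is
#' inserted at the box center spanning the membrane.
#'
#' @param spec a [membrane_spec()].
#' @param protein a [protein_model()].
#' @param seed integer RNG seed.
#' @return list with elements `frame` (a `lg_frame`) and `topology`
#'   (a `lg_topology` carrying the protein model as attribute `"protein"`).
#' @export
build_membrane <- function(spec, protein, seed = 1) {
  stopifnot(inherits(spec, "lg_membrane_spec"), inherits(protein, "lg_protein"))
  box <- spec$box
  if (max(abs(protein$positions[, 1:2] - box[1] / 2)) > box[1] / 2 ||
      any(protein$positions[, 3] < 0 | protein$positions[, 3] > box[3]))
    stop_lg("protein does not fit inside the box", class = "lipidgate_sizing_error")

  set.seed(as.integer(seed))
  spacing <- sqrt(spec$area_per_lipid)
  nx <- floor(box[1] / spacing); ny <- floor(box[2] / spacing)
  gx <- (seq_len(nx) - 0.5) * (box[1] / nx)
  gy <- (seq_len(ny) - 0.5) * (box[2] / ny)
  grid <- expand.grid(x = gx, y = gy)
  ctr <- box[1:2] / 2
  keep <- sqrt((grid$x - ctr[1])^2 + (grid$y - ctr[2])^2) > protein$footprint_radius
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) < spec$lipids_per_leaflet)
    stop_lg("only %d lattice sites outside the protein footprint for %d lipids",
            nrow(grid), spec$lipids_per_leaflet, class = "lipidgate_sizing_error")

  place_leaflet <- function(comp, leaflet) {
    counts <- largest_remainder(comp, spec$lipids_per_leaflet)
    counts <- counts[counts > 0]
    n <- sum(counts)
    idx <- sample.int(nrow(grid), n)
    pos <- cbind(grid$x[idx], grid$y[idx])
    pos <- pos + matrix(rnorm(2 * n, sd = 0.15 * spacing), ncol = 2)
    pos[, 1] <- pos[, 1] %% box[1]
    pos[, 2] <- pos[, 2] %% box[2]
    z <- if (leaflet == "inner") protein$z_inner else protein$z_outer
    list(pos = cbind(pos, z),
         species = rep(names(counts), counts),
         leaflet = rep(leaflet, n))
  }

  inner <- place_leaflet(spec$inner, "inner")
  outer <- place_leaflet(spec$outer, "outer")

  n_prot <- nrow(protein$positions)
  lipid_pos <- rbind(inner$pos, outer$pos)
  n_lip <- nrow(lipid_pos)

  positions <- rbind(protein$positions, lipid_pos)
  topology <- data.frame(
    bead_id = seq_len(n_prot + n_lip),
    molecule_id = c(rep(1L, n_prot), 1L + seq_len(n_lip)),
    species = c(rep("PROTEIN", n_prot), inner$species, outer$species),
    resid = c(protein$map$resid, rep(NA_integer_, n_lip)),
    subunit = c(protein$map$subunit, rep(NA_integer_, n_lip)),
    leaflet0 = c(rep(NA_character_, n_prot), inner$leaflet, outer$leaflet),
    stringsAsFactors = FALSE
  )
  topology <- as_lg_topology(topology)
  attr(topology, "protein") <- protein

  frame <- lg_frame(time = 0, positions = positions, box = box)
  list(frame = frame, topology = topology)
}

#' Construct a single trajectory frame
#'
#' @param time time in ns.
#' @param positions N x 3 numeric matrix of bead positions (nm).
#' @param box length-3 box vector (nm).
#' @param periodic_z is the box treated as periodic in Z for distance
#'   calculations? The synthetic membranes are not.
#' @return `lg_frame` object.
#' @export
lg_frame <- function(time, positions, box, periodic_z = FALSE) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)),
            length(box) == 3, all(box > 0), is.finite(time))
  structure(list(time = time, positions = positions, box = as.numeric(box),
                 periodic_z = isTRUE(periodic_z)),
            class = "lg_frame")
}

as_lg_topology <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("bead_id", "molecule_id", "species") %in% names(df)))
  check_species(df$species, allow_protein = TRUE)
  if (anyDuplicated(df$bead_id))
    stop_lg("duplicate bead ids", class = "lipidgate_topology_error")
  class(df) <- c("lg_topology", "data.frame")
  df
}

#' @export
print.lg_topology <- function(x, ...) {
  cat(sprintf("<lg_topology> %d beads, %d molecules\n",
              nrow(x), length(unique(x$molecule_id))))
  print(table(x$species))
  invisible(x)
}

#' @export
print.lg_membrane_spec <- function(x, ...) {
  cat(sprintf("<lg_membrane_spec> box %.1f x %.1f x %.1f nm, %d lipids/leaflet\n",
              x$box[1], x$box[2], x$box[3], x$lipids_per_leaflet))
  cat(" inner:", paste(sprintf("%s %.3g%%", names(x$inner), x$inner), collapse = ", "), "\n")
  cat(" outer:", paste(sprintf("%s %.3g%%", names(x$outer), x$outer), collapse = ", "), "\n")
  invisible(x)
}
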