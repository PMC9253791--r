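#' Residue sets lining the L1 and L2 lipid coordination sites
#'
#' L1 sits in the voltage-sensor-like domain, L2 in the pore domain of each
#' TRPC3 subunit. The shipped defaults are the eight L1 residues
#' (W334, C350, L351, L354, A390, I394, N560, M586) and the nine L2 residues
#' (E615, F618, K619, F622, W623, N645, Y648, A649, G652), replicated over
#' the four subunits of the tetramer.
#'
#' @param name `"L1"` or `"L2"`.
#' @param resids integer residue ids lining the site (defaults above).
#' @param subunits subunits the set is replicated over (default 1:4).
#' @return `lg_site` object.
#' @export
site_definition <- function(name = c("L1", "L2"), resids = NULL, subunits = 1:4) {
  name <- match.arg(name)
  if (is.null(resids)) {
    resids <- switch(name,
      L1 = c(334L, 350L, 351L, 354L, 390L, 394L, 560L, 586L),
      L2 = c(615L, 618L, 619L, 622L, 623L, 645L, 648L, 649L, 652L))
  }
  stopifnot(length(resids) >= 1, !anyDuplicated(resids), all(subunits %in% 1:4))
  structure(list(name = name, resids = as.integer(resids),
                 subunits = as.integer(subunits)),
            class = "lg_site")
}

#' @export
print.lg_site <- function(x, ...) {
  cat(sprintf("<lg_site> %s: %d residues x subunits {%s}\n",
              x$name, length(x$resids), paste(x$subunits, collapse = ",")))
  invisible(x)
}

#' Stylised coarse-grained TRPC3 tetramer
#'
#' Builds a reduced, four-fold symmetric bead model of the TRPC3
#' transmembrane domain: per subunit, one bead per L1/L2 site residue placed
#' at the membrane-facing surface near its pocket, plus scaffold beads on an
#' inner cylinder. Pocket capture centers sit just outside the protein
#' surface at the inner-leaflet plane, one L1 and one L2 pocket per subunit
#' (4-fold symmetric placement). The model is positionally fixed throughout
#' a simulation, as the backbone is restrained in the reference CG systems.
#'
#' @param center xy center (nm); defaults to the center of a 24 x 24 box.
#' @param z_mid membrane midplane height (nm).
#' @param radius protein surface radius (nm).
#' @param footprint_radius lateral exclusion radius for lipid placement (nm).
#' @param pocket_radius capture radius of each pocket (nm).
#' @param leaflet_offset half-distance between the leaflet bead planes (nm).
#' @param n_scaffold scaffold beads per subunit (residue ids 900+).
#' @return `lg_protein` object with `positions`, `map` (resid, subunit),
#'   `pockets` (site, subunit, center, radius, resids), leaflet planes
#'   `z_inner`/`z_outer`, and `z_mid`.
#' @export
protein_model <- function(center = c(12, 12), z_mid = 6, radius = 3.5,
                          footprint_radius = 4.2, pocket_radius = 0.55,
                          leaflet_offset = 1.0, n_scaffold = 24) {
  l1 <- site_definition("L1")
  l2 <- site_definition("L2")
  z_inner <- z_mid - leaflet_offset
  z_outer <- z_mid + leaflet_offset

  pos <- list(); resid <- integer(); subunit <- integer()
  pockets <- list()
  for (su in 1:4) {
    ang0 <- (su - 1) * pi / 2
    # pocket centers just outside the surface; L1 offset 45 deg from L2
    for (site in c("L1", "L2")) {
      ang <- ang0 + if (site == "L1") pi / 4 else 0
      pc <- c(center + (radius + 0.45) * c(cos(ang), sin(ang)), z_inner)
      site_res <- if (site == "L1") l1$resids else l2$resids
      pockets[[length(pockets) + 1]] <- list(site = site, subunit = su,
                                             center = pc, radius = pocket_radius,
                                             resids = site_res)
      # site residue beads ring the pocket on the protein surface
      k <- length(site_res)
      ring <- ang + seq(-0.35, 0.35, length.out = k)
      rp <- cbind(center[1] + radius * cos(ring),
                  center[2] + radius * sin(ring),
                  z_inner + seq(-0.25, 0.25, length.out = k))
      pos[[length(pos) + 1]] <- rp
      resid <- c(resid, site_res)
      subunit <- c(subunit, rep(su, k))
    }
    # scaffold beads: inner cylinder spanning the membrane
    ks <- seq_len(n_scaffold)
    angs <- ang0 + 2 * pi * ks / (4 * n_scaffold)
    zs <- z_mid + 1.6 * sin(ks)  # spread through the TM region
    sp <- cbind(center[1] + 0.6 * radius * cos(angs),
                center[2] + 0.6 * radius * sin(angs),
                pmin(pmax(zs, z_inner - 0.5), z_outer + 0.5))
    pos[[length(pos) + 1]] <- sp
    resid <- c(resid, 900L + ks)
    subunit <- c(subunit, rep(su, n_scaffold))
  }
  positions <- do.call(rbind, pos)
  map <- data.frame(resid = resid, subunit = subunit)

  pk <- data.frame(
    site = vapply(pockets, `[[`, "", "site"),
    subunit = vapply(pockets, function(p) p$subunit, 1L),
    cx = vapply(pockets, function(p) p$center[1], 1.0),
    cy = vapply(pockets, function(p) p$center[2], 1.0),
    cz = vapply(pockets, function(p) p$center[3], 1.0),
    radius = vapply(pockets, function(p) p$radius, 1.0)
  )
  obj <- structure(list(positions = positions, map = map, pockets = pk,
                        pocket_resids = list(L1 = l1$resids, L2 = l2$resids),
                        footprint_radius = footprint_radius,
                        z_inner = z_inner, z_outer = z_outer, z_mid = z_mid),
                   class = "lg_protein")
  validate_protein(obj)
}

validate_protein <- function(p) {
  # 4-fold symmetry of pocket placement and residue coverage
  for (site in unique(p$pockets$site)) {
    if (sum(p$pockets$site == site) != 4)
      stop_lg("pocket set for %s is not 4-fold", site, class = "lipidgate_protein_error")
    if (!all(p$pocket_resids[[site]] %in% p$map$resid))
      stop_lg("pocket residues missing from bead map", class = "lipidgate_protein_error")
  }
  p
}

#' @export
print.lg_protein <- function(x, ...) {
  cat(sprintf("<lg_protein> %d beads, %d pockets, footprint %.1f nm\n",
              nrow(x$positions), nrow(x$pockets), x$footprint_radius))
  invisible(x)
}
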