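#' Bead pairs within a distance cutoff under periodic boundaries
#'
#' Minimum-image distances in an orthorhombic box; the Z dimension is only
#' wrapped when `periodic_z = TRUE` (the synthetic membranes are finite in
#' Z). Two code paths are available --- a vectorised all-pairs evaluation and
#' a cell list with cell edge >= cutoff --- under the contract that both
#' return identical pairs; `"auto"` uses the cell list for large systems.
#'
#' @param pos_a,pos_b N x 3 position matrices (nm).
#' @param box length-3 box (nm).
#' @param cutoff distance cutoff (nm). Must be below half the smallest
#'   periodic box edge, otherwise the minimum image is ambiguous.
#' @param periodic_z wrap Z?
#' @param method `"auto"`, `"brute"` or `"cell"`.
#' @return data.frame with columns `i` (row in `pos_a`), `j` (row in
#'   `pos_b`), ordered by `i` then `j`.
#' @export
pairs_within_cutoff <- function(pos_a, pos_b, box, cutoff,
                                periodic_z = FALSE,
                                method = c("auto", "brute", "cell")) {
  method <- match.arg(method)
  pos_a <- as.matrix(pos_a); pos_b <- as.matrix(pos_b)
  stopifnot(ncol(pos_a) == 3, ncol(pos_b) == 3, cutoff > 0)
  wrapped <- c(TRUE, TRUE, periodic_z)
  if (cutoff >= min(box[wrapped]) / 2)
    stop_lg("cutoff %.3g nm >= half the smallest periodic box edge (%.3g nm)",
            cutoff, min(box[wrapped]), class = "lipidgate_ambiguity_error")
  if (method == "auto")
    method <- if (nrow(pos_a) < 1000 && nrow(pos_b) < 1000) "brute" else "cell"
  out <- switch(method,
    brute = pairs_brute(pos_a, pos_b, box, cutoff, wrapped),
    cell = pairs_cell(pos_a, pos_b, box, cutoff, wrapped))
  out[order(out$i, out$j), , drop = FALSE]
}

min_image_delta <- function(d, edge) d - edge * round(d / edge)

pairs_brute <- function(pos_a, pos_b, box, cutoff, wrapped) {
  na <- nrow(pos_a); nb <- nrow(pos_b)
  if (na == 0 || nb == 0) return(data.frame(i = integer(), j = integer()))
  d2 <- matrix(0, na, nb)
  for (k in 1:3) {
    dk <- outer(pos_a[, k], pos_b[, k], "-")
    if (wrapped[k]) dk <- min_image_delta(dk, box[k])
    d2 <- d2 + dk * dk
  }
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  data.frame(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]))
}

pairs_cell <- function(pos_a, pos_b, box, cutoff, wrapped) {
  na <- nrow(pos_a); nb <- nrow(pos_b)
  if (na == 0 || nb == 0) return(data.frame(i = integer(), j = integer()))
  ncell <- pmax(1L, as.integer(floor(box / cutoff)))
  edge <- box / ncell
  cell_of <- function(pos) {
    idx <- matrix(0L, nrow(pos), 3)
    for (k in 1:3) {
      ck <- as.integer(floor((pos[, k] %% box[k]) / edge[k]))
      idx[, k] <- pmin(ck, ncell[k] - 1L)  # guard numeric edge case
    }
    idx
  }
  cb <- cell_of(pos_b)
  key_b <- (cb[, 1] * ncell[2] + cb[, 2]) * ncell[3] + cb[, 3]
  buckets <- split(seq_len(nb), key_b)
  ca <- cell_of(pos_a)
  res_i <- vector("list", na); res_j <- vector("list", na)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (i in seq_len(na)) {
    cand <- integer()
    for (o in seq_len(nrow(offs))) {
      cc <- ca[i, ] + offs[o, ]
      ok <- TRUE
      for (k in 1:3) {
        if (wrapped[k]) cc[k] <- cc[k] %% ncell[k]
        else if (cc[k] < 0 || cc[k] >= ncell[k]) { ok <- FALSE; break }
      }
      if (!ok) next
      b <- buckets[[as.character((cc[1] * ncell[2] + cc[2]) * ncell[3] + cc[3])]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- unique(cand)
    if (!length(cand)) next
    d2 <- numeric(length(cand))
    for (k in 1:3) {
      dk <- pos_a[i, k] - pos_b[cand, k]
      if (wrapped[k]) dk <- min_image_delta(dk, box[k])
      d2 <- d2 + dk * dk
    }
    keep <- cand[d2 <= cutoff^2]
    if (length(keep)) { res_i[[i]] <- rep(i, length(keep)); res_j[[i]] <- keep }
  }
  data.frame(i = as.integer(unlist(res_i)), j = as.integer(unlist(res_j)))
}
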