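#' Build the neighbor table of a configuration
#'
#' Lists, for every atom, the neighbors closer than `r_cut` together with
#' their displacement vectors (minimum image when periodic), distances and
#' species. Atoms exactly at the cutoff are excluded (open interval); this is
#' harmless because every radial basis function vanishes at the cutoff.
#'
#' @param config An [atomic_configuration()].
#' @param r_cut Cutoff radius in Angstrom. For periodic configurations it
#'   must be smaller than half the smallest cell height for the minimum-image
#'   convention to be valid.
#' @return An object of class `neighbor_table`: a list with one entry per
#'   atom, each holding `index` (neighbor atom indices), `disp` (an
#'   `n_neighbors x 3` matrix of displacement vectors pointing from the
#'   central atom to the neighbor), `dist` and `species`.
#' @export
build_neighbor_table <- function(config, r_cut) {
  n <- n_atoms(config)
  if (any(config$periodic)) {
    h <- cell_heights(config$cell)
    lim <- min(h[config$periodic]) / 2
    if (r_cut >= lim) {
      stop(sprintf(paste0("r_cut = %g exceeds the minimum-image limit %g ",
                          "(half the smallest periodic cell height)"),
                   r_cut, lim))
    }
  }
  pos <- config$positions
  out <- vector("list", n)
  for (i in seq_len(n)) {
    disp <- sweep(pos, 2L, pos[i, ])
    disp <- minimum_image(disp, config$cell, config$periodic)
    d <- sqrt(rowSums(disp^2))
    keep <- which(d < r_cut & seq_len(n) != i)
    out[[i]] <- list(index = keep,
                     disp = disp[keep, , drop = FALSE],
                     dist = d[keep],
                     species = config$species[keep])
  }
  structure(out, class = "neighbor_table", r_cut = r_cut)
}
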